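#' Tabular alignment report
#'
#' Formats a [flux_alignment] as the downloadable tab-separated report:
#' matched reaction pairs with their per-pair contribution to the similarity
#' score, conserved metabolic pathways (connected matched subgraphs of two or
#' more reactions), gaps in the network (unmatched reactions of the first
#' map) and solely inserted reactions (unmatched reactions of the second
#' map).
#'
#' @param r a `flux_alignment`.
#' @param path optional file to write the report to.
#' @return character vector of report lines (invisibly when `path` is
#'   given).
#' @export
alignment_report <- function(r, path = NULL) {
  stopifnot(inherits(r, "flux_alignment"))
  lines <- c(
    paste0("# alignment\t", r$map_a, "\t", r$map_b),
    paste0("# method\t", r$method, "\tlambda\t", format(r$lam)),
    paste0("# score\t", format(r$score, digits = 15)),
    if (!is.na(r$p_value)) paste0("# p_value\t", format(r$p_value)),
    "",
    "[matched reactions]",
    "id_a\tid_b\tcontribution")
  if (nrow(r$matching))
    lines <- c(lines, sprintf("%s\t%s\t%.9g", r$matching$id_a,
                              r$matching$id_b, r$matching$contribution))
  lines <- c(lines, "", "[conserved pathways]")
  if (length(r$conserved_pathways)) {
    for (k in seq_along(r$conserved_pathways)) {
      pw <- r$conserved_pathways[[k]]
      lines <- c(lines, sprintf("pathway_%d\t%s", k,
                                paste(paste(pw$id_a, pw$id_b, sep = "="),
                                      collapse = "\t")))
    }
  }
  lines <- c(lines, "", "[gaps]", r$gaps, "", "[insertions]", r$insertions)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Export an alignment as a GraphML (and SIF) graph
#'
#' Writes a Cytoscape-compatible graph holding both flux maps and the
#' alignment between them: one node per reaction (attributes `map`, `flux`,
#' `ec`), the directed within-map edges with their shared-compound
#' coefficient `m` as weight, and one undirected `match` edge per matched
#' pair carrying its `contribution` to the score (the natural edge-width
#' channel in Cytoscape). Node names are prefixed `a:` / `b:` so the two
#' maps never collide.
#'
#' @param r a `flux_alignment`.
#' @param a,b the `flux_map` objects that were aligned.
#' @param graphml path for the GraphML file (`NULL` to skip).
#' @param sif optional path for a SIF rendering of the same graph.
#' @return the igraph object, invisibly.
#' @export
export_alignment_graph <- function(r, a, b, graphml = NULL, sif = NULL) {
  stopifnot(inherits(r, "flux_alignment"))
  ga <- build_flux_graph(a)
  gb <- build_flux_graph(b)
  nodes <- data.frame(
    name = c(paste0("a:", a$id), paste0("b:", b$id)),
    map = c(rep(a$name, n_reactions(a)), rep(b$name, n_reactions(b))),
    flux = c(a$flux, b$flux),
    ec = c(vapply(a$ec, function(e) if (is.null(e)) "" else format_ec(e), ""),
           vapply(b$ec, function(e) if (is.null(e)) "" else format_ec(e), "")),
    stringsAsFactors = FALSE)
  edge_rows <- function(g, prefix) {
    if (!nrow(g$edges)) return(NULL)
    data.frame(from = paste0(prefix, g$edges$from),
               to = paste0(prefix, g$edges$to),
               interaction = "flow", weight = g$edges$m,
               contribution = NA_real_, stringsAsFactors = FALSE)
  }
  match_rows <- if (nrow(r$matching)) {
    data.frame(from = paste0("a:", r$matching$id_a),
               to = paste0("b:", r$matching$id_b),
               interaction = "match", weight = NA_real_,
               contribution = r$matching$contribution,
               stringsAsFactors = FALSE)
  } else NULL
  edges <- rbind(edge_rows(ga, "a:"), edge_rows(gb, "b:"), match_rows)
  g <- igraph::graph_from_data_frame(
    edges %||% data.frame(from = character(), to = character()),
    directed = TRUE, vertices = nodes)
  if (!is.null(graphml))
    igraph::write_graph(g, graphml, format = "graphml")
  if (!is.null(sif)) {
    sif_lines <- if (is.null(edges) || !nrow(edges)) character() else
      sprintf("%s\t%s\t%s", edges$from, edges$interaction, edges$to)
    writeLines(sif_lines, sif)
  }
  invisible(g)
}
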