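#' Parse a chemical equation into signed stoichiometry
#'
#' The flux-table dialect writes one reaction per row as
#' `"2pg <=> pep + h2o"` or `"fdp => dhap + g3p"`. Terms on a side are joined
#' with `+`; a stoichiometric coefficient is a leading number separated from
#' the metabolite id by whitespace (`"2 g3p"`), so metabolite names that start
#' with a digit (`2pg`, `6pg`, `13bpg`) stay unambiguous. `<=>` marks the
#' reaction as (written) reversible, `=>` as irreversible; the distinction is
#' preserved on round-trip but carries no weight in any score. One side may be
#' empty for transport/unknown pseudo-reactions (`"mal =>"`, `"=> g6p"`).
#' A metabolite appearing on both sides is netted; coefficients netting to
#' zero are dropped.
#'
#' @param eq equation string.
#' @return list with `stoich` (named numeric, negative = consumed) and
#'   `reversible` (logical).
#' @export
parse_equation <- function(eq) {
  stopifnot(is.character(eq), length(eq) == 1L)
  rev <- grepl("<=>", eq, fixed = TRUE)
  sides <- if (rev) strsplit(eq, "<=>", fixed = TRUE)[[1]]
           else strsplit(eq, "=>", fixed = TRUE)[[1]]
  if (!grepl("<=>|=>", eq))
    stop_fluxalign("malformed equation (no arrow): ", eq)
  if (length(sides) > 2L)
    stop_fluxalign("malformed equation (multiple arrows): ", eq)
  sides <- c(sides, rep("", 2L - length(sides)))
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(numeric(0))
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    if (any(!nzchar(terms)))
      stop_fluxalign("malformed equation (empty term): ", eq)
    out <- numeric(0)
    for (t in terms) {
      m <- regmatches(t, regexec("^([0-9]*\\.?[0-9]+)\\s+(\\S.*)$", t))[[1]]
      if (length(m) == 3L) {
        coef <- as.numeric(m[2]); met <- m[3]
      } else {
        coef <- 1; met <- t
      }
      if (grepl("\\s", met))
        stop_fluxalign("malformed equation (metabolite id with spaces): ", eq)
      if (coef == 0) stop_fluxalign("zero coefficient in equation: ", eq)
      prev <- if (met %in% names(out)) out[[met]] else 0
      out[met] <- prev + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (met in names(rhs)) st[met] <- (if (met %in% names(st)) st[met] else 0) + rhs[met]
  st <- st[st != 0]
  if (length(st) == 0L)
    stop_fluxalign("equation nets to nothing: ", eq)
  list(stoich = st, reversible = rev)
}

# inverse of parse_equation, canonical form
deparse_equation <- function(stoich, reversible = FALSE) {
  fmt <- function(s) {
    if (length(s) == 0L) return("")
    paste(vapply(names(s), function(m) {
      cf <- abs(s[[m]])
      if (cf == 1) m else paste(format(cf, digits = 15), m)
    }, ""), collapse = " + ")
  }
  lhs <- fmt(stoich[stoich < 0])
  rhs <- fmt(stoich[stoich > 0])
  arrow <- if (reversible) "<=>" else "=>"
  trimws(paste(lhs, arrow, rhs))
}

#' Read a flux-distribution table
#'
#' Reads a flux map from the package's 5-column table dialect:
#' `id`, `ec`, `equation`, `flux`, `compartment` (header row required; `ec`
#' and `compartment` may be empty). The on-disk dialects are tab-separated
#' UTF-8 text (`dialect = "tsv"`) and Excel workbooks with one case per sheet
#' (`dialect = "xlsx"`, first sheet by default, requires the readxl package).
#' A data frame with those columns is accepted directly. Absent flux values
#' are the literal `NA` (or an empty cell), never 0.
#'
#' This table dialect is this package's own, documented format: the upstream
#' database's submission template is not published, so a self-contained
#' lossless dialect is defined here instead.
#'
#' Substrate-uptake reactions default to all `unknown...` pseudo-reactions
#' (lumped feeds of the carbon source), which matches the curation convention;
#' override with `substrate_ids`.
#'
#' @param source file path (TSV or .xlsx) or a data frame.
#' @param dialect `"tsv"`, `"xlsx"`, or `"auto"` (by file extension).
#' @param sheet sheet name or index for Excel workbooks.
#' @param substrate_ids substrate-uptake reaction ids; `NULL` = all
#'   `unknown...` reactions.
#' @param name case label; defaults to the file (or sheet) name.
#' @param metadata named list of study metadata.
#' @return A validated [flux_map()]. Unparseable rows raise an error naming
#'   the row.
#' @export
parse_flux_table <- function(source, dialect = c("auto", "tsv", "xlsx"),
                             sheet = 1, substrate_ids = NULL,
                             name = NULL, metadata = list()) {
  dialect <- match.arg(dialect)
  if (is.data.frame(source)) {
    df <- source
    name <- name %||% "flux_map"
  } else {
    stopifnot(is.character(source), length(source) == 1L)
    if (dialect == "auto")
      dialect <- if (grepl("\\.xlsx?$", source, ignore.case = TRUE)) "xlsx" else "tsv"
    if (dialect == "xlsx") {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop_fluxalign("reading Excel workbooks requires the readxl package")
      df <- as.data.frame(readxl::read_excel(source, sheet = sheet,
                                             col_types = "text"))
      name <- name %||% if (is.character(sheet)) sheet
                        else sub("\\.[^.]+$", "", basename(source))
    } else {
      df <- utils::read.delim(source, sep = "\t", header = TRUE,
                              colClasses = "character", na.strings = NULL,
                              quote = "", comment.char = "#",
                              fileEncoding = "UTF-8")
      name <- name %||% sub("\\.[^.]+$", "", basename(source))
    }
  }
  names(df) <- tolower(trimws(names(df)))
  need <- c("id", "equation", "flux")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fluxalign("missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop_fluxalign("no reactions")

  blank_to_na <- function(x) {
    x <- trimws(as.character(x))
    x[!nzchar(x) | toupper(x) == "NA"] <- NA_character_
    x
  }
  id <- trimws(as.character(df$id))
  ec_raw <- blank_to_na(df[["ec"]] %||% rep(NA, nrow(df)))
  comp <- blank_to_na(df[["compartment"]] %||% rep(NA, nrow(df)))
  flux_raw <- blank_to_na(df$flux)
  flux <- suppressWarnings(as.numeric(flux_raw))
  bad_flux <- which(!is.na(flux_raw) & is.na(flux))
  if (length(bad_flux))
    stop_fluxalign("row ", bad_flux[1], " (", id[bad_flux[1]],
                   "): unparseable flux value '", flux_raw[bad_flux[1]], "'")

  stoich <- vector("list", nrow(df))
  reversible <- logical(nrow(df))
  ecs <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    pe <- tryCatch(parse_equation(as.character(df$equation[i])),
                   error = function(e)
                     stop_fluxalign("row ", i, " (", id[i], "): ",
                                    conditionMessage(e)))
    stoich[[i]] <- pe$stoich
    reversible[i] <- pe$reversible
    if (!is.na(ec_raw[i]))
      ecs[[i]] <- tryCatch(unclass(ec_class(ec_raw[i])),
                           error = function(e)
                             stop_fluxalign("row ", i, " (", id[i],
                                            "): invalid EC '", ec_raw[i], "'"))
  }
  if (is.null(substrate_ids))
    substrate_ids <- id[reaction_type(id) == "unknown"]
  flux_map(id = id, stoich = stoich, flux = flux, ec = ecs,
           compartment = comp, reversible = reversible,
           substrate_ids = substrate_ids, name = name, metadata = metadata)
}

#' Write a flux map as a canonical TSV table
#'
#' Inverse of [parse_flux_table()]: writes the 5-column tab-separated dialect.
#' Parsing the written file recovers an identical flux map (round-trip
#' identity on canonical-form tables).
#'
#' @param map a `flux_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_flux_table <- function(map, path) {
  stopifnot(inherits(map, "flux_map"))
  df <- as.data.frame(map)
  df$flux <- vapply(map$flux, function(v)
    if (is.na(v)) "NA" else format(v, digits = 15), "")
  df$compartment[is.na(df$compartment)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize a flux map to JSON (and back)
#'
#' A lossless JSON form of the flux map for programmatic interchange:
#' reactions with id, EC, signed stoichiometry, flux, compartment, plus
#' substrate ids and metadata.
#'
#' @param map a `flux_map`.
#' @param path optional file to write; when `NULL` the JSON string is
#'   returned.
#' @return `flux_map_to_json()`: a JSON string (or `path` invisibly);
#'   `flux_map_from_json()`: a `flux_map`.
#' @export
flux_map_to_json <- function(map, path = NULL) {
  stopifnot(inherits(map, "flux_map"))
  obj <- list(
    name = map$name,
    substrate_ids = map$substrate_ids,
    metadata = map$metadata,
    reactions = lapply(seq_along(map$id), function(i) list(
      id = map$id[i],
      ec = if (is.null(map$ec[[i]])) NULL else as.integer(map$ec[[i]]),
      stoich = as.list(map$stoich[[i]]),
      flux = map$flux[i],
      compartment = map$compartment[i],
      reversible = map$reversible[i])))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname flux_map_to_json
#' @param json JSON string or file path produced by [flux_map_to_json()].
#' @export
flux_map_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  rx <- obj$reactions
  flux_map(
    id = vapply(rx, `[[`, "", "id"),
    stoich = lapply(rx, function(r) unlist(r$stoich)),
    flux = vapply(rx, function(r) r$flux %||% NA_real_, NA_real_),
    ec = lapply(rx, function(r) if (is.null(r$ec)) NULL else unlist(r$ec)),
    compartment = vapply(rx, function(r) r$compartment %||% NA_character_,
                         NA_character_),
    reversible = vapply(rx, function(r) isTRUE(r$reversible), TRUE),
    substrate_ids = unlist(obj$substrate_ids) %||% character(),
    name = obj$name %||% "flux_map",
    metadata = obj$metadata %||% list())
}
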