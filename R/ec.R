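#' EC classes and the enzyme hierarchy
#'
#' The EC numbering system is a four-level hierarchy
#' (class.subclass.sub-subclass.serial). A possibly-partial EC class is stored
#' as an ordered integer vector of 1--4 levels; prefix ordering defines the
#' hierarchy, so the common upper class of two enzymes is the longest common
#' prefix of their classes.
#'
#' `ec_class()` accepts an integer vector, a dotted string (`"2.7.1.11"`), or
#' a bracket/colon form (`"[2:7:1:11]"`).
#'
#' @param x EC class in any accepted form.
#' @return An `ec_class` object (integer vector of length 1--4).
#' @examples
#' ec_class("2.7.1.11")
#' ec_common_upper_class(ec_class("2.2.3.4"), ec_class("2.2.3.5")) # [2:2:3]
#' @export
ec_class <- function(x) {
  if (inherits(x, "ec_class")) return(x)
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    x <- gsub("[][ ]", "", x)
    x <- strsplit(x, "[.:]")[[1]]
    x <- x[nzchar(x)]
  }
  x <- suppressWarnings(as.integer(x))
  if (length(x) < 1L || length(x) > 4L || anyNA(x) || any(x < 1))
    stop_fluxalign("not a valid EC class")
  structure(x, class = "ec_class")
}

format_ec <- function(e) paste(unclass(e), collapse = ".")

#' @export
format.ec_class <- function(x, ...) format_ec(x)

#' @export
print.ec_class <- function(x, ...) {
  cat("<ec_class> [", paste(unclass(x), collapse = ":"), "]\n", sep = "")
  invisible(x)
}

#' Common upper class of two EC classes
#'
#' The lowest enzyme class that is an ancestor of both: the longest common
#' prefix of the two level vectors. Two identical enzymes have their own class
#' as common upper class; enzymes differing already at the top level have
#' none.
#'
#' @param u,v `ec_class` objects (or anything [ec_class()] accepts).
#' @return An `ec_class`, or `NULL` when the top levels differ.
#' @export
ec_common_upper_class <- function(u, v) {
  u <- unclass(ec_class(u)); v <- unclass(ec_class(v))
  k <- 0L
  for (i in seq_len(min(length(u), length(v)))) {
    if (u[i] != v[i]) break
    k <- i
  }
  if (k == 0L) NULL else structure(u[seq_len(k)], class = "ec_class")
}

#' Node similarity of two enzymes in an EC universe
#'
#' The similarity between enzymes `u` and `v` is `1 / C(h_uv)`, where `h_uv`
#' is their common upper class and `C(h)` counts the distinct enzyme classes
#' of the universe that fall under `h` (i.e. have `h` as a prefix). The score
#' lies in `[0, 1]`: it is 1 when `u == v` and `u` is the only enzyme of its
#' class in the universe, and 0 when the two enzymes share no upper class.
#'
#' The universe is, by convention, the set of distinct EC classes appearing in
#' the two flux maps being aligned.
#'
#' @param u,v EC classes.
#' @param universe list of EC classes (duplicates are collapsed).
#' @return numeric similarity in `[0, 1]`.
#' @examples
#' uni <- list(ec_class("2.2.3.4"), ec_class("2.2.3.5"))
#' node_similarity(uni[[1]], uni[[2]], uni) # 1 / C([2:2:3]) = 0.5
#' @export
node_similarity <- function(u, v, universe) {
  u <- ec_class(u); v <- ec_class(v)
  stopifnot(length(universe) >= 1L)
  h <- ec_common_upper_class(u, v)
  if (is.null(h)) return(0)
  uni <- unique(lapply(universe, function(e) unclass(ec_class(e))))
  h <- unclass(h)
  under <- vapply(uni, function(e)
    length(e) >= length(h) && all(e[seq_along(h)] == h), logical(1))
  C <- sum(under)
  if (C == 0L) stop_fluxalign("universe does not contain the compared classes")
  1 / C
}

# Node similarity matrix between the reactions of two maps.
# Enzymes (reactions with an EC class) score 1/C(h_uv) against the distinct-EC
# universe of both maps; pseudo-reactions (transport/unknown, or any reaction
# without an EC) score 1 against the identical id and 0 otherwise; an
# enzyme never matches a pseudo-reaction.
node_similarity_matrix <- function(a, b) {
  universe <- unique(c(a$ec[!vapply(a$ec, is.null, TRUE)],
                       b$ec[!vapply(b$ec, is.null, TRUE)]))
  S <- matrix(0, n_reactions(a), n_reactions(b),
              dimnames = list(a$id, b$id))
  for (i in seq_along(a$id)) {
    for (j in seq_along(b$id)) {
      eu <- a$ec[[i]]; ev <- b$ec[[j]]
      S[i, j] <-
        if (!is.null(eu) && !is.null(ev)) node_similarity(eu, ev, universe)
        else if (is.null(eu) && is.null(ev) &&
                 id_key(a$id[i]) == id_key(b$id[j])) 1
        else 0
    }
  }
  S
}
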