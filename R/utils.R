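# internal helpers shared across modules

# Run `expr` under a temporary RNG state seeded with `seed`; restores
# the caller's .Random.seed so library calls never disturb user RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# case-folded reaction-id key (KEGG R-numbers are case-insensitive in practice)
id_key <- function(x) tolower(trimws(x))

vnorm <- function(x) sqrt(sum(x^2))

stop_fluxalign <- function(...) stop(..., call. = FALSE)
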