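#' @keywords internal
"_PACKAGE"

# Internal argument checks ---------------------------------------------------

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (positive && x <= 0) stopf("`%s` must be > 0", name)
  if (nonneg && x < 0) stopf("`%s` must be >= 0", name)
  invisible(x)
}

#' Derive a module-specific seed from a global seed
#'
#' One global seed fans out to per-module random streams so that stochastic
#' stages (phantom placement, noise, weight init, example sampling) are
#' isolated from each other: changing how many draws one stage consumes never
#' perturbs the others.  The derivation hashes the module tag into an offset
#' and keeps the result inside the 32-bit integer range R requires of seeds.
#'
#' @param seed integer global seed.
#' @param tag character module tag, e.g. `"phantom"` or `"train"`.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, tag) {
  check_number(seed, "seed")
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587L)
}

# run code with a local RNG state (does not disturb the caller's stream)
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
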