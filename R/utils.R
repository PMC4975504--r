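# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded draws inside the
#' package never perturb user-level randomness.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage child seed from one pipeline seed
#'
#' Stable arithmetic derivation (kept below 2^31) so that toggling one stage
#' does not shift the random stream of another.
#' @noRd
child_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(simulate = 101L, lesions = 211L, gensini = 307L,
               associate = 401L, interact = 503L, resample = 601L,
               mdr = 701L, report = 809L)
  off <- offsets[[stage]] %||% 997L
  (as.integer(seed) * 31L + off) %% .Machine$integer.max
}

check_probability <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
  if (!ok) stop(sprintf("`%s` must be %s", name,
                        if (open) "in (0, 1)" else "in [0, 1]"), call. = FALSE)
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("`%s` must be positive and finite", name), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != floor(x))
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

GENOTYPE_LEVELS <- c("GG", "AG", "AA")

#' Normalize free-text genotype labels to GG/AG/AA
#' @noRd
normalize_genotype <- function(x) {
  g <- toupper(trimws(as.character(x)))
  g[g == "GA"] <- "AG"
  g
}
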