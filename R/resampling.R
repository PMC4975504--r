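# Monte-Carlo permutation empirical p-values for genotype-table association,
# and Bonferroni multiple-testing control.

#' Plan a Monte-Carlo permutation test
#'
#' @param n_permutations number of random tables to draw (default 100000,
#'   the conventional choice for stable 3-decimal empirical p-values).
#' @param seed integer seed for reproducibility.
#' @param statistic which genetic-model statistic to permute: `"allelic"`,
#'   `"additive"`, `"dominant"` or `"recessive"`.
#' @return Object of class `permutation_plan`.
#' @export
permutation_plan <- function(n_permutations = 100000, seed = NULL,
                             statistic = c("allelic", "additive",
                                           "dominant", "recessive")) {
  check_count(n_permutations, "n_permutations")
  statistic <- match.arg(statistic)
  structure(list(n_permutations = as.integer(n_permutations), seed = seed,
                 statistic = statistic),
            class = "permutation_plan")
}

# squared Wald z on the log cross-product OR (Haldane-corrected when needed);
# cheap, monotone in association evidence, works for any 2x2 collapse
wald_z2 <- function(a, b, cc, d) {
  if (any(c(a, b, cc, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  log((a * d) / (b * cc))^2 / (1 / a + 1 / b + 1 / cc + 1 / d)
}

# association statistic for one 2x3 genotype count matrix under one model
genotype_statistic <- function(m, statistic) {
  switch(statistic,
    allelic = wald_z2(2 * m[1, 3] + m[1, 2], 2 * m[1, 1] + m[1, 2],
                      2 * m[2, 3] + m[2, 2], 2 * m[2, 1] + m[2, 2]),
    dominant = wald_z2(m[1, 2] + m[1, 3], m[1, 1],
                       m[2, 2] + m[2, 3], m[2, 1]),
    recessive = wald_z2(m[1, 3], m[1, 1] + m[1, 2],
                        m[2, 3], m[2, 1] + m[2, 2]),
    additive = {
      # Cochran-Armitage trend chi-square with scores 0/1/2
      s <- 0:2
      n <- sum(m); r1 <- sum(m[1, ]); cs <- colSums(m)
      num <- sum(s * (m[1, ] - r1 * cs / n))
      den <- r1 * (1 - r1 / n) * (sum(s^2 * cs) - sum(s * cs)^2 / n) / n
      if (den <= 0) 0 else num^2 / den
    })
}

#' Monte-Carlo permutation empirical p-value for a genotype table
#'
#' Holds the genotype-column totals and the case/control row totals fixed
#' and redraws random tables from the multivariate hypergeometric null
#' (equivalent to permuting case/control labels over subjects, but far
#' cheaper; Patefield's algorithm via [stats::r2dtable()]). The empirical
#' p-value uses the add-one estimator
#' `(1 + #\{permuted statistic >= observed\}) / (1 + n_permutations)`, which
#' can never return 0.
#'
#' @param g a [genotype_table()].
#' @param plan a [permutation_plan()].
#' @return List with `p` (empirical), `observed` statistic, `exceedances`,
#'   `n_permutations`, `statistic` and `seed`.
#' @export
empirical_p <- function(g, plan = permutation_plan()) {
  stopifnot(inherits(g, "genotype_table"), inherits(plan, "permutation_plan"))
  m <- unclass(g)
  if (any(rowSums(m) == 0) || sum(colSums(m) > 0) < 2L)
    stop("degenerate margins: need both rows and >= 2 genotype columns",
         call. = FALSE)
  obs <- genotype_statistic(m, plan$statistic)
  tables <- with_seed(plan$seed,
                      stats::r2dtable(plan$n_permutations, rowSums(m),
                                      colSums(m)))
  stats_perm <- vapply(tables, genotype_statistic, 0,
                       statistic = plan$statistic)
  b <- sum(stats_perm >= obs - 1e-12)
  list(p = (1 + b) / (1 + plan$n_permutations), observed = obs,
       exceedances = b, n_permutations = plan$n_permutations,
       statistic = plan$statistic, seed = plan$seed)
}

#' Bonferroni correction
#'
#' Adjusted p-values `min(1, m * p)` and significance flags at the
#' family-wise threshold `alpha / m`.
#'
#' @param p vector of p-values in [0, 1].
#' @param m number of comparisons (default `length(p)`); a warning is
#'   raised if `m < length(p)`.
#' @param alpha family-wise error rate (default 0.05).
#' @return List with `adjusted`, `significant`, `threshold` and `m`.
#' @examples
#' bonferroni_adjust(0.001, m = 24)  # adjusted 0.024, significant
#' @export
bonferroni_adjust <- function(p, m = length(p), alpha = 0.05) {
  check_probability(p, "p", open = FALSE)
  check_count(m, "m")
  check_probability(alpha, "alpha")
  if (m < length(p))
    warning("m is smaller than the number of p-values supplied")
  list(adjusted = pmin(1, m * p), significant = p < alpha / m,
       threshold = alpha / m, m = m)
}
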