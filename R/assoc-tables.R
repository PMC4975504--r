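#' Build a 2 x 3 case-control genotype count table
#'
#' The unit of single-SNP association analysis: genotype counts for cases and
#' controls at the three levels GG (major homozygote), AG (heterozygote) and
#' AA (minor homozygote).
#'
#' @param cases,controls numeric vectors of length 3 giving counts for
#'   GG, AG, AA (in that order), or named vectors with those names.
#' @param label optional study-set tag (e.g. "discovery").
#' @return An object of class `genotype_table`: a 2 x 3 integer matrix with
#'   rows `case`/`control` and columns `GG`/`AG`/`AA`.
#' @examples
#' genotype_table(cases = c(495, 558, 119), controls = c(526, 463, 97),
#'                label = "discovery")
#' @export
genotype_table <- function(cases, controls, label = NULL) {
  as3 <- function(x, what) {
    if (!is.null(names(x))) {
      if (!all(GENOTYPE_LEVELS %in% names(x)))
        stop(sprintf("`%s` must be named GG, AG, AA", what), call. = FALSE)
      x <- x[GENOTYPE_LEVELS]
    }
    if (length(x) != 3L || any(!is.finite(x)) || any(x < 0) ||
        any(x != floor(x)))
      stop(sprintf("`%s` must be 3 nonnegative integer counts (GG, AG, AA)",
                   what), call. = FALSE)
    as.integer(x)
  }
  m <- rbind(case = as3(cases, "cases"), control = as3(controls, "controls"))
  colnames(m) <- GENOTYPE_LEVELS
  if (any(rowSums(m) < 1))
    stop("each of cases and controls must contain at least one subject",
         call. = FALSE)
  structure(m, class = c("genotype_table", class(m)), label = label)
}

#' @export
print.genotype_table <- function(x, ...) {
  lab <- attr(x, "label")
  cat("Genotype count table", if (!is.null(lab)) paste0(" [", lab, "]"),
      "\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' Build a 2 x 2 exposed/reference case-control table
#'
#' @param case_exposed,case_reference,control_exposed,control_reference
#'   nonnegative integer counts.
#' @param label optional tag.
#' @return An object of class `two_by_two`: a 2 x 2 matrix with rows
#'   `case`/`control` and columns `exposed`/`reference`.
#' @export
two_by_two <- function(case_exposed, case_reference,
                       control_exposed, control_reference, label = NULL) {
  v <- c(case_exposed, case_reference, control_exposed, control_reference)
  if (length(v) != 4L || any(!is.finite(v)) || any(v < 0) ||
      any(v != floor(v)))
    stop("all four cells must be nonnegative integer counts", call. = FALSE)
  m <- matrix(as.integer(v), nrow = 2, byrow = TRUE,
              dimnames = list(c("case", "control"),
                              c("exposed", "reference")))
  structure(m, class = c("two_by_two", class(m)), label = label)
}

#' @export
print.two_by_two <- function(x, ...) {
  lab <- attr(x, "label")
  cat("2x2 case-control table", if (!is.null(lab)) paste0(" [", lab, "]"),
      "\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' Collapse a genotype table to an allele count table
#'
#' Counts minor (A) alleles as exposed and major (G) alleles as reference:
#' each AA subject contributes two A alleles, each heterozygote one of each.
#'
#' @param g a [genotype_table()].
#' @return A [two_by_two()] of allele counts (columns `exposed` = A,
#'   `reference` = G); totals are twice the subject counts.
#' @examples
#' g <- genotype_table(c(495, 558, 119), c(526, 463, 97))
#' allele_table(g)  # 796 A / 1548 G alleles in cases
#' @export
allele_table <- function(g) {
  stopifnot(inherits(g, "genotype_table"))
  two_by_two(2L * g["case", "AA"] + g["case", "AG"],
             2L * g["case", "GG"] + g["case", "AG"],
             2L * g["control", "AA"] + g["control", "AG"],
             2L * g["control", "GG"] + g["control", "AG"],
             label = attr(g, "label"))
}

#' Recode a genotype table under a dominant or recessive model
#'
#' Dominant: carriers of the minor allele (AG + AA) are exposed, GG is the
#' reference. Recessive: AA is exposed, AG + GG is the reference.
#'
#' @param g a [genotype_table()].
#' @param model `"dominant"` or `"recessive"`.
#' @return A [two_by_two()].
#' @export
recode_model <- function(g, model = c("dominant", "recessive")) {
  stopifnot(inherits(g, "genotype_table"))
  model <- match.arg(model)
  if (model == "dominant")
    two_by_two(g["case", "AG"] + g["case", "AA"], g["case", "GG"],
               g["control", "AG"] + g["control", "AA"], g["control", "GG"],
               label = attr(g, "label"))
  else
    two_by_two(g["case", "AA"], g["case", "AG"] + g["case", "GG"],
               g["control", "AA"], g["control", "AG"] + g["control", "GG"],
               label = attr(g, "label"))
}

#' Odds ratio with Woolf confidence interval and Wald p-value
#'
#' Cross-product odds ratio `ad/bc` with the Woolf (log-scale) confidence
#' interval `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` and a
#' two-sided Wald p-value from `z = log(OR)/SE`. When any cell is zero the
#' Haldane-Anscombe continuity correction adds 0.5 to every cell. The Pearson
#' chi-square p-value on the uncorrected table is reported alongside.
#'
#' @param t a [two_by_two()].
#' @param alpha confidence level complement (default 0.05 for a 95% CI).
#' @return An object of class `assoc_result` with elements `or`, `ci`
#'   (length-2), `p` (Wald), `p_pearson`, `method`, `corrected`.
#' @examples
#' odds_ratio(two_by_two(1595, 3039, 1469, 3339))  # OR 1.19, p 6.1e-5
#' @export
odds_ratio <- function(t, alpha = 0.05) {
  stopifnot(inherits(t, "two_by_two"))
  check_probability(alpha, "alpha")
  if (sum(t["case", ]) == 0 || sum(t["control", ]) == 0)
    stop("odds ratio undefined: a table row is empty", call. = FALSE)
  a <- t["case", "exposed"]; b <- t["case", "reference"]
  cc <- t["control", "exposed"]; d <- t["control", "reference"]
  corrected <- any(c(a, b, cc, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- stats::qnorm(1 - alpha / 2)
  ci <- exp(log(or) + c(-1, 1) * z * se)
  p <- 2 * stats::pnorm(-abs(log(or) / se))
  p_pearson <- tryCatch(
    suppressWarnings(stats::chisq.test(unclass(t), correct = FALSE)$p.value),
    error = function(e) NA_real_)
  structure(list(or = or, ci = ci, p = p, p_pearson = p_pearson,
                 se_log = se, method = "wald", model = attr(t, "label"),
                 corrected = corrected, alpha = alpha),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("OR %.3f (%.0f%% CI %.3f-%.3f), p = %.3g [%s]%s\n",
              x$or, 100 * (1 - x$alpha), x$ci[1], x$ci[2], x$p, x$method,
              if (isTRUE(x$corrected)) " (Haldane-Anscombe corrected)" else ""))
  invisible(x)
}

#' Per-allele (additive) trend odds ratio
#'
#' Fits a single-predictor logistic regression of case status on minor-allele
#' dosage (GG = 0, AG = 1, AA = 2) using the grouped genotype counts as
#' frequency weights, and reports the per-allele odds ratio with Wald CI/p.
#'
#' @param g a [genotype_table()].
#' @param alpha CI level complement.
#' @return An `assoc_result` with `method = "trend"`.
#' @export
additive_trend <- function(g, alpha = 0.05) {
  stopifnot(inherits(g, "genotype_table"))
  check_probability(alpha, "alpha")
  present <- colSums(g) > 0
  if (sum(present) < 2L)
    stop("additive trend undefined: only one genotype present", call. = FALSE)
  d <- data.frame(y = rep(c(1, 0), each = 3), dose = rep(0:2, 2),
                  n = c(g["case", ], g["control", ]))
  d <- d[d$n > 0, ]
  fit <- fit_logistic(d, model_spec("y", "dose", weights = "n"))
  b <- unname(fit$coefficients["dose"])
  se <- unname(sqrt(fit$covariance["dose", "dose"]))
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(or = exp(b), ci = exp(b + c(-1, 1) * z * se),
                 p = 2 * stats::pnorm(-abs(b / se)), p_pearson = NA_real_,
                 se_log = se, method = "trend", model = "additive",
                 corrected = FALSE, alpha = alpha),
            class = "assoc_result")
}

#' Pearson chi-square test of Hardy-Weinberg equilibrium
#'
#' Compares observed genotype counts with the proportions `p^2`, `2pq`, `q^2`
#' implied by the sample allele frequency (1 df).
#'
#' @param counts length-3 vector of genotype counts (GG, AG, AA).
#' @return A list with `chisq`, `df` (1), `p`, and the minor-allele
#'   frequency `maf` used for the expected counts.
#' @examples
#' hwe_test(c(526, 463, 97))  # p = 0.734
#' @export
hwe_test <- function(counts) {
  if (length(counts) != 3L || any(!is.finite(counts)) || any(counts < 0))
    stop("`counts` must be 3 nonnegative genotype counts (GG, AG, AA)",
         call. = FALSE)
  n <- sum(counts)
  if (n < 1) stop("total genotype count must be >= 1", call. = FALSE)
  q <- (2 * counts[3] + counts[2]) / (2 * n)
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  keep <- expected > 0
  chisq <- sum((counts[keep] - expected[keep])^2 / expected[keep])
  list(chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       maf = unname(q))
}

#' Minor allele frequency in one study group
#'
#' @param g a [genotype_table()] or allele-level [two_by_two()].
#' @param group `"case"` or `"control"`.
#' @return Frequency of the minor (A) allele among all alleles in the group.
#' @export
minor_allele_frequency <- function(g, group = c("control", "case")) {
  group <- match.arg(group)
  if (inherits(g, "genotype_table")) g <- allele_table(g)
  stopifnot(inherits(g, "two_by_two"))
  tot <- sum(g[group, ])
  if (tot == 0) stop(sprintf("no alleles in %s group", group), call. = FALSE)
  unname(g[group, "exposed"] / tot)
}

#' Breslow-Day test of homogeneity of odds ratios across strata
#'
#' Tests whether stratum-specific odds ratios are compatible with the
#' Mantel-Haenszel common odds ratio, with Tarone's correction by default.
#'
#' @param strata list of [two_by_two()] tables (at least two).
#' @param tarone apply Tarone's correction (default `TRUE`).
#' @return List with `chisq`, `df` (strata - 1), `p`, and `or_mh`.
#' @examples
#' d <- two_by_two(796, 1548, 657, 1515)   # discovery alleles
#' r <- two_by_two(799, 1491, 812, 1824)   # replication alleles
#' breslow_day(list(d, r))                 # p = 0.864
#' @export
breslow_day <- function(strata, tarone = TRUE) {
  if (!is.list(strata) || length(strata) < 2L ||
      !all(vapply(strata, inherits, logical(1), "two_by_two")))
    stop("`strata` must be a list of >= 2 two_by_two tables", call. = FALSE)
  for (t in strata)
    if (any(rowSums(t) == 0))
      stop("each stratum must have cases and controls", call. = FALSE)
  R <- sum(vapply(strata, function(t)
    t["case", "exposed"] * t["control", "reference"] / sum(t), 0))
  S <- sum(vapply(strata, function(t)
    t["case", "reference"] * t["control", "exposed"] / sum(t), 0))
  or_mh <- R / S
  stat <- 0; resid_sum <- 0; var_sum <- 0
  for (t in strata) {
    a <- t["case", "exposed"]
    n1 <- sum(t["case", ]); n0 <- sum(t["control", ])
    m1 <- sum(t[, "exposed"])
    # expected a under the common OR: a(n0 - m1 + a) = OR (m1 - a)(n1 - a)
    A <- 1 - or_mh
    B <- (n0 - m1) + or_mh * (m1 + n1)
    C <- -or_mh * m1 * n1
    if (abs(A) < 1e-12) {
      ea <- -C / B
    } else {
      disc <- sqrt(B^2 - 4 * A * C)
      roots <- c((-B + disc) / (2 * A), (-B - disc) / (2 * A))
      ok <- roots > max(0, m1 - n0) & roots < min(m1, n1)
      ea <- roots[ok][1]
    }
    va <- 1 / (1 / ea + 1 / (n1 - ea) + 1 / (m1 - ea) + 1 / (n0 - m1 + ea))
    stat <- stat + (a - ea)^2 / va
    resid_sum <- resid_sum + (a - ea)
    var_sum <- var_sum + va
  }
  if (tarone) stat <- stat - resid_sum^2 / var_sum
  df <- length(strata) - 1L
  list(chisq = max(0, stat), df = df,
       p = stats::pchisq(max(0, stat), df = df, lower.tail = FALSE),
       or_mh = or_mh, tarone = tarone)
}

#' Pool genotype tables across study stages by summing counts
#'
#' The merged two-stage table is the element-wise sum of the stage tables
#' (commutative and associative).
#'
#' @param strata list of [genotype_table()] (or [two_by_two()]) objects.
#' @param label tag for the pooled table.
#' @return A table of the same class as the inputs.
#' @export
pool_strata <- function(strata, label = "merged") {
  if (!is.list(strata) || length(strata) < 1L)
    stop("`strata` must be a nonempty list of tables", call. = FALSE)
  cls <- if (inherits(strata[[1]], "genotype_table")) "genotype_table"
         else "two_by_two"
  if (!all(vapply(strata, inherits, logical(1), cls)))
    stop("all tables must share the same class", call. = FALSE)
  m <- Reduce(`+`, lapply(strata, unclass))
  if (cls == "genotype_table")
    genotype_table(m["case", ], m["control", ], label = label)
  else
    two_by_two(m["case", "exposed"], m["case", "reference"],
               m["control", "exposed"], m["control", "reference"],
               label = label)
}

#' Inverse-variance fixed-effect pooled odds ratio
#'
#' A clearly-labeled alternative combiner: weights stratum log odds ratios by
#' inverse Woolf variances. The primary merged analysis in this package pools
#' raw counts instead (see [pool_strata()]).
#'
#' @param results list of `assoc_result` objects from [odds_ratio()].
#' @param alpha CI level complement.
#' @return An `assoc_result` with `method = "inverse_variance"`.
#' @export
pool_inverse_variance <- function(results, alpha = 0.05) {
  stopifnot(all(vapply(results, inherits, logical(1), "assoc_result")))
  w <- vapply(results, function(r) 1 / r$se_log^2, 0)
  b <- sum(w * vapply(results, function(r) log(r$or), 0)) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(or = exp(b), ci = exp(b + c(-1, 1) * z * se),
                 p = 2 * stats::pnorm(-abs(b / se)), p_pearson = NA_real_,
                 se_log = se, method = "inverse_variance", model = NULL,
                 corrected = FALSE, alpha = alpha),
            class = "assoc_result")
}

#' Power of the two-sided two-sample proportion z-test
#'
#' Classic normal-approximation power without continuity correction:
#' `power = pnorm((|p1 - p2| - z * SE0) / SE1)` where `SE0` uses the pooled
#' proportion under the null and `SE1` the two proportions under the
#' alternative. `n1`, `n2` count subjects per group.
#'
#' @param p1,p2 the two proportions (e.g. case and control minor-allele
#'   frequencies), in (0, 1).
#' @param n1,n2 per-group sample sizes (>= 2).
#' @param alpha two-sided type-I error (default 0.05).
#' @return Power in (0, 1).
#' @examples
#' power_two_proportions(0.3442, 0.3055, 2317, 2404)  # 0.810
#' @export
power_two_proportions <- function(p1, p2, n1, n2, alpha = 0.05) {
  check_probability(c(p1, p2), "p1/p2")
  check_count(n1, "n1", min = 2L); check_count(n2, "n2", min = 2L)
  check_probability(alpha, "alpha")
  pbar <- (p1 * n1 + p2 * n2) / (n1 + n2)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  se1 <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm((abs(p1 - p2) - z * se0) / se1)
}
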