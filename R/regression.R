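#' Specify a logistic or linear model by column names
#'
#' @param response name of the binary response column.
#' @param terms character vector of main-effect columns.
#' @param interactions list of length-2 character vectors; both members must
#'   also appear in `terms`.
#' @param weights optional name of a frequency-weight column, so grouped
#'   count data reproduce individual-level fits.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response, terms, interactions = list(),
                       weights = NULL) {
  stopifnot(is.character(response), length(response) == 1L,
            is.character(terms), length(terms) >= 1L)
  if (anyDuplicated(terms))
    stop("duplicate terms in model spec", call. = FALSE)
  if (length(interactions)) {
    if (!is.list(interactions))
      interactions <- list(interactions)
    for (pair in interactions) {
      if (length(pair) != 2L)
        stop("each interaction must name exactly two columns", call. = FALSE)
      if (!all(pair %in% terms))
        stop(sprintf("interaction members %s must appear as main effects",
                     paste(pair, collapse = ":")), call. = FALSE)
    }
  }
  structure(list(response = response, terms = terms,
                 interactions = interactions, weights = weights),
            class = "model_spec")
}

spec_formula <- function(spec) {
  rhs <- c(spec$terms,
           vapply(spec$interactions, paste, "", collapse = ":"))
  stats::as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")),
                    env = baseenv())
}

#' Fit a logistic regression model
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' (convergence tolerance 1e-8, at most 100 iterations), with frequency
#' weights supported so grouped count data reproduce closed-form odds
#' ratios. Perfect separation and rank deficiency are reported as errors
#' rather than silently returning unstable estimates.
#'
#' @param data a data frame (individual records, or grouped cells with a
#'   count column named by `spec$weights`).
#' @param spec a [model_spec()].
#' @return An object of class `logistic_fit` with elements `coefficients`
#'   (log-odds scale), `covariance`, `loglik`, `n_iter`, `converged`,
#'   `formula` and the underlying `glm` object.
#' @examples
#' d <- data.frame(y = c(1, 1, 0, 0), g = c(1, 0, 1, 0),
#'                 n = c(1341, 976, 1246, 1158))
#' exp(coef(fit_logistic(d, model_spec("y", "g", weights = "n"))))["g"]
#' @export
fit_logistic <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"), is.data.frame(data))
  needed <- setdiff(c(spec$response, spec$terms, spec$weights), "1")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  y <- data[[spec$response]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1)))
    stop("response must be binary (0/1, logical, or a two-level factor)",
         call. = FALSE)
  data[[spec$response]] <- y
  data$.freq_w <- if (is.null(spec$weights)) rep(1, nrow(data))
                  else data[[spec$weights]]
  fit <- suppressWarnings(stats::glm(
    spec_formula(spec), family = stats::binomial(), data = data,
    weights = .freq_w,
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design: collinear terms ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  if ((length(cf) > 1L && max(abs(cf[-1])) > 15) || !fit$converged)
    stop("fit did not converge (|beta| > 15 suggests perfect separation); ",
         "largest coefficient: ",
         names(which.max(abs(cf[-1])))[1], call. = FALSE)
  structure(list(coefficients = cf, covariance = stats::vcov(fit),
                 loglik = as.numeric(stats::logLik(fit)),
                 n_iter = fit$iter, converged = fit$converged,
                 formula = spec_formula(spec), spec = spec, glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit:", deparse(x$formula), "\n")
  se <- sqrt(diag(x$covariance))
  out <- data.frame(beta = x$coefficients, or = exp(x$coefficients), se = se,
                    p = 2 * stats::pnorm(-abs(x$coefficients / se)))
  print(round(out, 4))
  cat(sprintf("logLik %.3f, %d IRLS iterations\n", x$loglik, x$n_iter))
  invisible(x)
}

#' Likelihood-ratio test between nested logistic fits
#'
#' @param full,reduced `logistic_fit` objects; the reduced model's terms must
#'   be a subset of the full model's.
#' @return List with `chisq = 2 * (loglik_full - loglik_reduced)`, `df`
#'   (parameter difference) and `p`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "logistic_fit"), inherits(reduced, "logistic_fit"))
  full_terms <- attr(stats::terms(full$formula), "term.labels")
  red_terms <- attr(stats::terms(reduced$formula), "term.labels")
  norm_term <- function(t) paste(sort(strsplit(t, ":")[[1]]), collapse = ":")
  if (!all(vapply(red_terms, norm_term, "") %in%
           vapply(full_terms, norm_term, "")))
    stop("`reduced` is not nested in `full`", call. = FALSE)
  df <- length(full$coefficients) - length(reduced$coefficients)
  if (df < 0) stop("`reduced` has more parameters than `full`", call. = FALSE)
  chisq <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0) 1 else stats::pchisq(chisq, df = df, lower.tail = FALSE)
  list(chisq = chisq, df = df, p = p)
}

#' Multiplicative gene-environment interaction test
#'
#' Fits `outcome ~ G + E (+ covariates)` against the same model plus the
#' `G x E` product term and reports the likelihood-ratio p-value together
#' with the interaction odds ratio `exp(beta_GE)` and its Wald CI.
#'
#' @param data data frame (individual records or grouped counts).
#' @param g name of the (coded) genotype column.
#' @param e name of the binary environment column.
#' @param covariates additional adjustment columns.
#' @param response name of the binary outcome column (default
#'   `"status_case"`, the coding written by the cohort generator).
#' @param weights optional frequency-weight column for grouped data.
#' @param alpha CI level complement.
#' @return An object of class `interaction_test` with `p` (LRT), `chisq`,
#'   `df`, `or_interaction`, `ci`, `p_wald` and both fits.
#' @export
interaction_test <- function(data, g, e, covariates = character(),
                             response = "status_case", weights = NULL,
                             alpha = 0.05) {
  missing_cols <- setdiff(c(response, g, e, covariates), names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  w <- if (is.null(weights)) rep(1, nrow(data)) else data[[weights]]
  cells <- table(g = data[[g]][w > 0], e = data[[e]][w > 0])
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)
    stop("degenerate stratum cell(s): ",
         paste(sprintf("g=%s,e=%s", rownames(cells)[idx[, 1]],
                       colnames(cells)[idx[, 2]]), collapse = "; "),
         call. = FALSE)
  }
  terms <- c(g, e, covariates)
  full <- fit_logistic(data, model_spec(response, terms,
                                        interactions = list(c(g, e)),
                                        weights = weights))
  reduced <- fit_logistic(data, model_spec(response, terms,
                                           weights = weights))
  lrt <- likelihood_ratio_test(full, reduced)
  int_name <- grep(":", names(full$coefficients), value = TRUE)[1]
  b <- full$coefficients[int_name]
  se <- sqrt(full$covariance[int_name, int_name])
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(p = lrt$p, chisq = lrt$chisq, df = lrt$df,
                 or_interaction = unname(exp(b)),
                 ci = unname(exp(b + c(-1, 1) * z * se)),
                 p_wald = unname(2 * stats::pnorm(-abs(b / se))),
                 full = full, reduced = reduced),
            class = "interaction_test")
}

#' @export
print.interaction_test <- function(x, ...) {
  cat(sprintf(
    "GxE multiplicative interaction: OR %.3f (%.3f-%.3f), LRT p = %.4g\n",
    x$or_interaction, x$ci[1], x$ci[2], x$p))
  invisible(x)
}

#' Grouped data frame from exposure-stratified 2 x 2 tables
#'
#' Converts a pair of carrier-recoded [two_by_two()] tables (one per level
#' of a binary environmental factor) into the eight-cell grouped data frame
#' expected by [interaction_test()], with columns `status_case`, `g`, `e`
#' and frequency weight `n`.
#'
#' @param exposed 2 x 2 table for the exposed stratum (e.g. with T2DM).
#' @param unexposed 2 x 2 table for the unexposed stratum.
#' @return An 8-row data frame.
#' @examples
#' yes <- two_by_two(487, 263, 325, 289)  # carriers/GG with T2DM
#' no  <- two_by_two(854, 713, 921, 869)  # carriers/GG without T2DM
#' interaction_test(ge_strata_data(yes, no), "g", "e", weights = "n")
#' @export
ge_strata_data <- function(exposed, unexposed) {
  stopifnot(inherits(exposed, "two_by_two"), inherits(unexposed, "two_by_two"))
  grid <- expand.grid(status_case = c(1L, 0L), g = c(1L, 0L), e = c(1L, 0L))
  pick <- function(t, case, exp_) {
    t[if (case) "case" else "control", if (exp_) "exposed" else "reference"]
  }
  grid$n <- mapply(function(y, g, e)
    pick(if (e) exposed else unexposed, y, g),
    grid$status_case, grid$g, grid$e)
  grid
}

#' ANCOVA comparison of group means adjusted for covariates
#'
#' Ordinary least-squares linear model `outcome ~ group + covariates`; the
#' group effect is tested by the partial F comparing models with and without
#' the group factor, and adjusted means are evaluated at the grand covariate
#' means (the classic ANCOVA convention).
#'
#' @param data data frame.
#' @param outcome numeric outcome column name.
#' @param group grouping column (coerced to factor, >= 2 levels).
#' @param covariates covariate column names.
#' @return List with `adjusted_means` (named by group level), `p` (partial
#'   F), `f`, `df`, and the full `lm` fit.
#' @export
ancova_compare <- function(data, outcome, group, covariates = character()) {
  stopifnot(is.data.frame(data))
  y <- data[[outcome]]
  if (!is.numeric(y)) stop("`outcome` must be numeric", call. = FALSE)
  if (stats::var(y) == 0) stop("constant outcome", call. = FALSE)
  data[[group]] <- factor(data[[group]])
  if (nlevels(data[[group]]) < 2L)
    stop("`group` must have at least two levels", call. = FALSE)
  rhs_full <- paste(c(group, covariates), collapse = " + ")
  full <- stats::lm(stats::as.formula(paste(outcome, "~", rhs_full)),
                    data = data)
  rhs_red <- if (length(covariates)) paste(covariates, collapse = " + ")
             else "1"
  reduced <- stats::lm(stats::as.formula(paste(outcome, "~", rhs_red)),
                       data = data)
  an <- stats::anova(reduced, full)
  newdata <- data.frame(lvl = levels(data[[group]]))
  names(newdata) <- group
  for (cv in covariates) {
    v <- data[[cv]]
    newdata[[cv]] <- if (is.numeric(v)) mean(v) else {
      # most frequent level, a fixed reference for categorical covariates
      names(sort(table(v), decreasing = TRUE))[1]
    }
  }
  adj <- stats::predict(full, newdata = newdata)
  names(adj) <- levels(data[[group]])
  list(adjusted_means = adj, p = an[["Pr(>F)"]][2], f = an$F[2],
       df = c(an$Df[2], an$Res.Df[2]), fit = full)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison. Uses exact enumeration when both samples
#' are small (`n_x * n_y <= 400`) and no ties are present; otherwise the
#' normal approximation with continuity and tie correction.
#'
#' @param x,y numeric vectors (nonempty).
#' @return List with `u` (U statistic for `x`), `p`, and `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y))
    stop("both samples must be nonempty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) * length(y) <= 400
  wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                           correct = TRUE)
  list(u = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal_approximation")
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and the asymptotic
#' t-approximation p-value.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with `rho` and `p`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
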