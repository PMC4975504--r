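test_that("grouped logistic fit reproduces the published dominant OR", {
  d <- data.frame(y = c(1, 1, 0, 0), g = c(1, 0, 1, 0),
                  n = c(1341, 976, 1246, 1158))
  fit <- fit_logistic(d, model_spec("y", "g", weights = "n"))
  expect_equal(unname(exp(fit$coefficients["g"])), 1.28, tolerance = 0.005)
  se <- sqrt(fit$covariance["g", "g"])
  p <- 2 * pnorm(-abs(fit$coefficients["g"] / se))
  expect_equal(unname(p), 3.04e-5, tolerance = 0.02)
})

test_that("grouped 2x2 fits equal the closed-form odds ratio", {
  set.seed(5)
  for (i in 1:10) {
    cells <- sample(5:80, 4)
    t <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    d <- data.frame(y = c(1, 1, 0, 0), g = c(1, 0, 1, 0), n = cells)
    fit <- fit_logistic(d, model_spec("y", "g", weights = "n"))
    expect_equal(unname(exp(fit$coefficients["g"])), odds_ratio(t)$or,
                 tolerance = 1e-6)
  }
})

test_that("grouped and expanded individual-level fits coincide", {
  d <- grouped_ge(263, 487, 289, 325, 713, 854, 869, 921)
  fit_g <- fit_logistic(d, model_spec("status_case", c("g", "e"),
                                      interactions = list(c("g", "e")),
                                      weights = "n"))
  fit_i <- fit_logistic(expand_grouped(d),
                        model_spec("status_case", c("g", "e"),
                                   interactions = list(c("g", "e"))))
  expect_equal(fit_g$coefficients, fit_i$coefficients, tolerance = 1e-6)
  expect_equal(fit_g$loglik, fit_i$loglik, tolerance = 1e-6)
})

test_that("intercept-only fit on a balanced outcome gives log-odds zero", {
  d <- data.frame(y = rep(c(1, 0), 25))
  fit <- fit_logistic(d, model_spec("y", "1"))
  expect_equal(unname(fit$coefficients[1]), 0, tolerance = 1e-8)
})

test_that("separation and rank deficiency are reported, not returned", {
  d <- data.frame(y = rep(c(1, 0), each = 20),
                  x = rep(c(1, 0), each = 20))
  expect_error(fit_logistic(d, model_spec("y", "x")), "separation")
  d2 <- data.frame(y = rep(c(1, 0), 20), a = rnorm(40))
  d2$b <- d2$a * 2
  expect_error(fit_logistic(d2, model_spec("y", c("a", "b"))), "collinear")
})

test_that("likelihood-ratio test behaves on nested fits", {
  d <- grouped_ge(263, 487, 289, 325, 713, 854, 869, 921)
  full <- fit_logistic(d, model_spec("status_case", c("g", "e"),
                                     interactions = list(c("g", "e")),
                                     weights = "n"))
  reduced <- fit_logistic(d, model_spec("status_case", c("g", "e"),
                                        weights = "n"))
  lrt <- likelihood_ratio_test(full, reduced)
  expect_equal(lrt$df, 1)
  expect_gte(lrt$chisq, 0)
  # identical models: chi-square 0, p 1
  self <- likelihood_ratio_test(full, full)
  expect_equal(self$chisq, 0, tolerance = 1e-10)
  expect_equal(self$p, 1)
  # non-nested pair is refused
  other <- fit_logistic(d, model_spec("status_case", "g", weights = "n"))
  expect_error(likelihood_ratio_test(other, reduced), "nested")
})

test_that("interaction LRT reproduces the published subgroup p-values", {
  t2dm <- interaction_test(grouped_ge(263, 487, 289, 325,
                                      713, 854, 869, 921),
                           "g", "e", weights = "n")
  expect_equal(round(t2dm$p, 3), 0.004)
  hyper <- interaction_test(grouped_ge(238, 443, 266, 283,
                                       738, 898, 892, 963),
                            "g", "e", weights = "n")
  expect_equal(round(hyper$p, 3), 0.001)
  bmi <- interaction_test(grouped_ge(444, 673, 456, 455,
                                     532, 668, 702, 791),
                          "g", "e", weights = "n")
  expect_equal(round(bmi$p, 3), 0.009)
  # the interaction OR matches the stratified OR ratio
  expect_equal(t2dm$or_interaction, (487 / 263 * 289 / 325) /
                 (854 / 713 * 869 / 921), tolerance = 1e-6)
})

test_that("LRT and Wald interaction p-values agree across all subgroups", {
  for (s in rs2107595_subgroup_tables()) {
    it <- interaction_test(ge_strata_data(s$exposed, s$unexposed),
                           "g", "e", weights = "n")
    expect_equal(it$p, it$p_wald, tolerance = 0.25)
  }
})

test_that("degenerate stratum cells are named in the error", {
  d <- grouped_ge(10, 20, 15, 12, 30, 25, 20, 18)
  d$n[d$g == 1 & d$e == 1] <- 0
  expect_error(interaction_test(d, "g", "e", weights = "n"), "degenerate")
})

test_that("ANCOVA reduces to the t-test and recovers adjusted offsets", {
  set.seed(11)
  d <- data.frame(y = c(rnorm(40, 1.20, 0.4), rnorm(40, 1.06, 0.4)),
                  grp = rep(c("case", "control"), each = 40),
                  age = rnorm(80, 60, 9))
  plain <- ancova_compare(d, "y", "grp")
  tt <- t.test(y ~ grp, data = d, var.equal = TRUE)
  expect_equal(plain$p, tt$p.value, tolerance = 1e-10)
  # identical groups: adjusted difference zero
  d2 <- rbind(d, d)
  d2$grp <- rep(c("a", "b"), each = 80)
  d2$y <- rep(d$y, 2)
  eq <- ancova_compare(d2, "y", "grp", covariates = "age")
  expect_equal(unname(diff(eq$adjusted_means)), 0, tolerance = 1e-10)
  expect_error(ancova_compare(transform(d, y = 1), "y", "grp"), "constant")
})

test_that("ANCOVA recovers a known group offset net of a covariate", {
  # offset 0.14 on the scale of the expression contrast 1.20 vs 1.06
  set.seed(19)
  hits <- 0
  for (i in 1:20) {
    n <- 120
    age <- rnorm(2 * n, 60, 9)
    grp <- rep(c(1, 0), each = n)
    y <- 1.06 + 0.14 * grp + 0.01 * (age - 60) + rnorm(2 * n, 0, 0.40)
    d <- data.frame(y = y, grp = factor(grp), age = age)
    fit <- ancova_compare(d, "y", "grp", covariates = "age")
    est <- unname(fit$adjusted_means["1"] - fit$adjusted_means["0"])
    se_est <- sqrt(sum(diag(vcov(fit$fit))[2]))
    if (abs(est - 0.14) <= qnorm(0.975) * se_est) hits <- hits + 1
  }
  expect_gte(hits, 17)  # ~95% CI coverage over 20 replicates
})

test_that("Mann-Whitney matches exact enumeration and a permutation oracle", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p, 0.1)  # 2/choose(6,3): both extreme arrangements
  expect_equal(r$method, "exact")
  # identical samples sit at the null center
  same <- mann_whitney(1:10, 1:10)
  expect_gt(same$p, 0.9)
  # tie-heavy vectors against a brute-force label permutation
  set.seed(23)
  x <- c(1, 1, 2, 2, 3, 5, 5)
  y <- c(2, 3, 3, 4, 4, 4, 6, 6)
  obs <- mann_whitney(x, y)
  pooled <- c(x, y)
  nx <- length(x)
  ranks <- rank(pooled)
  obs_u <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  null_dev <- replicate(20000, {
    idx <- sample(length(pooled), nx)
    abs(sum(rank(pooled)[idx]) - nx * (nx + 1) / 2 -
          nx * (length(y)) / 2)
  })
  p_perm <- mean(null_dev >= abs(obs_u - nx * length(y) / 2) - 1e-9)
  expect_equal(obs$p, p_perm, tolerance = 0.05)
  expect_error(mann_whitney(numeric(), 1:3), "nonempty")
})

test_that("Spearman correlation is a rank correlation with tie handling", {
  expect_equal(spearman_test(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_test(1:10, -(1:10))$rho, -1)
  # tied example against the direct Pearson-on-average-ranks formula
  x <- c(1, 2, 2, 4, 5, 6)
  y <- c(2, 1, 4, 4, 6, 5)
  expect_equal(spearman_test(x, y)$rho,
               cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
})
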