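# Synthetic case-control cohort generator.
#
# Cases and controls are sampled retrospectively from a large simulated
# source population in which disease risk follows a logistic model, so the
# embedded effect sizes keep their odds-ratio interpretation.

#' Configuration for the synthetic cohort generator
#'
#' Defaults embed the study conditions the package's analyses expect: a
#' single SNP with control minor-allele frequency 0.306 in Hardy-Weinberg
#' proportions, a dominant genotype odds ratio of 1.28, binary risk-factor
#' covariates at realistic prevalences, an age/sex-matched design (their
#' ORs are 1), and right-skewed severity scores with median near 30.
#'
#' @param n_cases,n_controls numbers of cases and controls to sample.
#' @param maf minor-allele frequency in the source population, in (0, 1).
#' @param model genetic model coding the risk genotype: `"dominant"`
#'   (AG + AA), `"additive"` (allele dosage) or `"recessive"` (AA).
#' @param genotype_or odds ratio per unit of the coded genotype.
#' @param covariate_prevalences named probabilities for the binary
#'   covariates `smoking`, `drinking`, `t2dm`, `hyperlipidemia`,
#'   `hypertension`.
#' @param covariate_ors named odds ratios for the same covariates plus
#'   optionally `bmi` (the BMI > 25 indicator).
#' @param interaction_ors named odds ratios applied to the product of the
#'   coded genotype with a covariate (accepted names as in
#'   `covariate_ors`); empty means purely multiplicative main effects.
#' @param baseline_prevalence disease probability at reference levels.
#' @param age_mean,age_sd,bmi_mean,bmi_sd,p_male continuous covariate
#'   parameters (years, kg/m2).
#' @param gensini_log_mean,gensini_log_sd log-normal parameters of the
#'   severity score attached to cases.
#' @param gensini_genotype_shift multiplicative score shift for carriers of
#'   the risk genotype.
#' @param occlusion_rate fraction of simulated lesions flagged as acute
#'   total occlusions.
#' @param population_factor source population size as a multiple of
#'   `n_cases + n_controls` (doubled automatically when a draw yields too
#'   few cases).
#' @param seed integer seed; fixed seed gives a bit-identical cohort.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 2317, n_controls = 2404,
                          maf = 0.306,
                          model = c("dominant", "additive", "recessive"),
                          genotype_or = 1.28,
                          covariate_prevalences = c(
                            smoking = 0.30, drinking = 0.26, t2dm = 0.25,
                            hyperlipidemia = 0.23, hypertension = 0.40),
                          covariate_ors = c(
                            smoking = 1.6, drinking = 1.2, t2dm = 1.8,
                            hyperlipidemia = 1.7, hypertension = 1.9,
                            bmi = 1.4),
                          interaction_ors = numeric(),
                          baseline_prevalence = 0.08,
                          age_mean = 60, age_sd = 9,
                          bmi_mean = 24.6, bmi_sd = 3.1,
                          p_male = 0.55,
                          gensini_log_mean = log(28),
                          gensini_log_sd = 0.85,
                          gensini_genotype_shift = 1.18,
                          occlusion_rate = 0.05,
                          population_factor = 20,
                          seed = NULL) {
  model <- match.arg(model)
  check_count(n_cases, "n_cases"); check_count(n_controls, "n_controls")
  check_probability(maf, "maf")
  check_positive(genotype_or, "genotype_or")
  check_probability(baseline_prevalence, "baseline_prevalence")
  check_probability(covariate_prevalences, "covariate_prevalences")
  check_positive(covariate_ors, "covariate_ors")
  if (length(interaction_ors)) check_positive(interaction_ors,
                                              "interaction_ors")
  check_probability(occlusion_rate, "occlusion_rate", open = FALSE)
  check_positive(c(age_sd, bmi_sd, gensini_log_sd, gensini_genotype_shift,
                   population_factor), "scale parameters")
  known <- c("smoking", "drinking", "t2dm", "hyperlipidemia",
             "hypertension", "bmi")
  bad <- setdiff(c(names(covariate_ors), names(interaction_ors),
                   names(covariate_prevalences)), known)
  if (length(bad))
    stop("unknown covariate name(s): ", paste(bad, collapse = ", "),
         "; accepted: ", paste(known, collapse = ", "), call. = FALSE)
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    maf = maf, model = model, genotype_or = genotype_or,
    covariate_prevalences = covariate_prevalences,
    covariate_ors = covariate_ors, interaction_ors = interaction_ors,
    baseline_prevalence = baseline_prevalence,
    age_mean = age_mean, age_sd = age_sd,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd, p_male = p_male,
    gensini_log_mean = gensini_log_mean, gensini_log_sd = gensini_log_sd,
    gensini_genotype_shift = gensini_genotype_shift,
    occlusion_rate = occlusion_rate,
    population_factor = population_factor, seed = seed),
    class = "cohort_config")
}

#' Simulate genotypes in Hardy-Weinberg proportions
#'
#' Draws GG/AG/AA genotypes i.i.d. with probabilities `(1-q)^2`, `2q(1-q)`,
#' `q^2` for minor-allele frequency `q`.
#'
#' @param n number of subjects.
#' @param maf minor-allele frequency in (0, 1).
#' @param seed optional integer seed (reproducible draws; the caller's RNG
#'   state is untouched).
#' @return Factor with levels GG, AG, AA.
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  check_count(n, "n")
  check_probability(maf, "maf")
  probs <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  with_seed(seed,
    factor(sample(GENOTYPE_LEVELS, n, replace = TRUE, prob = probs),
           levels = GENOTYPE_LEVELS))
}

genotype_risk_coding <- function(genotype, model) {
  dose <- as.integer(genotype) - 1L  # GG=0, AG=1, AA=2
  switch(model,
         dominant = as.integer(dose >= 1L),
         additive = dose,
         recessive = as.integer(dose == 2L))
}

simulate_population <- function(config, n_pop) {
  g <- simulate_genotypes(n_pop, config$maf)
  gc <- genotype_risk_coding(g, config$model)
  prev <- config$covariate_prevalences
  cov <- list(
    smoking = stats::rbinom(n_pop, 1, prev[["smoking"]]),
    drinking = stats::rbinom(n_pop, 1, prev[["drinking"]]),
    t2dm = stats::rbinom(n_pop, 1, prev[["t2dm"]]),
    hyperlipidemia = stats::rbinom(n_pop, 1, prev[["hyperlipidemia"]]),
    hypertension = stats::rbinom(n_pop, 1, prev[["hypertension"]]))
  age <- stats::rnorm(n_pop, config$age_mean, config$age_sd)
  bmi <- stats::rnorm(n_pop, config$bmi_mean, config$bmi_sd)
  sex <- ifelse(stats::rbinom(n_pop, 1, config$p_male) == 1,
                "male", "female")
  exposure <- function(nm) if (nm == "bmi") as.integer(bmi > 25) else cov[[nm]]
  eta <- stats::qlogis(config$baseline_prevalence) +
    log(config$genotype_or) * gc
  for (nm in names(config$covariate_ors))
    eta <- eta + log(config$covariate_ors[[nm]]) * exposure(nm)
  for (nm in names(config$interaction_ors))
    eta <- eta + log(config$interaction_ors[[nm]]) * gc * exposure(nm)
  y <- stats::rbinom(n_pop, 1, stats::plogis(eta))
  data.frame(genotype = g, g_coded = gc, age = age, sex = sex, bmi = bmi,
             smoking = cov$smoking, drinking = cov$drinking,
             t2dm = cov$t2dm, hyperlipidemia = cov$hyperlipidemia,
             hypertension = cov$hypertension, y = y)
}

#' Simulate a retrospective case-control cohort
#'
#' Simulates a large source population (at least `population_factor` times
#' the requested cohort; doubled automatically, up to three times, if a
#' draw yields too few cases or controls), assigns disease status from the
#' logistic model `logit(p) = b0 + bG*g + sum(bE*e) + sum(bGE*g*e)` with
#' `b = log(OR)` and `g` the genotype coded under `config$model`, then
#' samples `n_cases` cases and `n_controls` controls without replacement.
#' Cases get a modified-Gensini-scale severity score from a log-normal
#' distribution, shifted multiplicatively for risk-genotype carriers.
#'
#' @param config a [cohort_config()].
#' @return Data frame (one row per subject) with columns `subject_id`,
#'   `status` (factor control/case), `status_case` (0/1), `genotype`,
#'   `g_dominant`, `age`, `sex`, `bmi`, `bmi_over25`, `smoking`,
#'   `drinking`, `t2dm`, `hyperlipidemia`, `hypertension` and `gensini`
#'   (NA for controls). The config and seed are attached as attributes.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    total <- config$n_cases + config$n_controls
    factor_now <- config$population_factor
    pop <- NULL
    for (attempt in 1:4) {
      pop <- simulate_population(config, ceiling(factor_now * total))
      if (sum(pop$y == 1) >= config$n_cases &&
          sum(pop$y == 0) >= config$n_controls) break
      pop <- NULL
      factor_now <- factor_now * 2
    }
    if (is.null(pop))
      stop("could not sample enough cases/controls; increase ",
           "`population_factor` or `baseline_prevalence`", call. = FALSE)
    idx <- c(sample(which(pop$y == 1), config$n_cases),
             sample(which(pop$y == 0), config$n_controls))
    cohort <- pop[idx, , drop = FALSE]
    rownames(cohort) <- NULL
    carrier <- as.integer(cohort$genotype != "GG")
    gensini <- rep(NA_real_, nrow(cohort))
    is_case <- cohort$y == 1
    gensini[is_case] <- stats::rlnorm(
      sum(is_case),
      meanlog = config$gensini_log_mean +
        log(config$gensini_genotype_shift) * carrier[is_case],
      sdlog = config$gensini_log_sd)
    out <- data.frame(
      subject_id = sprintf("S%05d", seq_len(nrow(cohort))),
      status = factor(ifelse(is_case, "case", "control"),
                      levels = c("control", "case")),
      status_case = as.integer(is_case),
      genotype = cohort$genotype,
      g_dominant = carrier,
      age = round(cohort$age, 1),
      sex = cohort$sex,
      bmi = round(cohort$bmi, 1),
      bmi_over25 = as.integer(round(cohort$bmi, 1) > 25),
      smoking = cohort$smoking, drinking = cohort$drinking,
      t2dm = cohort$t2dm, hyperlipidemia = cohort$hyperlipidemia,
      hypertension = cohort$hypertension,
      gensini = round(gensini, 1))
    attr(out, "config") <- config
    attr(out, "seed") <- config$seed
    out
  })
}

#' Genotype count table from a cohort
#'
#' @param cohort data frame from [simulate_cohort()] or [read_cohort()].
#' @param label optional tag.
#' @return A [genotype_table()].
#' @export
cohort_genotype_table <- function(cohort, label = NULL) {
  tab <- table(cohort$status, factor(cohort$genotype,
                                     levels = GENOTYPE_LEVELS))
  genotype_table(cases = as.integer(tab["case", GENOTYPE_LEVELS]),
                 controls = as.integer(tab["control", GENOTYPE_LEVELS]),
                 label = label)
}

# representative stenosis percentages, one per band
BAND_STENOSIS <- c("1" = 15, "2" = 40, "4" = 65, "8" = 85, "16" = 95,
                   "32" = 100)

#' Simulate per-case angiographic lesion sets
#'
#' For each case a target severity is taken from its `gensini` column (or
#' drawn from the configured log-normal when absent) and a lesion set is
#' constructed greedily over distinct coronary segments so that the
#' computed modified Gensini score approximates the target. A configurable
#' fraction of subjects additionally receives an acute-total-occlusion
#' lesion (which contributes at most 5 points).
#'
#' @param cases case rows of a cohort data frame (all `status == "case"`).
#' @param config a [cohort_config()] (for the severity distribution and
#'   occlusion rate).
#' @param seed optional integer seed.
#' @return Lesion data frame with columns `subject_id`, `segment`,
#'   `stenosis_pct`, `acute_occlusion`.
#' @export
simulate_lesions <- function(cases, config = cohort_config(), seed = NULL) {
  stopifnot(is.data.frame(cases), inherits(config, "cohort_config"))
  if (nrow(cases) == 0L)
    return(data.frame(subject_id = character(), segment = character(),
                      stenosis_pct = numeric(), acute_occlusion = logical()))
  if (!is.null(cases$status) && any(cases$status != "case"))
    stop("`cases` must contain case records only", call. = FALSE)
  vocab <- coronary_segments()
  with_seed(seed, {
    rows <- vector("list", nrow(cases))
    for (i in seq_len(nrow(cases))) {
      target <- cases$gensini[i]
      if (is.null(target) || is.na(target))
        target <- stats::rlnorm(1, config$gensini_log_mean,
                                config$gensini_log_sd)
      segs <- sample(names(vocab))
      remaining <- target
      seg_used <- character(); pct <- numeric(); occl <- logical()
      for (s in segs) {
        if (remaining < 0.5) break
        opts <- as.numeric(names(BAND_STENOSIS))  # points 1..32
        contrib <- opts * vocab[[s]]
        fit <- contrib[contrib <= remaining]
        if (!length(fit)) next
        best <- max(fit)
        pts <- opts[contrib == best][1]
        seg_used <- c(seg_used, s)
        pct <- c(pct, BAND_STENOSIS[[as.character(pts)]])
        occl <- c(occl, FALSE)
        remaining <- remaining - best
      }
      if (!length(seg_used)) {  # tiny target: one minimal lesion
        s <- sample(names(vocab)[vocab <= 1], 1)
        seg_used <- s; pct <- BAND_STENOSIS[["1"]]; occl <- FALSE
      }
      if (stats::runif(1) < config$occlusion_rate) {
        free <- setdiff(names(vocab), seg_used)
        if (length(free)) {
          s <- sample(free, 1)
          seg_used <- c(seg_used, s); pct <- c(pct, 100)
          occl <- c(occl, TRUE)
        }
      }
      rows[[i]] <- data.frame(subject_id = cases$subject_id[i],
                              segment = seg_used, stenosis_pct = pct,
                              acute_occlusion = occl)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write a cohort table to CSV/TSV
#'
#' The delimiter follows the file extension (`.tsv` = tab, otherwise
#' comma). The generator seed, when present, is recorded in a `# seed:`
#' comment line ahead of the header.
#'
#' @param cohort cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(cohort, "seed")
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  utils::write.table(cohort, con, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
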