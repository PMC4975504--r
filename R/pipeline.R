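# Workflow orchestration: simulate -> gensini -> associate -> interact ->
# resample -> mdr -> report, with deterministic per-stage child seeds and a
# JSON run manifest.

#' Read an individual-level cohort table
#'
#' Accepts CSV or TSV (by extension), skipping `#` comment lines. Required
#' columns: `subject_id`, `status` (case/control, or 1/0), `genotype`
#' (GG/AG/AA, case-insensitive, "GA" normalized to "AG"). Other columns are
#' carried through; a `status_case` 0/1 column and dominant/BMI codings are
#' added when derivable.
#'
#' @param path file path.
#' @return Validated cohort data frame.
#' @export
read_cohort <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("empty cohort table: ", path, call. = FALSE)
  need <- c("subject_id", "status", "genotype")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("cohort file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  st <- tolower(trimws(as.character(d$status)))
  st[st %in% c("1", "case")] <- "case"
  st[st %in% c("0", "control")] <- "control"
  bad <- which(!st %in% c("case", "control"))
  if (length(bad))
    stop("unrecognized status value(s) ",
         paste(unique(d$status[bad]), collapse = ", "), " at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  g <- normalize_genotype(d$genotype)
  bad <- which(!g %in% GENOTYPE_LEVELS | is.na(g))
  if (length(bad))
    stop("unrecognized genotype value(s) ",
         paste(unique(d$genotype[bad]), collapse = ", "), " at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  d$status <- factor(st, levels = c("control", "case"))
  d$status_case <- as.integer(st == "case")
  d$genotype <- factor(g, levels = GENOTYPE_LEVELS)
  d$g_dominant <- as.integer(g != "GG")
  if (!is.null(d$bmi) && is.null(d$bmi_over25))
    d$bmi_over25 <- as.integer(d$bmi > 25)
  d
}

#' Read a genotype count table
#'
#' TSV with a `group` column (case/control) and columns GG, AG, AA.
#'
#' @param path file path.
#' @param label optional study-set tag.
#' @return A [genotype_table()].
#' @export
read_counts <- function(path, label = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("group", GENOTYPE_LEVELS)
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("count file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  rows <- tolower(d$group)
  if (!all(c("case", "control") %in% rows))
    stop("count file needs one `case` and one `control` row", call. = FALSE)
  genotype_table(
    cases = unlist(d[rows == "case", GENOTYPE_LEVELS][1, ]),
    controls = unlist(d[rows == "control", GENOTYPE_LEVELS][1, ]),
    label = label)
}

#' Write a genotype count table as TSV
#' @param g a [genotype_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(g, path) {
  stopifnot(inherits(g, "genotype_table"))
  d <- data.frame(group = rownames(g), unclass(g), check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

assoc_summary_row <- function(model, t, alpha) {
  r <- if (model == "additive") additive_trend(t, alpha)
       else odds_ratio(t, alpha)
  data.frame(model = model, or = r$or, ci_low = r$ci[1], ci_high = r$ci[2],
             p = r$p)
}

#' Association summary across genetic models
#'
#' Computes allelic, additive, dominant and recessive odds ratios with
#' Woolf CIs and Wald p-values for one genotype table, plus the control
#' Hardy-Weinberg p and the case/control minor-allele frequencies.
#'
#' @param g a [genotype_table()].
#' @param alpha CI level complement.
#' @return List with `table` (one row per model), `hwe_control`,
#'   `maf_case`, `maf_control`.
#' @export
associate_models <- function(g, alpha = 0.05) {
  stopifnot(inherits(g, "genotype_table"))
  tab <- rbind(
    assoc_summary_row("allelic", allele_table(g), alpha),
    assoc_summary_row("additive", g, alpha),
    assoc_summary_row("dominant", recode_model(g, "dominant"), alpha),
    assoc_summary_row("recessive", recode_model(g, "recessive"), alpha))
  list(table = tab,
       hwe_control = hwe_test(g["control", ]),
       maf_case = minor_allele_frequency(g, "case"),
       maf_control = minor_allele_frequency(g, "control"))
}

default_run_config <- function() {
  list(out_dir = ".", seed = 1L,
       stages = c("simulate", "gensini", "associate", "interact",
                  "resample", "mdr", "report"),
       cohort = list(n_cases = 500, n_controls = 500),
       paths = list(cohort = NULL, lesions = NULL, counts = NULL),
       assoc = list(alpha = 0.05),
       interact = list(exposures = c("t2dm", "hyperlipidemia",
                                     "bmi_over25")),
       resample = list(n_permutations = 10000,
                       statistics = c("allelic", "dominant")),
       mdr = list(factors = c("g_dominant", "t2dm", "hyperlipidemia",
                              "bmi_over25"),
                  max_size = 3, folds = 5, repeats = 2,
                  permutations = 0))
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  base <- default_run_config()
  merge_lists <- function(a, b) {
    for (nm in names(b))
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_lists(a[[nm]], b[[nm]]) else b[[nm]]
    a
  }
  merge_lists(base, config)
}

#' Run the full study workflow
#'
#' Executes the enabled stages in dependency order, writing per-stage TSV
#' and JSON outputs plus a `manifest.json` recording the package version,
#' seed, per-stage child seeds and input file checksums. One global seed
#' fans out to stable per-stage child seeds, so toggling one stage never
#' shifts another stage's randomness; a fixed seed makes the run
#' byte-identical.
#'
#' Individual-level stages (gensini, interact, mdr) need a cohort (either
#' simulated or read from `paths$cohort`); when only a count table is
#' supplied they are skipped with a notice.
#'
#' @param config a named list (see `Details`), or the path of a YAML/JSON
#'   config file. Recognized top-level fields: `out_dir`, `seed`, `stages`,
#'   `cohort` (arguments for [cohort_config()]), `paths` (`cohort`,
#'   `lesions`, `counts`), `assoc`, `interact`, `resample`, `mdr`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- load_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(...) file.path(cfg$out_dir, ...)
  manifest <- list(package = "snpgxe",
                   version = as.character(utils::packageVersion("snpgxe")),
                   seed = cfg$seed, stages = cfg$stages,
                   stage_seeds = list(), outputs = character(),
                   inputs = list())
  note <- function(...) message("[snpgxe] ", ...)
  enabled <- function(s) s %in% cfg$stages

  for (p in Filter(Negate(is.null), cfg$paths))
    if (!file.exists(p)) stop("input path does not exist: ", p,
                              call. = FALSE)
  for (nm in names(cfg$paths))
    if (!is.null(cfg$paths[[nm]]))
      manifest$inputs[[nm]] <- unname(tools::md5sum(cfg$paths[[nm]]))

  cohort <- NULL; lesions <- NULL; counts <- NULL
  if (!is.null(cfg$paths$cohort)) cohort <- read_cohort(cfg$paths$cohort)
  if (!is.null(cfg$paths$lesions)) lesions <- read_lesions(cfg$paths$lesions)
  if (!is.null(cfg$paths$counts)) counts <- read_counts(cfg$paths$counts)

  if (enabled("simulate") && is.null(cohort)) {
    sseed <- child_seed(cfg$seed, "simulate")
    manifest$stage_seeds$simulate <- sseed
    cc <- do.call(cohort_config, c(cfg$cohort, list(seed = sseed)))
    cohort <- simulate_cohort(cc)
    write_cohort(cohort, outfile("cohort.tsv"))
    manifest$outputs <- c(manifest$outputs, "cohort.tsv")
    if (is.null(lesions)) {
      lseed <- child_seed(cfg$seed, "lesions")
      manifest$stage_seeds$lesions <- lseed
      lesions <- simulate_lesions(cohort[cohort$status == "case", ], cc,
                                  seed = lseed)
      utils::write.csv(lesions, outfile("lesions.csv"), row.names = FALSE)
      manifest$outputs <- c(manifest$outputs, "lesions.csv")
    }
  }

  if (enabled("gensini")) {
    if (is.null(lesions)) {
      note("gensini stage skipped: no lesion data available")
    } else {
      scores <- gensini_scores(lesions)
      sev <- dichotomize_severity(scores$score, "median")
      scores$severe <- sev$severity
      write_gensini(scores, outfile("gensini_scores.tsv"))
      manifest$outputs <- c(manifest$outputs, "gensini_scores.tsv")
      manifest$gensini_cutoff <- sev$cutoff
    }
  }

  if (enabled("associate")) {
    g <- counts %||% (if (!is.null(cohort))
      cohort_genotype_table(cohort, label = "cohort"))
    if (is.null(g)) {
      note("associate stage skipped: no genotype data available")
    } else {
      res <- associate_models(g, alpha = cfg$assoc$alpha)
      utils::write.table(res$table, outfile("association.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(models = res$table, hwe_control = res$hwe_control,
             maf_case = res$maf_case, maf_control = res$maf_control),
        outfile("association.json"), auto_unbox = TRUE, digits = NA)
      manifest$outputs <- c(manifest$outputs,
                            "association.tsv", "association.json")
      counts <- g
    }
  }

  if (enabled("interact")) {
    if (is.null(cohort)) {
      note("interact stage skipped: needs individual-level cohort data")
    } else {
      rows <- lapply(cfg$interact$exposures, function(e) {
        it <- interaction_test(cohort, "g_dominant", e)
        data.frame(exposure = e, or_interaction = it$or_interaction,
                   ci_low = it$ci[1], ci_high = it$ci[2], p_lrt = it$p)
      })
      itab <- do.call(rbind, rows)
      utils::write.table(itab, outfile("interactions.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      manifest$outputs <- c(manifest$outputs, "interactions.tsv")
    }
  }

  if (enabled("resample")) {
    if (is.null(counts)) {
      note("resample stage skipped: no genotype data available")
    } else {
      rseed <- child_seed(cfg$seed, "resample")
      manifest$stage_seeds$resample <- rseed
      perms <- lapply(cfg$resample$statistics, function(s)
        empirical_p(counts, permutation_plan(cfg$resample$n_permutations,
                                             seed = rseed, statistic = s)))
      names(perms) <- cfg$resample$statistics
      jsonlite::write_json(perms, outfile("permutation.json"),
                           auto_unbox = TRUE, digits = NA)
      manifest$outputs <- c(manifest$outputs, "permutation.json")
    }
  }

  if (enabled("mdr")) {
    if (is.null(cohort)) {
      note("mdr stage skipped: needs individual-level cohort data")
    } else {
      mseed <- child_seed(cfg$seed, "mdr")
      manifest$stage_seeds$mdr <- mseed
      m <- cfg$mdr
      res <- mdr_search(cohort, m$factors, max_size = m$max_size,
                        folds = m$folds, repeats = m$repeats, seed = mseed)
      utils::write.table(res$best_per_size, outfile("mdr.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      eg <- entropy_graph(cohort, m$factors)
      jsonlite::write_json(
        list(univariate_percent = as.list(eg$univariate),
             pairwise = eg$pairwise,
             outcome_entropy_bits = eg$outcome_entropy),
        outfile("entropy.json"), auto_unbox = TRUE, digits = NA)
      manifest$outputs <- c(manifest$outputs, "mdr.tsv", "entropy.json")
      if (m$permutations > 0) {
        pt <- mdr_permutation_test(cohort, m$factors,
                                   n_perm = m$permutations,
                                   max_size = m$max_size, folds = m$folds,
                                   repeats = m$repeats, seed = mseed)
        manifest$mdr_permutation_p <- pt$p
      }
    }
  }

  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
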