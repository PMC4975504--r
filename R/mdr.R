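# Multifactor dimensionality reduction (MDR).
#
# Exhaustive search over factor combinations; each multilocus cell is
# collapsed to high or low risk by comparing its case:control ratio with the
# overall ratio in the training split; models are scored by cross-validated
# balanced testing accuracy, selection stability by cross-validation
# consistency (CVC), and significance by outcome-label permutation.

mdr_outcome_binary <- function(data, outcome) {
  y <- data[[outcome]]
  if (is.null(y)) stop("outcome column `", outcome, "` not found",
                       call. = FALSE)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1)))
    stop("outcome must be binary", call. = FALSE)
  y
}

# integer cell code (1..n_cells) for each row under a factor combination
mdr_cell_codes <- function(data, factors) {
  f <- interaction(data[factors], drop = FALSE, lex.order = TRUE)
  list(code = as.integer(f), n_cells = nlevels(f), labels = levels(f))
}

#' Label multilocus cells as high or low risk
#'
#' Each observed cell is labeled high-risk when its case:control ratio is at
#' least the overall training ratio (ties labeled high); nonempty cells with
#' zero controls are high-risk, and empty cells default to low-risk (so
#' combinations unseen in training predict control).
#'
#' @param data training data frame.
#' @param factors character vector of categorical column names.
#' @param outcome binary outcome column name (default `"status_case"`).
#' @param threshold case:control ratio threshold; default is the training
#'   set's overall ratio.
#' @return Object of class `mdr_model`: `factors`, `cell_labels` (character
#'   "high"/"low" named by cell), `threshold`, per-cell counts.
#' @export
mdr_label_cells <- function(data, factors, outcome = "status_case",
                            threshold = NULL) {
  y <- mdr_outcome_binary(data, outcome)
  if (length(unique(y)) < 2L)
    stop("training data must contain both cases and controls", call. = FALSE)
  cc <- mdr_cell_codes(data, factors)
  cases <- tabulate(cc$code[y == 1], nbins = cc$n_cells)
  controls <- tabulate(cc$code[y == 0], nbins = cc$n_cells)
  if (is.null(threshold)) threshold <- sum(y == 1) / sum(y == 0)
  check_positive(threshold, "threshold")
  high <- ifelse(controls > 0, cases / controls >= threshold, cases > 0)
  labels <- ifelse(high, "high", "low")
  names(labels) <- cc$labels
  structure(list(factors = factors, cell_labels = labels,
                 threshold = threshold,
                 counts = data.frame(cell = cc$labels, cases = cases,
                                     controls = controls)),
            class = "mdr_model")
}

#' @export
print.mdr_model <- function(x, ...) {
  cat("MDR model over {", paste(x$factors, collapse = ", "), "}, ",
      sum(x$cell_labels == "high"), " high-risk cell(s), threshold ",
      signif(x$threshold, 4), "\n", sep = "")
  invisible(x)
}

#' Balanced testing accuracy of an MDR model
#'
#' Predicts case for subjects falling in high-risk cells (cells unseen in
#' training predict control) and returns
#' `(sensitivity + specificity) / 2`.
#'
#' @param model an [mdr_label_cells()] model.
#' @param data test data frame containing the model's factor columns.
#' @param outcome binary outcome column name.
#' @return List with `balanced_accuracy`, `accuracy` (plain fraction
#'   correct), `sensitivity`, `specificity`.
#' @export
mdr_balanced_accuracy <- function(model, data, outcome = "status_case") {
  stopifnot(inherits(model, "mdr_model"))
  y <- mdr_outcome_binary(data, outcome)
  if (length(unique(y)) < 2L)
    stop("test data must contain both cases and controls", call. = FALSE)
  cc <- mdr_cell_codes(data, model$factors)
  lab <- model$cell_labels[cc$labels[cc$code]]
  pred <- as.integer(!is.na(lab) & lab == "high")
  sens <- sum(pred == 1 & y == 1) / sum(y == 1)
  spec <- sum(pred == 0 & y == 0) / sum(y == 0)
  list(balanced_accuracy = (sens + spec) / 2,
       accuracy = mean(pred == y), sensitivity = sens, specificity = spec)
}

# stratified fold assignment: within each outcome class, folds are dealt
# round-robin over a random order
mdr_fold_assignments <- function(y, folds, repeats) {
  lapply(seq_len(repeats), function(r) {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < folds)
        stop("fewer than `folds` subjects in a class", call. = FALSE)
      fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
    fold
  })
}

#' Repeated stratified cross-validation of one factor combination
#'
#' `folds`-fold stratified cross-validation repeated `repeats` times
#' (default 10 x 10 = 100 held-out evaluations): cells are labeled on the
#' training folds and balanced accuracy is measured on the held-out fold.
#'
#' @param data data frame.
#' @param factors factor combination to evaluate.
#' @param outcome binary outcome column.
#' @param folds,repeats cross-validation scheme.
#' @param seed integer seed (fixed seed gives identical folds).
#' @return List with `mean_accuracy` and the vector of per-evaluation
#'   `accuracies` (length `folds * repeats`).
#' @export
mdr_cross_validate <- function(data, factors, outcome = "status_case",
                               folds = 10, repeats = 10, seed = NULL) {
  check_count(folds, "folds", min = 2L); check_count(repeats, "repeats")
  y <- mdr_outcome_binary(data, outcome)
  with_seed(seed, {
    assignments <- mdr_fold_assignments(y, folds, repeats)
    acc <- numeric(0)
    for (fold in assignments)
      for (f in seq_len(folds)) {
        train <- data[fold != f, , drop = FALSE]
        test <- data[fold == f, , drop = FALSE]
        model <- mdr_label_cells(train, factors, outcome)
        acc <- c(acc,
                 mdr_balanced_accuracy(model, test,
                                       outcome)$balanced_accuracy)
      }
    list(mean_accuracy = mean(acc), accuracies = acc)
  })
}

#' Exhaustive MDR search over factor combinations
#'
#' Evaluates every combination of 1 to `max_size` candidate factors under a
#' shared repeated stratified cross-validation scheme. Within each size,
#' each of the `folds * repeats` evaluations votes for the combination with
#' the highest held-out balanced accuracy; the vote count is the
#' cross-validation consistency (CVC). The per-size winner maximizes CVC
#' (ties broken by mean testing accuracy), and the overall best model
#' maximizes CVC across sizes, ties broken by mean testing accuracy, then
#' by smaller size.
#'
#' @param data data frame.
#' @param candidates candidate factor column names.
#' @param outcome binary outcome column.
#' @param max_size largest combination size (default `min(4, #candidates)`).
#' @param folds,repeats cross-validation scheme (default 10 x 10).
#' @param seed integer seed.
#' @return Object of class `mdr_result`: `best_per_size` data frame
#'   (factors, cvc, mean testing accuracy), `overall_best`, `evaluations`
#'   (= folds * repeats) and the full per-combination accuracy table.
#' @export
mdr_search <- function(data, candidates, outcome = "status_case",
                       max_size = NULL, folds = 10, repeats = 10,
                       seed = NULL) {
  if (length(candidates) < 1L)
    stop("need at least one candidate factor", call. = FALSE)
  max_size <- max_size %||% min(4L, length(candidates))
  check_count(max_size, "max_size")
  max_size <- min(max_size, length(candidates))
  check_count(folds, "folds", min = 2L); check_count(repeats, "repeats")
  y <- mdr_outcome_binary(data, outcome)
  combos <- unlist(lapply(seq_len(max_size), function(k)
    utils::combn(candidates, k, simplify = FALSE)), recursive = FALSE)
  sizes <- lengths(combos)
  n_eval <- folds * repeats
  with_seed(seed, {
    assignments <- mdr_fold_assignments(y, folds, repeats)
    acc <- matrix(NA_real_, nrow = length(combos), ncol = n_eval)
    e <- 0L
    for (fold in assignments)
      for (f in seq_len(folds)) {
        e <- e + 1L
        train <- data[fold != f, , drop = FALSE]
        test <- data[fold == f, , drop = FALSE]
        for (ci in seq_along(combos)) {
          model <- mdr_label_cells(train, combos[[ci]], outcome)
          acc[ci, e] <- mdr_balanced_accuracy(model, test,
                                              outcome)$balanced_accuracy
        }
      }
    cvc <- integer(length(combos))
    for (k in unique(sizes)) {
      rows <- which(sizes == k)
      for (e in seq_len(n_eval)) {
        win <- rows[which.max(acc[rows, e])]
        cvc[win] <- cvc[win] + 1L
      }
    }
    mean_acc <- rowMeans(acc)
    per_size <- do.call(rbind, lapply(unique(sizes), function(k) {
      rows <- which(sizes == k)
      ord <- rows[order(-cvc[rows], -mean_acc[rows])]
      best <- ord[1]
      data.frame(size = k,
                 factors = paste(combos[[best]], collapse = ", "),
                 cvc = cvc[best], evaluations = n_eval,
                 testing_accuracy = mean_acc[best])
    }))
    ord <- order(-per_size$cvc, -per_size$testing_accuracy, per_size$size)
    overall <- per_size[ord[1], ]
    structure(list(best_per_size = per_size,
                   overall_best = strsplit(overall$factors, ", ")[[1]],
                   overall_accuracy = overall$testing_accuracy,
                   overall_cvc = overall$cvc,
                   evaluations = n_eval,
                   combinations = vapply(combos, paste, "", collapse = ", "),
                   cvc = cvc, mean_accuracy = mean_acc),
              class = "mdr_result")
  })
}

#' @export
print.mdr_result <- function(x, ...) {
  cat("MDR search over", length(x$combinations), "combinations,",
      x$evaluations, "CV evaluations\n")
  print(x$best_per_size, row.names = FALSE)
  cat("Overall best: {", paste(x$overall_best, collapse = ", "),
      "} CVC ", x$overall_cvc, "/", x$evaluations, "\n", sep = "")
  invisible(x)
}

#' Permutation significance of the best MDR model
#'
#' Permutes the outcome labels `n_perm` times, reruns the full search per
#' permutation, and reports the add-one empirical p-value for the observed
#' best testing accuracy.
#'
#' @param data data frame.
#' @param candidates candidate factor columns.
#' @param outcome binary outcome column.
#' @param n_perm number of permutations (default 1000).
#' @param max_size,folds,repeats search settings (shared by the observed
#'   and permuted runs).
#' @param seed integer seed.
#' @return List with `p`, `observed_accuracy`, `exceedances`, `n_perm`.
#' @export
mdr_permutation_test <- function(data, candidates, outcome = "status_case",
                                 n_perm = 1000, max_size = NULL,
                                 folds = 10, repeats = 10, seed = NULL) {
  check_count(n_perm, "n_perm")
  observed <- mdr_search(data, candidates, outcome, max_size = max_size,
                         folds = folds, repeats = repeats, seed = seed)
  obs_acc <- observed$overall_accuracy
  perm_acc <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      d <- data
      d[[outcome]] <- sample(data[[outcome]])
      res <- mdr_search(d, candidates, outcome, max_size = max_size,
                        folds = folds, repeats = repeats,
                        seed = sample.int(2^30, 1))
      res$overall_accuracy
    }, 0)
  })
  b <- sum(perm_acc >= obs_acc - 1e-12)
  list(p = (1 + b) / (1 + n_perm), observed_accuracy = obs_acc,
       exceedances = b, n_perm = n_perm, observed = observed)
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

mutual_information <- function(x, y) {
  tab <- table(x, y)
  entropy_bits(rowSums(tab)) + entropy_bits(colSums(tab)) -
    entropy_bits(as.vector(tab))
}

#' Interaction entropy graph
#'
#' Decomposes the outcome entropy explained by each factor and factor pair:
#' the univariate effect of factor A is `100 * I(A; Y) / H(Y)` and the
#' pairwise effect of A and B is the interaction information
#' `100 * [I(A,B; Y) - I(A; Y) - I(B; Y)] / H(Y)` (positive = synergy,
#' negative = redundancy), all entropies in bits. Pairs are classed as
#' strong/moderate/weak by configurable percentage thresholds.
#'
#' @param data data frame of categorical factors plus a binary outcome.
#' @param factors factor column names.
#' @param outcome binary outcome column.
#' @param thresholds length-2 numeric: minimum absolute percentage of
#'   outcome entropy for a "strong" and a "moderate" pairwise interaction.
#' @return Object of class `entropy_graph`: `univariate` (named percent
#'   vector), `pairwise` (data frame with `a`, `b`, `percent`, `strength`),
#'   `outcome_entropy` (bits).
#' @export
entropy_graph <- function(data, factors, outcome = "status_case",
                          thresholds = c(strong = 2, moderate = 1)) {
  y <- mdr_outcome_binary(data, outcome)
  hy <- entropy_bits(table(y))
  if (hy == 0) stop("constant outcome: entropy is zero", call. = FALSE)
  uni <- vapply(factors, function(f)
    100 * mutual_information(data[[f]], y) / hy, 0)
  pairs <- if (length(factors) >= 2) utils::combn(factors, 2,
                                                  simplify = FALSE)
           else list()
  pw <- do.call(rbind, lapply(pairs, function(p) {
    joint <- interaction(data[[p[1]]], data[[p[2]]], drop = TRUE)
    ii <- 100 * (mutual_information(joint, y) -
                   mutual_information(data[[p[1]]], y) -
                   mutual_information(data[[p[2]]], y)) / hy
    data.frame(a = p[1], b = p[2], percent = ii,
               strength = if (abs(ii) >= thresholds[["strong"]]) "strong"
                          else if (abs(ii) >= thresholds[["moderate"]])
                            "moderate" else "weak")
  }))
  structure(list(univariate = uni,
                 pairwise = pw %||% data.frame(),
                 outcome_entropy = hy, thresholds = thresholds),
            class = "entropy_graph")
}

#' @export
print.entropy_graph <- function(x, ...) {
  cat(sprintf("Outcome entropy %.4f bits\nUnivariate (%% of H(Y)):\n",
              x$outcome_entropy))
  print(round(x$univariate, 2))
  if (NROW(x$pairwise)) {
    cat("Pairwise interaction information (% of H(Y)):\n")
    print(transform(x$pairwise, percent = round(percent, 2)),
          row.names = FALSE)
  }
  invisible(x)
}
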