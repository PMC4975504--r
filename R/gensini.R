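# Modified Gensini angiographic severity scoring.
#
# Each coronary segment lesion gets band points by percent stenosis, a
# segment-importance multiplier, and the weighted contributions are summed.

#' Coronary segment vocabulary and multipliers
#'
#' The fixed list of accepted coronary segment labels with their
#' modified-Gensini importance multipliers: 5 for the main left coronary
#' artery, 2.5 for the proximal left anterior descending (LAD) and proximal
#' left circumflex, 1.5 for the mid LAD, 0.5 for the second diagonal and
#' posterolateral branches, and 1 for all other branches.
#'
#' @return Named numeric vector of multipliers, names are the accepted
#'   segment labels.
#' @export
coronary_segments <- function() {
  c(MLCA = 5,
    proximal_LAD = 2.5, proximal_LCX = 2.5,
    mid_LAD = 1.5,
    second_diagonal = 0.5, posterolateral = 0.5,
    distal_LAD = 1, first_diagonal = 1, distal_LCX = 1,
    obtuse_marginal = 1, right_coronary_proximal = 1,
    right_coronary_mid = 1, right_coronary_distal = 1,
    posterior_descending = 1)
}

#' Stenosis band points
#'
#' Maps percent luminal narrowing to severity points: 1 for 0-25%, 2 for
#' 26-50%, 4 for 51-75%, 8 for 76-90%, 16 for 91-99% and 32 for total (100%)
#' occlusion. Continuous inputs use half-open bands ((25, 50] -> 2, etc.) so
#' every value in [0, 100] maps unambiguously and the printed integer bands
#' are honoured.
#'
#' @param stenosis_pct percent stenosis, in [0, 100] (vectorized).
#' @return Integer points in {1, 2, 4, 8, 16, 32}.
#' @examples
#' stenosis_points(c(0, 80, 100))  # 1, 8, 32
#' @export
stenosis_points <- function(stenosis_pct) {
  if (any(!is.finite(stenosis_pct)) ||
      any(stenosis_pct < 0 | stenosis_pct > 100))
    stop("`stenosis_pct` must be in [0, 100]", call. = FALSE)
  pts <- rep(NA_integer_, length(stenosis_pct))
  pts[stenosis_pct <= 25] <- 1L
  pts[stenosis_pct > 25 & stenosis_pct <= 50] <- 2L
  pts[stenosis_pct > 50 & stenosis_pct <= 75] <- 4L
  pts[stenosis_pct > 75 & stenosis_pct <= 90] <- 8L
  pts[stenosis_pct > 90 & stenosis_pct < 100] <- 16L
  pts[stenosis_pct == 100] <- 32L
  pts
}

#' Segment importance multiplier
#'
#' @param segment segment label(s), from [coronary_segments()]
#'   (case-sensitive match after trimming whitespace).
#' @return Numeric multiplier(s) in {5, 2.5, 1.5, 1, 0.5}.
#' @examples
#' segment_multiplier("MLCA")          # 5
#' segment_multiplier("proximal_LAD")  # 2.5
#' @export
segment_multiplier <- function(segment) {
  vocab <- coronary_segments()
  seg <- trimws(as.character(segment))
  unknown <- setdiff(unique(seg), names(vocab))
  if (length(unknown))
    stop("unknown coronary segment(s): ",
         paste(unknown, collapse = ", "),
         "; accepted labels: ", paste(names(vocab), collapse = ", "),
         call. = FALSE)
  unname(vocab[seg])
}

#' Modified Gensini score for one subject
#'
#' Sums `stenosis_points(pct) * segment_multiplier(segment)` over a
#' subject's lesions. A lesion flagged as an acute total occlusion is scored
#' as a non-critical lesion: its points are forced to the lowest band (1)
#' and the weighted contribution is capped at 5, so every such lesion
#' contributes in the 0-5 range regardless of segment.
#'
#' @param lesions data frame with columns `subject_id`, `segment`,
#'   `stenosis_pct` and (optionally) `acute_occlusion` (logical/0-1); all
#'   rows must share one `subject_id`. May be empty (score 0).
#' @return Object of class `gensini_result`: list with `subject_id`,
#'   `score`, and `contributions` (per-lesion data frame with `points`,
#'   `multiplier`, `weighted`).
#' @examples
#' l <- data.frame(subject_id = "p1",
#'                 segment = c("MLCA", "mid_LAD"),
#'                 stenosis_pct = c(95, 60))
#' modified_gensini(l)$score  # 16*5 + 4*1.5 = 86
#' @export
modified_gensini <- function(lesions) {
  stopifnot(is.data.frame(lesions))
  if (nrow(lesions) == 0L)
    return(structure(list(subject_id = NA_character_, score = 0,
                          contributions = data.frame()),
                     class = "gensini_result"))
  need <- c("subject_id", "segment", "stenosis_pct")
  if (!all(need %in% names(lesions)))
    stop("lesion table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ids <- unique(as.character(lesions$subject_id))
  if (length(ids) != 1L)
    stop("all lesions must share one subject_id; got: ",
         paste(ids, collapse = ", "), call. = FALSE)
  occ <- as.logical(lesions$acute_occlusion %||% rep(FALSE, nrow(lesions)))
  occ[is.na(occ)] <- FALSE
  pts <- stenosis_points(lesions$stenosis_pct)
  mult <- segment_multiplier(lesions$segment)
  pts[occ] <- 1L
  weighted <- pts * mult
  weighted[occ] <- pmin(weighted[occ], 5)
  structure(list(
    subject_id = ids,
    score = sum(weighted),
    contributions = data.frame(segment = as.character(lesions$segment),
                               stenosis_pct = lesions$stenosis_pct,
                               acute_occlusion = occ, points = pts,
                               multiplier = mult, weighted = weighted)),
    class = "gensini_result")
}

#' @export
print.gensini_result <- function(x, ...) {
  cat(sprintf("Modified Gensini score for %s: %g (%d lesion%s)\n",
              x$subject_id, x$score, nrow(x$contributions),
              if (nrow(x$contributions) == 1) "" else "s"))
  invisible(x)
}

#' Modified Gensini scores for a multi-subject lesion table
#'
#' @param lesions data frame as in [modified_gensini()], any number of
#'   subjects.
#' @return Data frame with one row per subject: `subject_id`, `score`,
#'   `n_lesions`.
#' @export
gensini_scores <- function(lesions) {
  stopifnot(is.data.frame(lesions))
  if (nrow(lesions) == 0L)
    return(data.frame(subject_id = character(), score = numeric(),
                      n_lesions = integer()))
  pieces <- split(lesions, as.character(lesions$subject_id))
  out <- data.frame(
    subject_id = names(pieces),
    score = vapply(pieces, function(d) modified_gensini(d)$score, 0),
    n_lesions = vapply(pieces, nrow, 0L),
    row.names = NULL)
  out[order(out$subject_id), , drop = FALSE]
}

#' Dichotomize severity scores at a cutoff
#'
#' Severity is 1 when `score > cutoff` (strict, so scores equal to the
#' cutoff fall in the lower group, matching a median split into at-most-half
#' above).
#'
#' @param scores numeric vector of nonnegative severity scores.
#' @param cutoff numeric cutoff, or `"median"` to use the sample median.
#' @return List with `severity` (integer 0/1 vector) and `cutoff` used.
#' @export
dichotomize_severity <- function(scores, cutoff = "median") {
  if (!length(scores) || any(!is.finite(scores)))
    stop("`scores` must be nonempty and finite", call. = FALSE)
  if (identical(cutoff, "median")) cutoff <- stats::median(scores)
  if (!is.numeric(cutoff) || length(cutoff) != 1L)
    stop('`cutoff` must be a number or "median"', call. = FALSE)
  list(severity = as.integer(scores > cutoff), cutoff = cutoff)
}

#' Read a lesion table from CSV
#'
#' Expected columns: `subject_id`, `segment`, `stenosis_pct`,
#' `acute_occlusion` (0/1 or TRUE/FALSE; optional, default 0).
#'
#' @param path CSV file path.
#' @return Validated lesion data frame.
#' @export
read_lesions <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "segment", "stenosis_pct")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("lesion file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(d$acute_occlusion)) d$acute_occlusion <- FALSE
  d$acute_occlusion <- as.logical(d$acute_occlusion)
  segment_multiplier(d$segment)  # validates the vocabulary
  stenosis_points(d$stenosis_pct)  # validates the range
  d
}

#' Write per-subject Gensini scores as TSV
#'
#' @param scores data frame from [gensini_scores()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gensini <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
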