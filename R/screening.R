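#' Per-patient positive prediction ratio
#'
#' Aggregates single-cell genotype predictions to the patient level: the
#' positive prediction ratio r is the fraction of a patient's cells
#' predicted mutant. This is the screening statistic thresholded to build
#' the patient-level ROC.
#'
#' @param predictions Tibble with columns `patient_id`, `label` (predicted
#'   class, `"WT"`/`"MUT"`), and optionally `genotype` (true label).
#' @return Tibble with one row per patient: `patient_id`, `n_cells`,
#'   `positive_ratio`, and `genotype` when available.
#' @export
patient_ratios <- function(predictions) {
  stopifnot(nrow(predictions) >= 1,
            all(c("patient_id", "label") %in% names(predictions)))
  out <- predictions |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      positive_ratio = mean(.data$label == "MUT"),
      genotype = if ("genotype" %in% names(predictions))
        dplyr::first(.data$genotype) else NA_character_,
      .groups = "drop")
  out
}

#' Patient-level ROC over positive-prediction-ratio thresholds
#'
#' Sweeps the decision threshold t over all distinct patient ratios plus
#' +Inf, classifying a patient as mutant when `r >= t` (closed rule: the
#' threshold itself calls mutant). The area under the step curve is computed
#' by trapezoidal integration with integer accumulation, which makes it
#' exactly equal to the pair-concordance statistic (ties counted 1/2).
#'
#' @param ratios Tibble from [patient_ratios()] with `positive_ratio` and
#'   `genotype` (both `"WT"` and `"MUT"` must be present).
#' @return An object of class `roc_result`: list with `points` (tibble:
#'   threshold, fpr, tpr), `auc`, `concordance` (equal to `auc`),
#'   `n_positive`, `n_negative`.
#' @export
roc_auc <- function(ratios) {
  stopifnot(all(c("positive_ratio", "genotype") %in% names(ratios)))
  r_pos <- ratios$positive_ratio[ratios$genotype == "MUT"]
  r_neg <- ratios$positive_ratio[ratios$genotype == "WT"]
  if (length(r_pos) == 0 || length(r_neg) == 0)
    stop("both genotypes must be present to build a ROC curve")
  thresholds <- sort(unique(c(ratios$positive_ratio, Inf)),
                     decreasing = TRUE)
  pts <- tibble::tibble(
    threshold = thresholds,
    tp = vapply(thresholds, function(t) sum(r_pos >= t), 0),
    fp = vapply(thresholds, function(t) sum(r_neg >= t), 0))
  pts$tpr <- pts$tp / length(r_pos)
  pts$fpr <- pts$fp / length(r_neg)
  # integer-accumulated trapezoid: sum (dfp) * (tp_i + tp_{i+1}) over steps,
  # divided once, so the value is exactly the concordance count / (n1 n2)
  num <- 0
  for (i in seq_len(nrow(pts) - 1)) {
    num <- num + (pts$fp[i + 1] - pts$fp[i]) * (pts$tp[i] + pts$tp[i + 1])
  }
  auc <- num / (2 * length(r_pos) * length(r_neg))
  conc <- (sum(outer(r_pos, r_neg, `>`)) +
             0.5 * sum(outer(r_pos, r_neg, `==`))) /
    (length(r_pos) * length(r_neg))
  structure(
    list(points = dplyr::select(pts, "threshold", "fpr", "tpr"),
         auc = auc, concordance = conc,
         n_positive = length(r_pos), n_negative = length(r_neg),
         ratios_positive = sort(r_pos), ratios_negative = sort(r_neg)),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d MUT vs %d WT patients, AUC = %.4f\n",
              x$n_positive, x$n_negative, x$auc))
  invisible(x)
}

#' Operating points of a patient-level ROC
#'
#' Reports the maximum true positive rate achievable at zero false positive
#' rate and the minimum false positive rate achievable at full sensitivity,
#' each with the half-open interval `(lo, hi]` of thresholds attaining it
#' under the closed decision rule `r >= t`.
#'
#' @param roc A [roc_auc()] result.
#' @return A list with `tpr_at_zero_fpr` and `fpr_at_full_tpr`, each a list
#'   holding `value` and `threshold_interval` (c(lo, hi], hi may be Inf).
#' @export
operating_points <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  r_pos <- roc$ratios_positive
  r_neg <- roc$ratios_negative
  # FPR = 0 <=> t > max(WT ratios); TPR maximal for the smallest such t
  lo1 <- max(r_neg)
  above <- r_pos[r_pos > lo1]
  if (length(above) == 0) {
    tpr0 <- list(value = 0, threshold_interval = c(lo1, Inf))
  } else {
    hi1 <- min(above)  # smallest achieving threshold (closed rule)
    tpr0 <- list(value = sum(r_pos >= hi1) / length(r_pos),
                 threshold_interval = c(lo1, hi1))
  }
  # TPR = 1 <=> t <= min(MUT ratios); FPR minimal for the largest such t
  hi2 <- min(r_pos)
  below <- r_neg[r_neg < hi2]
  lo2 <- if (length(below) == 0) -Inf else max(below)
  fpr1 <- list(value = sum(r_neg >= hi2) / length(r_neg),
               threshold_interval = c(lo2, hi2))
  list(tpr_at_zero_fpr = tpr0, fpr_at_full_tpr = fpr1)
}

#' End-to-end patient screening from single-cell predictions
#'
#' @param predictions Tibble with `patient_id`, `label`, `genotype`.
#' @return List: `patients` (per-patient ratios), `roc` ([roc_auc()]),
#'   `operating_points`.
#' @export
screen_patients <- function(predictions) {
  pr <- patient_ratios(predictions)
  roc <- roc_auc(pr)
  list(patients = pr, roc = roc, operating_points = operating_points(roc))
}
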