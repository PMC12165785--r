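#' Calibration score of a variant
#'
#' The decision-relevant functional score is the variant's worst-case
#' behavior: the minimum replicate-mean normalized variant/WT' ratio across
#' the day-12 arms. The same thresholds apply in every arm, and the
#' pathogenic functional code is triggered by deleteriousness in any single
#' arm, so the minimum is the score that drives classification.
#'
#' @param summary_one Summary rows (from [summarize_ratios()]) for one
#'   variant; day-2 rows are ignored.
#' @return Minimum day-12 replicate-mean normalized ratio (percent).
#' @export
calibration_score <- function(summary_one) {
  s <- summary_one[summary_one$condition %in% DAY12_CONDITIONS, ,
                   drop = FALSE]
  if (nrow(s) == 0L) stop("no day-12 conditions present for ",
                          paste(unique(summary_one$variant_id),
                                collapse = ","))
  min(s$mean)
}

#' Calibration scores for every variant in a summary table
#'
#' @param summary_df Summary data.frame from [summarize_ratios()].
#' @return Data.frame `variant_id`, `score`.
#' @export
calibration_scores <- function(summary_df) {
  vids <- unique(summary_df$variant_id)
  data.frame(variant_id = vids,
             score = vapply(vids, function(v) {
               calibration_score(summary_df[summary_df$variant_id == v, ])
             }, numeric(1L)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' ROC curve over functional-score cutoffs
#'
#' Standard ROC construction: a variant is predicted pathogenic when its
#' score falls at or below the cutoff (lower functional score = more
#' deleterious). Cutoffs sweep the observed scores; AUC is computed by the
#' trapezoid rule, and the Youden-J-optimal single cutoff is reported for
#' transparency (the two-threshold intermediate-zone scheme used for
#' categorization is configuration, not inference).
#'
#' @param controls Data.frame with columns `truth`
#'   (`"benign"` / `"pathogenic"`) and `score` (percent). Rows with other
#'   truth labels (e.g. risk alleles) must be excluded by the caller;
#'   [calibrate_assay()] does this by role.
#' @return List of class `roc_result`: `points` (data.frame `cutoff`, `tpr`,
#'   `fpr`), `auc`, `youden_cutoff`.
#' @export
roc_curve <- function(controls) {
  truth <- controls$truth
  score <- controls$score
  if (!all(truth %in% c("benign", "pathogenic"))) {
    stop("truth must be 'benign' or 'pathogenic'")
  }
  n_pos <- sum(truth == "pathogenic")
  n_neg <- sum(truth == "benign")
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC requires at least one control of each truth class")
  }
  cutoffs <- c(-Inf, sort(unique(score)))
  tpr <- vapply(cutoffs, function(t) {
    sum(score <= t & truth == "pathogenic") / n_pos
  }, numeric(1L))
  fpr <- vapply(cutoffs, function(t) {
    sum(score <= t & truth == "benign") / n_neg
  }, numeric(1L))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  j <- tpr - fpr
  list(points = data.frame(cutoff = cutoffs, tpr = tpr, fpr = fpr),
       auc = auc,
       youden_cutoff = cutoffs[which.max(j)]) |>
    structure(class = "roc_result")
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Used for the sensitivity and specificity CIs. In the boundary case
#' `successes == trials` the lower limit has the closed form
#' `trials / (trials + z^2)`.
#'
#' @param successes,trials Counts with `0 <= successes <= trials`,
#'   `trials >= 1`.
#' @param confidence Two-sided confidence level; default 0.95.
#' @return Numeric `c(lower, upper)` in \[0,1\].
#' @export
wilson_interval <- function(successes, trials, confidence = 0.95) {
  if (trials < 1) stop("wilson_interval: trials must be >= 1")
  if (successes < 0 || successes > trials) {
    stop("wilson_interval: need 0 <= successes <= trials")
  }
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  center <- (p + z^2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' OddsPath of a functional assay from its control confusion matrix
#'
#' Implements the functional-evidence calibration of the ClinGen SVI
#' framework (Brnich et al.): `P1` is the prior proportion of pathogenic
#' variants among all controls; `P2` is the proportion of pathogenic
#' variants within a readout class (abnormal for the pathogenic OddsPath,
#' normal for the benign OddsPath); and
#' `OddsPath = (P2 * (1 - P1)) / ((1 - P2) * P1)`. When a readout class is
#' pure (`P2` would be 0 or 1), one hypothetical control of the opposite
#' truth is added to that class before computing `P2` — the framework's
#' correction for assays with a perfect binary readout.
#'
#' @param path_abnormal,path_normal Pathogenic controls with abnormal /
#'   normal readout.
#' @param benign_abnormal,benign_normal Benign controls with abnormal /
#'   normal readout.
#' @return List: `oddspath_pathogenic`, `oddspath_benign`, `p1`,
#'   `p2_abnormal`, `p2_normal`.
#' @export
compute_oddspath <- function(path_abnormal, path_normal,
                             benign_abnormal, benign_normal) {
  counts <- c(path_abnormal, path_normal, benign_abnormal, benign_normal)
  if (any(counts < 0)) stop("confusion-matrix counts must be non-negative")
  n_path <- path_abnormal + path_normal
  n_benign <- benign_abnormal + benign_normal
  if (n_path == 0L || n_benign == 0L) {
    stop("need at least one pathogenic and one benign control")
  }
  if (path_abnormal + benign_abnormal == 0L) {
    stop("empty readout class: no controls with abnormal readout")
  }
  if (path_normal + benign_normal == 0L) {
    stop("empty readout class: no controls with normal readout")
  }
  p1 <- n_path / (n_path + n_benign)

  p2_of <- function(n_path_in, n_benign_in) {
    # pure-class correction: one hypothetical opposite-truth control
    if (n_benign_in == 0L) n_benign_in <- 1L
    else if (n_path_in == 0L) n_path_in <- 1L
    n_path_in / (n_path_in + n_benign_in)
  }
  p2_abn <- p2_of(path_abnormal, benign_abnormal)
  p2_nrm <- p2_of(path_normal, benign_normal)
  oddspath <- function(p2) (p2 * (1 - p1)) / ((1 - p2) * p1)
  list(oddspath_pathogenic = oddspath(p2_abn),
       oddspath_benign = oddspath(p2_nrm),
       p1 = p1, p2_abnormal = p2_abn, p2_normal = p2_nrm)
}

#' Map an OddsPath value to ACMG evidence strength
#'
#' Cutpoints from the SVI functional-evidence calibration: pathogenic
#' OddsPath >= 350 very strong, >= 18.7 strong, >= 4.3 moderate, >= 2.1
#' supporting; benign OddsPath (reciprocal scale) <= 0.00285 very strong,
#' <= 0.053 strong, <= 0.23 moderate, <= 0.48 supporting. Anything weaker is
#' indeterminate.
#'
#' @param value Positive OddsPath value.
#' @param direction `"pathogenic"` or `"benign"`.
#' @return One of `"indeterminate"`, `"supporting"`, `"moderate"`,
#'   `"strong"`, `"very_strong"`.
#' @export
strength_from_oddspath <- function(value,
                                   direction = c("pathogenic", "benign")) {
  direction <- match.arg(direction)
  if (!is.finite(value) || value <= 0) stop("OddsPath must be positive")
  if (direction == "pathogenic") {
    if (value >= 350) "very_strong"
    else if (value >= 18.7) "strong"
    else if (value >= 4.3) "moderate"
    else if (value >= 2.1) "supporting"
    else "indeterminate"
  } else {
    if (value <= 0.00285) "very_strong"
    else if (value <= 0.053) "strong"
    else if (value <= 0.23) "moderate"
    else if (value <= 0.48) "supporting"
    else "indeterminate"
  }
}

#' Calibrate the assay from classified control variants
#'
#' Builds the control readout at the configured thresholds (abnormal =
#' score at or below the deleterious threshold; normal readout for
#' specificity = score above the neutral threshold), estimates sensitivity
#' and specificity with Wilson CIs, computes the ROC/AUC and the OddsPath
#' pair, and maps the OddsPath values to PS3/BS3 strengths. Controls with a
#' risk-allele role must not be included (exclude by role upstream, as the
#' assay excludes conflicting-classification variants from calibration).
#'
#' @param controls Data.frame with columns `variant_id`, `truth`
#'   (`"benign"` / `"pathogenic"`) and `score` (the [calibration_score()],
#'   percent).
#' @param threshold_deleterious,threshold_neutral Category thresholds in
#'   percent; defaults 25 and 50.
#' @param confidence Confidence level for the Wilson CIs.
#' @return List of class `calibration_result`: thresholds, `auc`,
#'   `youden_cutoff`, `sensitivity`, `specificity`, `sens_ci`, `spec_ci`,
#'   the [compute_oddspath()] fields, and `ps3_strength` / `bs3_strength`.
#' @export
calibrate_assay <- function(controls, threshold_deleterious = 25,
                            threshold_neutral = 50, confidence = 0.95) {
  if (threshold_deleterious <= 0 || threshold_deleterious >= threshold_neutral) {
    stop("need 0 < threshold_deleterious < threshold_neutral")
  }
  roc <- roc_curve(controls)
  is_path <- controls$truth == "pathogenic"
  abnormal <- controls$score <= threshold_deleterious
  normal <- controls$score > threshold_neutral
  n_path <- sum(is_path)
  n_benign <- sum(!is_path)
  sens_k <- sum(abnormal & is_path)
  spec_k <- sum(normal & !is_path)
  op <- compute_oddspath(path_abnormal = sum(is_path & abnormal),
                         path_normal = sum(is_path & !abnormal),
                         benign_abnormal = sum(!is_path & abnormal),
                         benign_normal = sum(!is_path & !abnormal))
  structure(c(list(threshold_deleterious = threshold_deleterious,
                   threshold_neutral = threshold_neutral,
                   auc = roc$auc, youden_cutoff = roc$youden_cutoff,
                   sensitivity = sens_k / n_path,
                   specificity = spec_k / n_benign,
                   sens_ci = wilson_interval(sens_k, n_path, confidence),
                   spec_ci = wilson_interval(spec_k, n_benign, confidence),
                   n_pathogenic = n_path, n_benign = n_benign),
              op,
              list(ps3_strength = strength_from_oddspath(
                     op$oddspath_pathogenic, "pathogenic"),
                   bs3_strength = strength_from_oddspath(
                     op$oddspath_benign, "benign"))),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Assay calibration\n")
  cat(sprintf("  thresholds: deleterious <= %.1f%%, neutral > %.1f%%\n",
              x$threshold_deleterious, x$threshold_neutral))
  cat(sprintf("  controls: %d pathogenic, %d benign; AUC = %.3f\n",
              x$n_pathogenic, x$n_benign, x$auc))
  cat(sprintf("  sensitivity = %.1f%% (95%% CI %.1f-%.1f%%)\n",
              100 * x$sensitivity, 100 * x$sens_ci[["lower"]],
              100 * x$sens_ci[["upper"]]))
  cat(sprintf("  specificity = %.1f%% (95%% CI %.1f-%.1f%%)\n",
              100 * x$specificity, 100 * x$spec_ci[["lower"]],
              100 * x$spec_ci[["upper"]]))
  cat(sprintf("  OddsPath: pathogenic = %.3f (%s), benign = %.3f (%s)\n",
              x$oddspath_pathogenic, x$ps3_strength,
              x$oddspath_benign, x$bs3_strength))
  invisible(x)
}
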