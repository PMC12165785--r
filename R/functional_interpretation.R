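#' Categorize a replicate-mean normalized ratio
#'
#' Boundaries follow the assay's printed inequalities: deleterious at or
#' below the deleterious threshold (<= 25%), intermediate above it up to and
#' including the neutral threshold (25--50%], neutral above that (> 50%).
#' Categorization uses the replicate mean, which is what is plotted against
#' the threshold lines.
#'
#' @param mean_ratio Numeric vector of replicate-mean normalized ratios
#'   (percent, >= 0).
#' @param thresholds Numeric `c(deleterious, neutral)`; defaults `c(25, 50)`.
#' @return Character vector over `"deleterious"`, `"intermediate"`,
#'   `"neutral"`.
#' @export
categorize <- function(mean_ratio, thresholds = c(deleterious = 25,
                                                  neutral = 50)) {
  if (any(mean_ratio < 0)) stop("normalized ratio cannot be negative")
  ifelse(mean_ratio <= thresholds[[1L]], "deleterious",
         ifelse(mean_ratio <= thresholds[[2L]], "intermediate", "neutral"))
}

#' Assign the PS3/BS3 functional evidence code from per-condition calls
#'
#' The mapping rule of the assay: a deleterious call in \emph{any} arm
#' (untreated or drug selection) triggers PS3 at the calibrated strength;
#' otherwise an intermediate call in any arm yields PS3 at indeterminate
#' strength (0 points — chosen so hypomorphic variants are not pushed toward
#' benign); only a variant neutral in \emph{every} arm receives BS3 at the
#' calibrated strength. Invariant to the order of conditions.
#'
#' @param calls Character vector of per-condition categories (QC-passing
#'   conditions only).
#' @param ps3_strength,bs3_strength Calibrated strengths, normally from
#'   [calibrate_assay()]; defaults `"moderate"` (the strength an OddsPath of
#'   9 / 0.071 supports).
#' @return An [evidence_code()]: PS3 (moderate or indeterminate) or BS3.
#' @export
assign_functional_code <- function(calls, ps3_strength = "moderate",
                                   bs3_strength = "moderate") {
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0L) stop("no categorized conditions")
  if (!all(calls %in% c("neutral", "intermediate", "deleterious"))) {
    stop("unknown functional category")
  }
  if (any(calls == "deleterious")) {
    evidence_code("PS3", "pathogenic", ps3_strength)
  } else if (any(calls == "intermediate")) {
    evidence_code("PS3", "pathogenic", "indeterminate")
  } else {
    evidence_code("BS3", "benign", bs3_strength)
  }
}

#' Per-variant functional calls for a ratio summary table
#'
#' Categorizes every QC-passing day-12 condition of every variant and
#' derives the overall PS3/BS3 code. Variants with no QC-passing day-12
#' condition are reported as not assessable (`NA` code).
#'
#' @param summary_df Summary data.frame from [summarize_ratios()].
#' @param calibration Optional `calibration_result`; supplies strengths and
#'   thresholds.
#' @param thresholds Used when `calibration` is `NULL`.
#' @return Data.frame: `variant_id`, one `cat_<condition>` column per
#'   day-12 arm, `overall_code` (`"PS3"` / `"BS3"` / `NA`),
#'   `overall_strength`.
#' @export
functional_calls <- function(summary_df, calibration = NULL,
                             thresholds = c(deleterious = 25, neutral = 50)) {
  ps3 <- "moderate"
  bs3 <- "moderate"
  if (!is.null(calibration)) {
    thresholds <- c(deleterious = calibration$threshold_deleterious,
                    neutral = calibration$threshold_neutral)
    ps3 <- calibration$ps3_strength
    bs3 <- calibration$bs3_strength
  }
  vids <- unique(summary_df$variant_id)
  cat_cols <- paste0("cat_", DAY12_CONDITIONS)
  out <- data.frame(variant_id = vids, stringsAsFactors = FALSE)
  for (col in cat_cols) out[[col]] <- rep(NA_character_, length(vids))
  if (length(vids) == 0L) {
    out$overall_code <- character(0)
    out$overall_strength <- character(0)
    return(out)
  }
  out$overall_code <- NA_character_
  out$overall_strength <- NA_character_
  for (i in seq_along(vids)) {
    s <- summary_df[summary_df$variant_id == vids[i] &
                      summary_df$condition %in% DAY12_CONDITIONS, ,
                    drop = FALSE]
    if (nrow(s) == 0L) next  # not assessable
    cats <- categorize(s$mean, thresholds)
    out[i, paste0("cat_", s$condition)] <- cats
    code <- assign_functional_code(cats, ps3, bs3)
    out$overall_code[i] <- code$code_id
    out$overall_strength[i] <- code$strength
  }
  out
}
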