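#' Variant/WT' (or frameshift/WT') read-count ratio for one sample
#'
#' The raw functional readout: the ratio of variant-edited (or
#' frameshift-indel) reads to WT'-edited reads within one sample. A zero
#' WT' count makes the ratio undefined; it raises an error so the sample is
#' flagged rather than silently dropped (an optional +0.5 pseudocount mode
#' exists but is off by default).
#'
#' @param sc One-row sample-counts data.frame.
#' @param numerator `"variant"` or `"frameshift"`.
#' @param pseudocount Added to both numerator and denominator when > 0;
#'   default 0 (no smoothing).
#' @return Dimensionless ratio.
#' @export
compute_ratio <- function(sc, numerator = c("variant", "frameshift"),
                          pseudocount = 0) {
  numerator <- match.arg(numerator)
  num <- sc[[paste0(numerator, "_reads")]]
  den <- sc$wtprime_reads
  if (pseudocount > 0) {
    num <- num + pseudocount
    den <- den + pseudocount
  }
  if (any(den == 0)) {
    stop("wtprime_reads is zero for sample ", sc$variant_id, "/",
         sc$condition, "/rep", sc$replicate_id,
         ": variant/WT' ratio undefined")
  }
  num / den
}

#' Normalize a day-12 ratio to its day-2 baseline
#'
#' The day-2 variant/WT' ratio is set at 100%; a day-X ratio is expressed
#' relative to it. The day-2 sample itself therefore always normalizes to
#' exactly 100.
#'
#' @param day2_ratio Day-2 raw ratio (> 0).
#' @param dayx_ratio Day-X raw ratio (>= 0).
#' @return Normalized ratio in percent: `100 * dayx_ratio / day2_ratio`.
#' @export
normalize_to_day2 <- function(day2_ratio, dayx_ratio) {
  if (any(day2_ratio <= 0)) {
    stop("day-2 variant/WT' ratio must be positive to normalize")
  }
  100 * dayx_ratio / day2_ratio
}

#' Aggregate per-replicate normalized ratios
#'
#' Replicates are normalized individually first, then averaged; the spread
#' is the sample standard deviation (n - 1 denominator). A single replicate
#' yields sd = 0 with a warning (no spread is estimable).
#'
#' @param values Numeric vector of per-replicate normalized ratios
#'   (percent).
#' @return List with `mean`, `sd` and `n`.
#' @export
aggregate_replicates <- function(values) {
  if (length(values) == 0L) stop("no replicate values to aggregate")
  n <- length(values)
  if (n == 1L) {
    warning("single replicate: standard deviation reported as 0")
    return(list(mean = values, sd = 0, n = 1L))
  }
  list(mean = mean(values), sd = stats::sd(values), n = n)
}

#' Per-replicate day-2-normalized ratios for a set of samples
#'
#' For every \{variant, replicate\} the day-2 raw ratio is computed once and
#' each condition's raw ratio (day 2 included) is normalized to it. Samples
#' failing the read-depth QC are excluded; if a replicate's day-2 sample
#' fails, the whole replicate is excluded for that variant.
#'
#' @param counts Sample-counts data.frame.
#' @param numerator `"variant"` or `"frameshift"`.
#' @param min_reads QC minimum depth; `NULL` disables QC.
#' @param pseudocount See [compute_ratio()].
#' @return Data.frame `variant_id`, `condition`, `replicate_id`,
#'   `raw_ratio`, `normalized_ratio` (percent; exactly 100 for every day-2
#'   row). Attribute `"qc_failures"` holds the excluded samples.
#' @export
normalized_ratios <- function(counts, numerator = c("variant", "frameshift"),
                              min_reads = 7500L, pseudocount = 0) {
  numerator <- match.arg(numerator)
  failures <- counts[0, ]
  if (!is.null(min_reads)) {
    counts <- qc_check(counts, min_reads)
    failures <- counts[!counts$qc_pass, , drop = FALSE]
    counts <- counts[counts$qc_pass, , drop = FALSE]
  }
  out <- vector("list", nrow(counts))
  k <- 0L
  for (vid in unique(counts$variant_id)) {
    cv <- counts[counts$variant_id == vid, , drop = FALSE]
    for (rep_i in unique(cv$replicate_id)) {
      cr <- cv[cv$replicate_id == rep_i, , drop = FALSE]
      d2 <- cr[cr$condition == "day2", , drop = FALSE]
      if (nrow(d2) != 1L) next  # day-2 baseline missing or QC-failed
      r2 <- compute_ratio(d2, numerator, pseudocount)
      for (i in seq_len(nrow(cr))) {
        rx <- compute_ratio(cr[i, ], numerator, pseudocount)
        k <- k + 1L
        out[[k]] <- data.frame(
          variant_id = vid, condition = cr$condition[i],
          replicate_id = rep_i, raw_ratio = rx,
          normalized_ratio = if (cr$condition[i] == "day2") 100
                             else normalize_to_day2(r2, rx),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (k) do.call(rbind, out[seq_len(k)]) else
    data.frame(variant_id = character(), condition = character(),
               replicate_id = character(), raw_ratio = numeric(),
               normalized_ratio = numeric(), stringsAsFactors = FALSE)
  attr(res, "qc_failures") <- failures
  res
}

#' Replicate mean and SD per variant and condition
#'
#' @param ratios Data.frame from [normalized_ratios()].
#' @return Data.frame `variant_id`, `condition`, `mean`, `sd`, `n`.
#' @export
summarize_ratios <- function(ratios) {
  if (nrow(ratios) == 0L) {
    return(data.frame(variant_id = character(), condition = character(),
                      mean = numeric(), sd = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- interaction(ratios$variant_id, ratios$condition, drop = TRUE)
  parts <- split(ratios, key)
  out <- lapply(parts, function(p) {
    agg <- suppressWarnings(aggregate_replicates(p$normalized_ratio))
    data.frame(variant_id = p$variant_id[1L], condition = p$condition[1L],
               mean = agg$mean, sd = agg$sd, n = agg$n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res[order(res$variant_id, match(res$condition, CONDITIONS)), ]
}

#' Frameshift internal-control depletion report
#'
#' Frameshift indels arise from unrepaired nuclease cuts and act as an
#' inbuilt null-effect control: their normalized frameshift/WT' ratio should
#' be strongly depleted by day 12 in every arm. A condition is flagged
#' `depleted` when its replicate mean lies below `100 - k * sd`; the flag is
#' a run-level QC gate, not a variant call.
#'
#' @param fs_summary Summary data.frame from [summarize_ratios()] computed
#'   with `numerator = "frameshift"`.
#' @param k Multiplier on the replicate SD; default 2.
#' @return `fs_summary` restricted to day-12 rows with logical column
#'   `depleted` appended.
#' @export
frameshift_selection_report <- function(fs_summary, k = 2) {
  out <- fs_summary[fs_summary$condition != "day2", , drop = FALSE]
  out$depleted <- out$mean < 100 - k * out$sd
  row.names(out) <- NULL
  out
}
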