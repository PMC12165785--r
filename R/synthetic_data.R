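#' True effect profile for a simulated variant
#'
#' The generator parameterizes selection directly by the target
#' day-2-normalized variant/WT' ratio in each day-12 arm, so the generative
#' truth is identical to the measurand. Day-2 homology-directed-repair (HDR)
#' incorporation fractions are free parameters (the assay does not fix them);
#' defaults are realistic knockin rates: 10% variant, 10% WT', 20% frameshift
#' indels from unrepaired cuts, the remainder unedited/other.
#'
#' @param variant_id Variant label.
#' @param true_ratio Target normalized ratio in percent, either a single
#'   value recycled over the four day-12 arms or a named vector over
#'   [DAY12_CONDITIONS]. Values in \[0, 150\].
#' @param day2_fractions Named numeric `(variant, wtprime, frameshift,
#'   other)`, each in \[0,1\], summing to at most 1.
#' @param replicate_cv Coefficient of variation of the multiplicative
#'   log-normal replicate noise applied to the day-12 variant fraction.
#' @return A list of class `true_effect_profile`.
#' @export
true_effect_profile <- function(variant_id, true_ratio,
                                day2_fractions = c(variant = 0.10,
                                                   wtprime = 0.10,
                                                   frameshift = 0.20,
                                                   other = 0.60),
                                replicate_cv = 0.1) {
  if (length(true_ratio) == 1L) {
    true_ratio <- stats::setNames(rep(true_ratio, length(DAY12_CONDITIONS)),
                                  DAY12_CONDITIONS)
  }
  if (!all(DAY12_CONDITIONS %in% names(true_ratio))) {
    stop("true_ratio must be defined for all four day-12 conditions")
  }
  true_ratio <- true_ratio[DAY12_CONDITIONS]
  if (any(true_ratio < 0 | true_ratio > 150)) {
    stop("true_ratio must lie in [0, 150] percent")
  }
  f <- day2_fractions[c("variant", "wtprime", "frameshift", "other")]
  if (anyNA(f) || any(f < 0) || sum(f) > 1 + 1e-12) {
    stop("day2_fractions must be non-negative and sum to at most 1")
  }
  if (replicate_cv < 0) stop("replicate_cv must be >= 0")
  structure(list(variant_id = variant_id, true_ratio = true_ratio,
                 day2_fractions = f, replicate_cv = replicate_cv),
            class = "true_effect_profile")
}

#' Simulation configuration
#'
#' @param n_reads Reads per sample; default 7500, the QC-passing minimum
#'   depth of the assay.
#' @param n_replicates Biological replicates; default (and reporting
#'   minimum) 3.
#' @param frameshift_day12_retention Fraction of the day-2 frameshift class
#'   surviving to day 12, in \[0,1\]. Default 0.2, i.e. strong negative
#'   selection against frameshift indels, the assay's internal null control.
#' @param seed Mandatory integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_reads = 7500L, n_replicates = 3L,
                              frameshift_day12_retention = 0.2, seed) {
  if (missing(seed) || !is.numeric(seed)) {
    stop("a numeric seed is required for reproducibility")
  }
  stopifnot(n_reads >= 1, n_replicates >= 1,
            frameshift_day12_retention >= 0,
            frameshift_day12_retention <= 1)
  structure(list(n_reads = as.integer(n_reads),
                 n_replicates = as.integer(n_replicates),
                 frameshift_day12_retention = frameshift_day12_retention,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Internal: log-normal multiplier with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate per-sample read-class counts for one variant
#'
#' Draws one multinomial sample of `n_reads` reads per \{condition,
#' replicate\}. Day-2 class probabilities are the profile's HDR fractions.
#' In each day-12 arm the variant fraction is rescaled by
#' `true_ratio / 100` (so that in expectation the day-12/day-2 variant/WT'
#' ratio equals the target), the WT' fraction is held at its day-2 value
#' (WT' is the neutral internal reference by design), the frameshift
#' fraction is multiplied by `frameshift_day12_retention`, and the `other`
#' class absorbs the remainder. Replicate-level multiplicative log-normal
#' noise with coefficient of variation `replicate_cv` is applied to the
#' day-12 variant fraction before sampling.
#'
#' @param profile A [true_effect_profile()].
#' @param cfg A [simulation_config()]. When `reseed = TRUE` (default) the
#'   RNG is seeded from `cfg$seed` so identical inputs give identical
#'   outputs.
#' @param reseed Set `FALSE` when the caller manages the RNG stream (e.g.
#'   [simulate_panel()]).
#' @return Sample-counts data.frame, one row per \{condition, replicate\};
#'   class counts sum to `cfg$n_reads` in every row.
#' @export
simulate_counts <- function(profile, cfg, reseed = TRUE) {
  stopifnot(inherits(profile, "true_effect_profile"),
            inherits(cfg, "simulation_config"))
  if (reseed) set.seed(cfg$seed)
  f <- profile$day2_fractions
  out <- vector("list", length(CONDITIONS) * cfg$n_replicates)
  k <- 0L
  for (rep_i in seq_len(cfg$n_replicates)) {
    for (cond in CONDITIONS) {
      if (cond == "day2") {
        p <- c(f[["variant"]], f[["wtprime"]], f[["frameshift"]],
               1 - f[["variant"]] - f[["wtprime"]] - f[["frameshift"]])
      } else {
        fv <- f[["variant"]] * profile$true_ratio[[cond]] / 100 *
          rlnorm_cv(1L, profile$replicate_cv)
        ffs <- f[["frameshift"]] * cfg$frameshift_day12_retention
        if (fv + f[["wtprime"]] + ffs > 1) {
          stop("rescaled class fractions leave the simplex for ",
               profile$variant_id, " in ", cond,
               "; mis-specified profile (true_ratio or fractions too large)")
        }
        p <- c(fv, f[["wtprime"]], ffs, 1 - fv - f[["wtprime"]] - ffs)
      }
      draws <- stats::rmultinom(1L, cfg$n_reads, p)[, 1L]
      k <- k + 1L
      out[[k]] <- data.frame(variant_id = profile$variant_id,
                             condition = cond, replicate_id = rep_i,
                             variant_reads = draws[1L],
                             wtprime_reads = draws[2L],
                             frameshift_reads = draws[3L],
                             other_reads = draws[4L],
                             total_reads = sum(draws),
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Generate a variant panel with ground-truth effects and annotations
#'
#' Emulates the composition of a control + query panel: benign controls have
#' true normalized ratios above the neutral threshold in all arms,
#' pathogenic controls sit deep in the deleterious range in all arms, and
#' query variants are drawn from neutral / intermediate / deleterious strata
#' (default stratum weights 45:2:7, the composition observed for the 54
#' assayed VUS). Annotations are sampled consistently with the stratum;
#' notably, deleterious query variants still carry low in-silico
#' deleteriousness scores (BayesDel <= 0.18), mirroring the discordance
#' between metapredictors and functional effect in the PALB2-binding domain.
#'
#' @param n_benign_controls,n_pathogenic_controls,n_query Non-negative
#'   counts.
#' @param seed Integer seed.
#' @param query_strata Named weights for the query strata
#'   `(neutral, intermediate, deleterious)`.
#' @return A data.frame with one row per variant: `variant_id`, `role`
#'   (`control_benign` / `control_pathogenic` / `query`), `stratum`, the
#'   four `true_<condition>` ratio columns, and annotation columns
#'   `faf_max`, `maf_max`, `bayesdel_noaf`, `spliceai_delta`,
#'   `asserted_codes` (semicolon-separated `code:strength`, usually empty).
#' @export
generate_variant_panel <- function(n_benign_controls, n_pathogenic_controls,
                                   n_query, seed,
                                   query_strata = c(neutral = 45,
                                                    intermediate = 2,
                                                    deleterious = 7)) {
  counts <- c(n_benign_controls, n_pathogenic_controls, n_query)
  if (any(counts < 0)) stop("panel counts must be non-negative")
  set.seed(seed)
  n <- sum(counts)
  empty <- data.frame(variant_id = character(), role = character(),
                      stratum = character(),
                      true_day12_untreated = numeric(),
                      true_day12_parpi = numeric(),
                      true_day12_cisplatin = numeric(),
                      true_day12_mmc = numeric(),
                      faf_max = numeric(), maf_max = numeric(),
                      bayesdel_noaf = numeric(), spliceai_delta = numeric(),
                      asserted_codes = character(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)

  role <- rep(c("control_benign", "control_pathogenic", "query"), counts)
  stratum <- character(n)
  stratum[role == "control_benign"] <- "neutral"
  stratum[role == "control_pathogenic"] <- "deleterious"
  if (n_query > 0) {
    stratum[role == "query"] <- sample(names(query_strata), n_query,
                                       replace = TRUE,
                                       prob = query_strata / sum(query_strata))
  }

  draw_ratios <- function(s, is_control) {
    lim <- switch(s,
                  neutral = if (is_control) c(70, 110) else c(60, 110),
                  intermediate = c(28, 48),
                  deleterious = if (is_control) c(0, 15) else c(0, 20))
    stats::runif(4L, lim[1L], lim[2L])
  }
  ratios <- t(vapply(seq_len(n), function(i) {
    draw_ratios(stratum[i], grepl("^control", role[i]))
  }, numeric(4L)))
  colnames(ratios) <- paste0("true_", DAY12_CONDITIONS)

  faf <- rep(NA_real_, n)
  maf <- rep(NA_real_, n)
  bayesdel <- numeric(n)
  spliceai <- numeric(n)
  for (i in seq_len(n)) {
    if (role[i] == "control_benign") {
      faf[i] <- stats::runif(1, 1e-4, 1e-3)          # BS1 band
      maf[i] <- faf[i] * stats::runif(1, 1, 2)
      bayesdel[i] <- stats::runif(1, 0, 0.18)
      spliceai[i] <- stats::runif(1, 0, 0.1)
    } else if (role[i] == "control_pathogenic") {
      bayesdel[i] <- stats::runif(1, 0.30, 0.60)     # DBD-style controls
      spliceai[i] <- stats::runif(1, 0, 0.1)
    } else {
      # rare query VUS: absent from controls or barely observed
      if (stats::runif(1) < 0.5) maf[i] <- stats::runif(1, 1e-6, 2e-5)
      bayesdel[i] <- stats::runif(1, 0, 0.18)        # PBD discordance
      spliceai[i] <- if (stratum[i] == "deleterious" &&
                         stats::runif(1) < 4 / 7) {
        stats::runif(1, 0.2, 0.9)                    # splice-region effect
      } else {
        stats::runif(1, 0, 0.1)
      }
    }
  }

  data.frame(variant_id = sprintf("c.%d%s>%s", seq_len(n) * 3L,
                                  sample(c("A", "C", "G", "T"), n, TRUE),
                                  sample(c("A", "C", "G", "T"), n, TRUE)),
             role = role, stratum = stratum, ratios,
             faf_max = faf, maf_max = maf, bayesdel_noaf = round(bayesdel, 4),
             spliceai_delta = round(spliceai, 4),
             asserted_codes = "", stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Simulate counts for a whole panel
#'
#' Derives a per-variant seed from `cfg$seed` (kept below 2^31) so each
#' variant's counts are individually reproducible, then calls
#' [simulate_counts()] for every panel row.
#'
#' @param panel Data.frame from [generate_variant_panel()].
#' @param cfg A [simulation_config()].
#' @inheritParams true_effect_profile
#' @return Sample-counts data.frame over all variants.
#' @export
simulate_panel <- function(panel, cfg,
                           day2_fractions = c(variant = 0.10, wtprime = 0.10,
                                              frameshift = 0.20,
                                              other = 0.60),
                           replicate_cv = 0.1) {
  out <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    prof <- true_effect_profile(
      panel$variant_id[i],
      stats::setNames(as.numeric(panel[i, paste0("true_", DAY12_CONDITIONS)]),
                      DAY12_CONDITIONS),
      day2_fractions = day2_fractions, replicate_cv = replicate_cv)
    cfg_i <- cfg
    cfg_i$seed <- as.integer((cfg$seed + 7919 * i) %% .Machine$integer.max)
    out[[i]] <- simulate_counts(prof, cfg_i)
  }
  do.call(rbind, out)
}

#' Generate synthetic edit definitions for a panel
#'
#' Builds, deterministically from the seed, a random reference amplicon per
#' variant plus the two expected edited amplicons: the variant edit is a
#' substitution at the amplicon midpoint and the WT' edit a substitution
#' three bases downstream (synonymous-position spacing).
#'
#' @param panel Panel data.frame (only `variant_id` is used).
#' @param seed Integer seed.
#' @param amplicon_length Length of the synthetic amplicons.
#' @return Named list of [edit_definition()] objects keyed by `variant_id`.
#' @export
make_edit_definitions <- function(panel, seed, amplicon_length = 60L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  defs <- vector("list", nrow(panel))
  names(defs) <- panel$variant_id
  mid <- amplicon_length %/% 2L
  for (i in seq_len(nrow(panel))) {
    ref <- sample(bases, amplicon_length, replace = TRUE)
    sub_at <- function(s, pos) {
      s[pos] <- sample(setdiff(bases, s[pos]), 1L)
      s
    }
    var <- sub_at(ref, mid)
    wtp <- sub_at(ref, mid + 3L)
    defs[[i]] <- edit_definition(panel$variant_id[i],
                                 paste(ref, collapse = ""),
                                 paste(var, collapse = ""),
                                 paste(wtp, collapse = ""))
  }
  defs
}

# Internal: filesystem-safe sample file name
sample_file_name <- function(variant_id, condition, replicate_id) {
  safe <- gsub("[^A-Za-z0-9._-]", "_", variant_id)
  sprintf("%s__%s__rep%s.tsv", safe, condition, replicate_id)
}

#' Write per-sample allele tables in the ingest dialect
#'
#' Emits one tab-delimited allele table per sample row: an exact-match row
#' for the variant amplicon, one for the WT' amplicon, the frameshift reads
#' split over 1-bp and 2-bp deletion alleles (net indel length not divisible
#' by 3 by construction), and the unedited reference row carrying the
#' `other` reads. Writing then re-ingesting is the identity on the sample
#' counts.
#'
#' @param samples Sample-counts data.frame.
#' @param edit_defs Named list of [edit_definition()] objects.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest data.frame (`file`, `variant_id`,
#'   `condition`, `replicate_id`), also written to `manifest.tsv` in
#'   `out_dir`. An empty sample set yields no files and an empty manifest.
#' @export
write_allele_tables <- function(samples, edit_defs, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(file = character(), variant_id = character(),
                         condition = character(), replicate_id = character(),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    ed <- edit_defs[[s$variant_id]]
    if (is.null(ed)) stop("no edit definition for variant ", s$variant_id)
    fs1 <- s$frameshift_reads %/% 2L
    fs2 <- s$frameshift_reads - fs1
    ref <- ed$reference_amplicon
    del <- function(k) substr(ref, 1L, nchar(ref) - k)  # k-bp deletion allele
    tab <- data.frame(
      Aligned_Sequence = c(ed$variant_amplicon, ed$wtprime_amplicon,
                           del(1L), del(2L), ref),
      Reads = c(s$variant_reads, s$wtprime_reads, fs1, fs2, s$other_reads),
      n_inserted = c(0L, 0L, 0L, 0L, 0L),
      n_deleted = c(0L, 0L, 1L, 2L, 0L),
      stringsAsFactors = FALSE)
    fn <- sample_file_name(s$variant_id, s$condition, s$replicate_id)
    utils::write.table(tab, file.path(out_dir, fn), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest[nrow(manifest) + 1L, ] <- list(fn, s$variant_id, s$condition,
                                            as.character(s$replicate_id))
  }
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
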