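test_that("panel generation respects counts, roles and seeded determinism", {
  panel <- generate_variant_panel(9, 14, 54, seed = 1)
  expect_equal(nrow(panel), 77L)
  expect_equal(as.integer(table(panel$role)[c("control_benign",
                                              "control_pathogenic", "query")]),
               c(9L, 14L, 54L))
  expect_identical(panel, generate_variant_panel(9, 14, 54, seed = 1))
  expect_false(identical(panel, generate_variant_panel(9, 14, 54, seed = 2)))
  expect_equal(nrow(generate_variant_panel(0, 0, 0, seed = 1)), 0L)
  expect_error(generate_variant_panel(-1, 0, 0, seed = 1), "non-negative")
})

test_that("control strata have the functional separation calibration assumes", {
  panel <- generate_variant_panel(20, 20, 0, seed = 7)
  rcols <- paste0("true_", DAY12_CONDITIONS)
  ben <- as.matrix(panel[panel$role == "control_benign", rcols])
  pat <- as.matrix(panel[panel$role == "control_pathogenic", rcols])
  expect_true(all(ben > 50))                     # neutral in every arm
  expect_true(all(apply(pat, 1, min) <= 25))     # deleterious somewhere
  expect_true(all(panel$bayesdel_noaf >= 0 & panel$bayesdel_noaf <= 1))
})

test_that("simulated counts conserve reads and are seed-deterministic", {
  prof <- true_effect_profile("v1", 60)
  cfg <- simulation_config(seed = 11)
  counts <- simulate_counts(prof, cfg)
  expect_equal(nrow(counts), length(CONDITIONS) * cfg$n_replicates)
  expect_true(all(counts$variant_reads + counts$wtprime_reads +
                    counts$frameshift_reads + counts$other_reads ==
                    cfg$n_reads))
  expect_identical(counts, simulate_counts(prof, cfg))
})

test_that("a lethal arm yields zero variant reads with WT' unaffected", {
  prof <- true_effect_profile("v1", c(day12_untreated = 0,
                                      day12_parpi = 100,
                                      day12_cisplatin = 100,
                                      day12_mmc = 100),
                              replicate_cv = 0)
  counts <- simulate_counts(prof, simulation_config(n_reads = 50000L,
                                                    seed = 3))
  dead <- counts[counts$condition == "day12_untreated", ]
  expect_true(all(dead$variant_reads == 0L))
  # WT' expectation unchanged: fraction 0.10 of reads
  expect_equal(mean(dead$wtprime_reads) / 50000, 0.10, tolerance = 0.05)
})

test_that("mis-specified profiles that leave the simplex are rejected", {
  prof <- true_effect_profile("v1", 150,
                              day2_fractions = c(variant = 0.7,
                                                 wtprime = 0.2,
                                                 frameshift = 0.05,
                                                 other = 0.05),
                              replicate_cv = 0)
  expect_error(simulate_counts(prof, simulation_config(seed = 1)),
               "simplex")
  expect_error(true_effect_profile("v1", 200), "\\[0, 150\\]")
  expect_error(true_effect_profile("v1", 50,
                                   day2_fractions = c(variant = 0.6,
                                                      wtprime = 0.5,
                                                      frameshift = 0,
                                                      other = 0)),
               "sum")
})

test_that("downstream ratios converge to the profiled truth at high depth", {
  # null effect: true ratio 100% everywhere, cv = 0, one million reads
  prof <- true_effect_profile("null", 100, replicate_cv = 0)
  cfg <- simulation_config(n_reads = 1e6, n_replicates = 3, seed = 5)
  s <- summarize_ratios(normalized_ratios(simulate_counts(prof, cfg),
                                          min_reads = NULL))
  expect_true(all(abs(s$mean[s$condition != "day2"] - 100) < 1))

  prof2 <- true_effect_profile("sel", 40, replicate_cv = 0)
  s2 <- summarize_ratios(normalized_ratios(simulate_counts(prof2, cfg),
                                           min_reads = NULL))
  expect_true(all(abs(s2$mean[s2$condition != "day2"] - 40) < 1))
})

test_that("simulated ratio estimates agree with an independent Monte-Carlo oracle", {
  # Oracle: the generative model re-implemented with sequential binomial
  # splits of the multinomial, vectorized, independent of simulate_counts().
  n <- 10000L
  fv <- 0.10
  fw <- 0.10
  true_ratio <- 20
  cv <- 0.1
  n_sims <- 10000L
  set.seed(400)
  sdlog <- sqrt(log(1 + cv^2))
  oracle_rep <- function(m) {
    v2 <- rbinom(m, n, fv)
    w2 <- rbinom(m, n - v2, fw / (1 - fv))
    fv12 <- fv * true_ratio / 100 *
      rlnorm(m, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    v12 <- rbinom(m, n, fv12)
    w12 <- rbinom(m, n - v12, fw / (1 - fv12))
    100 * (v12 / w12) / (v2 / w2)
  }
  oracle <- rowMeans(matrix(oracle_rep(3L * n_sims), ncol = 3L))
  oracle_mean <- mean(oracle)
  oracle_se <- sd(oracle) / sqrt(n_sims)
  expect_lt(abs(oracle_mean - true_ratio), 1)  # generator is unbiased

  # Implementation: 200 independent 3-replicate experiments
  prof <- true_effect_profile("v", true_ratio, replicate_cv = cv)
  est <- vapply(seq_len(200L), function(s) {
    cfg <- simulation_config(n_reads = n, n_replicates = 3L, seed = 1000 + s)
    r <- normalized_ratios(simulate_counts(prof, cfg), min_reads = NULL)
    mean(r$normalized_ratio[r$condition == "day12_untreated"])
  }, numeric(1L))
  # grand mean within the oracle's sampling band for 200 experiments
  expect_lt(abs(mean(est) - oracle_mean), 4 * sd(oracle) / sqrt(200L))
})

test_that("allele tables round-trip through write + ingest", {
  panel <- generate_variant_panel(1, 1, 2, seed = 9)
  cfg <- simulation_config(n_reads = 8000L, n_replicates = 2L, seed = 9)
  counts <- simulate_panel(panel, cfg)
  edits <- make_edit_definitions(panel, seed = 9)
  dir <- withr::local_tempdir()
  manifest <- write_allele_tables(counts, edits, dir)
  expect_equal(nrow(manifest), nrow(counts))

  back <- ingest_samples(file.path(dir, "manifest.tsv"), edits, dir = dir)
  cols <- c("variant_reads", "wtprime_reads", "frameshift_reads",
            "other_reads", "total_reads")
  key <- function(d) order(d$variant_id, d$condition, d$replicate_id)
  expect_equal(back[key(back), cols], counts[key(counts), cols],
               ignore_attr = TRUE)

  # written frameshift rows all carry a net indel not divisible by 3
  one <- read.delim(file.path(dir, manifest$file[1]))
  fs <- one[one$Aligned_Sequence != edits[[manifest$variant_id[1]]]$variant_amplicon &
              one$Aligned_Sequence != edits[[manifest$variant_id[1]]]$wtprime_amplicon &
              (one$n_inserted - one$n_deleted) != 0, ]
  expect_true(all((fs$n_inserted - fs$n_deleted) %% 3 != 0))
})

test_that("writing an empty sample set yields no sample files", {
  dir <- withr::local_tempdir()
  manifest <- write_allele_tables(sc_row()[0, ], list(), dir)
  expect_equal(nrow(manifest), 0L)
  expect_equal(setdiff(list.files(dir), "manifest.tsv"), character(0))
})
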