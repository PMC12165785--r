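test_that("population code follows the FAF/MAF bands, one code per variant", {
  expect_equal(population_code(faf_max = 0.002)$code_id, "BA1")
  expect_equal(population_code(faf_max = 0.002)$direction,
               "stand_alone_benign")
  bs1 <- population_code(faf_max = 5e-4)
  expect_equal(c(bs1$code_id, bs1$strength), c("BS1", "strong"))
  bs1s <- population_code(faf_max = 5e-5)
  expect_equal(c(bs1s$code_id, bs1s$strength), c("BS1", "supporting"))
  pm2i <- population_code(maf_max = 1e-5)
  expect_equal(c(pm2i$code_id, pm2i$strength), c("PM2", "indeterminate"))
  expect_equal(pm2i$points, 0L)
  pm2 <- population_code()  # absent in controls
  expect_equal(c(pm2$code_id, pm2$strength), c("PM2", "supporting"))
  # boundary: the BA1 band is strictly above 0.001
  expect_equal(population_code(faf_max = 0.001)$code_id, "BS1")
  expect_error(population_code(faf_max = 2), "\\[0,1\\]")
})

test_that("computational code follows the SpliceAI/BayesDel bands with a gap zone", {
  pp3 <- computational_code(bayesdel_noaf = 0.35, spliceai_delta = 0.05)
  expect_equal(c(pp3$code_id, pp3$strength), c("PP3", "supporting"))
  expect_equal(computational_code(0.05, 0.25)$code_id, "PP3")  # and/or
  bp4 <- computational_code(0.10, 0.05)
  expect_equal(c(bp4$code_id, bp4$points), c("BP4", -1L))
  expect_null(computational_code(0.10, 0.15))   # gap zone
  expect_null(computational_code(0.25, 0.05))   # gap zone (BayesDel side)
  expect_null(computational_code(NA, 0.5))      # missing score
  # PP3 suppressed when a PVS1 (RNA) code is asserted
  expect_null(computational_code(0.35, 0.95, pvs1_asserted = TRUE))
})

test_that("asserted splicing codes pass through with PVS1/PS1 exclusion", {
  ps1 <- apply_asserted_splicing_codes("PS1_splicing:moderate")
  expect_length(ps1, 1L)
  expect_equal(ps1[[1]]$points, 2L)
  expect_length(apply_asserted_splicing_codes(""), 0L)
  expect_length(apply_asserted_splicing_codes(NULL), 0L)
  expect_warning(
    both <- apply_asserted_splicing_codes(
      "PVS1_RNA:strong;PS1_splicing:moderate"),
    "dropping")
  expect_equal(vapply(both, `[[`, character(1), "code_id"), "PVS1_RNA")
  expect_error(apply_asserted_splicing_codes("PVS1_RNA"), "malformed")
})

test_that("point values match the published table", {
  expect_equal(points_for("pathogenic", "supporting"), 1L)
  expect_equal(points_for("pathogenic", "moderate"), 2L)
  expect_equal(points_for("pathogenic", "strong"), 4L)
  expect_equal(points_for("pathogenic", "very_strong"), 8L)
  expect_equal(points_for("pathogenic", "indeterminate"), 0L)
  expect_equal(points_for("benign", "supporting"), -1L)
  expect_equal(points_for("benign", "very_strong"), -8L)
  expect_error(evidence_code("BA1", "benign"), "stand-alone")
})

test_that("point totals map to the published class scale", {
  d23h <- list(evidence_code("PVS1_RNA", "pathogenic", "strong"),
               evidence_code("PS3", "pathogenic", "moderate"),
               evidence_code("PM2", "pathogenic", "supporting"))
  expect_equal(combine_points(d23h),
               list(point_total = 7L, point_class = "likely_pathogenic"))

  w31 <- list(evidence_code("PS3", "pathogenic", "moderate"),
              evidence_code("BP4", "benign", "supporting"),
              evidence_code("PM2", "pathogenic", "indeterminate"))
  expect_equal(combine_points(w31),
               list(point_total = 1L, point_class = "uncertain"))

  lb <- list(evidence_code("BS3", "benign", "moderate"),
             evidence_code("BP4", "benign", "supporting"))
  expect_equal(combine_points(lb),
               list(point_total = -3L, point_class = "likely_benign"))

  # scale boundaries, built from very-strong (8) and supporting (1) codes
  cls_at <- function(pts) {
    dir <- if (pts >= 0) "pathogenic" else "benign"
    codes <- c(rep(list(evidence_code(if (pts >= 0) "PS3" else "BS3", dir,
                                      "very_strong")), abs(pts) %/% 8),
               rep(list(evidence_code(if (pts >= 0) "PP3" else "BP4", dir,
                                      "supporting")), abs(pts) %% 8))
    combine_points(codes)$point_class
  }
  expect_equal(cls_at(10), "pathogenic")
  expect_equal(cls_at(9), "likely_pathogenic")
  expect_equal(cls_at(6), "likely_pathogenic")
  expect_equal(cls_at(5), "uncertain")
  expect_equal(cls_at(-1), "uncertain")
  expect_equal(cls_at(-2), "likely_benign")
  expect_equal(cls_at(-7), "benign")

  # BA1 short-circuits regardless of the sum
  ba1 <- list(evidence_code("BA1", "stand_alone_benign", "very_strong"),
              evidence_code("PS3", "pathogenic", "moderate"),
              evidence_code("PP3", "pathogenic", "supporting"))
  expect_equal(combine_points(ba1)$point_class, "benign")
})

test_that("qualitative combining reproduces the worked rule matches", {
  lp <- list(evidence_code("PVS1_RNA", "pathogenic", "strong"),
             evidence_code("PS3", "pathogenic", "moderate"),
             evidence_code("PM2", "pathogenic", "supporting"))
  expect_equal(combine_qualitative(lp), "likely_pathogenic")

  lb <- list(evidence_code("BS3", "benign", "moderate"),
             evidence_code("BP4", "benign", "supporting"))
  expect_equal(combine_qualitative(lb), "likely_benign")

  vus <- list(evidence_code("PS3", "pathogenic", "moderate"),
              evidence_code("PM2", "pathogenic", "supporting"))
  expect_equal(combine_qualitative(vus), "uncertain")

  # indeterminate codes are ignored
  expect_equal(combine_qualitative(c(vus, list(
    evidence_code("PM2", "pathogenic", "indeterminate")))), "uncertain")

  expect_equal(combine_qualitative(list(
    evidence_code("BA1", "stand_alone_benign", "very_strong"))), "benign")

  # two moderates + two supporting reach likely pathogenic
  expect_equal(combine_qualitative(list(
    evidence_code("PS3", "pathogenic", "moderate"),
    evidence_code("PS1_splicing", "pathogenic", "moderate"),
    evidence_code("PP3", "pathogenic", "supporting"),
    evidence_code("PM2", "pathogenic", "supporting"))), "likely_pathogenic")
})

test_that("worked classification bundles reproduce the assay's calls", {
  # splice-disrupting variant: PVS1(RNA) strong + PS3 moderate + absent in
  # controls; PP3-eligible scores are suppressed by the PVS1 assertion
  d23h <- classify_variant(
    evidence_code("PS3", "pathogenic", "moderate"),
    list(variant_id = "splice_loss", bayesdel_noaf = 0.17,
         spliceai_delta = 0.95, asserted_codes = "PVS1_RNA:strong"))
  expect_equal(d23h$point_class, "likely_pathogenic")
  expect_equal(d23h$qualitative_class, "likely_pathogenic")
  expect_equal(d23h$final_class, "likely_pathogenic")
  expect_false(d23h$discordant)
  expect_false(grepl("PP3", d23h$codes))

  # damaging missense with discordant in-silico scores: stays uncertain
  w31 <- classify_variant(
    evidence_code("PS3", "pathogenic", "moderate"),
    list(variant_id = "trp_missense", bayesdel_noaf = 0.10,
         spliceai_delta = 0.05, asserted_codes = ""))
  expect_equal(w31$final_class, "uncertain")
  expect_true(grepl("BP4", w31$codes))

  # neutral variant: BS3 moderate + BP4 + BS1 supporting
  neu <- classify_variant(
    evidence_code("BS3", "benign", "moderate"),
    list(variant_id = "neutral", faf_max = 5e-5, maf_max = 6e-5,
         bayesdel_noaf = 0.05, spliceai_delta = 0.01, asserted_codes = ""))
  expect_equal(neu$point_total, -4L)
  expect_equal(neu$final_class, "likely_benign")
})

test_that("BA1 dominates any bundle", {
  for (functional in list(NULL, evidence_code("PS3", "pathogenic", "moderate"),
                          evidence_code("BS3", "benign", "moderate"))) {
    res <- classify_variant(
      functional,
      list(variant_id = "common", faf_max = 0.02, maf_max = 0.03,
           bayesdel_noaf = 0.35, spliceai_delta = 0.0, asserted_codes = ""))
    expect_equal(res$final_class, "benign")
  }
})

test_that("no emittable bundle is pathogenic in one system and benign in the other", {
  strong_side <- c("pathogenic", "likely_pathogenic")
  benign_side <- c("benign", "likely_benign")
  for (bundle in enumerate_bundles()) {
    pt <- combine_points(bundle)$point_class
    ql <- combine_qualitative(bundle)
    contradiction <- (pt %in% strong_side && ql %in% benign_side) ||
      (ql %in% strong_side && pt %in% benign_side)
    expect_false(contradiction,
                 info = paste(vapply(bundle, `[[`, character(1), "code_id"),
                              collapse = "+"))
  }
})

test_that("one extra benign-supporting code shifts points by -1, never toward pathogenic", {
  ord <- seq_along(CLASSES)
  names(ord) <- CLASSES
  bp4 <- evidence_code("BP4", "benign", "supporting")
  for (bundle in enumerate_bundles()) {
    if (any(vapply(bundle, `[[`, character(1), "code_id") == "BP4")) next
    before <- combine_points(bundle)
    after <- combine_points(c(bundle, list(bp4)))
    expect_equal(after$point_total, before$point_total - 1L)
    expect_lte(ord[[after$point_class]], ord[[before$point_class]])
  }
})

test_that("panel classification joins calls to annotations and checks keys", {
  calls <- data.frame(variant_id = "v1", overall_code = "BS3",
                      overall_strength = "moderate")
  ann <- data.frame(variant_id = "v1", faf_max = NA_real_, maf_max = NA_real_,
                    bayesdel_noaf = 0.05, spliceai_delta = 0.01,
                    asserted_codes = "")
  res <- classify_panel(calls, ann)
  expect_equal(res$final_class, "likely_benign")  # BS3 -2, BP4 -1, PM2 +1
  expect_error(classify_panel(calls, ann[0, ]), "missing")
})
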