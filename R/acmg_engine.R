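#' Point value of an evidence code
#'
#' The point-based system assigns supporting = 1, moderate = 2, strong = 4,
#' very strong = 8 for pathogenic codes; benign codes carry the negated
#' values; indeterminate strength is worth 0 in either direction.
#'
#' @param direction `"pathogenic"`, `"benign"` or `"stand_alone_benign"`
#'   (BA1; scored as very strong benign, and short-circuited by
#'   [combine_points()] regardless).
#' @param strength One of the five strength levels.
#' @return Integer points.
#' @export
points_for <- function(direction, strength) {
  direction <- match.arg(direction,
                         c("pathogenic", "benign", "stand_alone_benign"))
  strength <- match.arg(strength, STRENGTHS)
  base <- c(indeterminate = 0L, supporting = 1L, moderate = 2L,
            strong = 4L, very_strong = 8L)[[strength]]
  if (direction == "pathogenic") base else -base
}

#' Construct an evidence code instance
#'
#' @param code_id One of `PS3`, `BS3`, `PM2`, `BA1`, `BS1`, `PP3`, `BP4`,
#'   `PS1_splicing`, `PVS1_RNA`.
#' @param direction Evidence direction; BA1 must be `"stand_alone_benign"`.
#' @param strength Evidence strength.
#' @return List of class `evidence_code` with `points` filled in.
#' @export
evidence_code <- function(code_id,
                          direction = c("pathogenic", "benign",
                                        "stand_alone_benign"),
                          strength = "supporting") {
  code_id <- match.arg(code_id, c("PS3", "BS3", "PM2", "BA1", "BS1",
                                  "PP3", "BP4", "PS1_splicing", "PVS1_RNA"))
  direction <- match.arg(direction)
  strength <- match.arg(strength, STRENGTHS)
  if (code_id == "BA1" && direction != "stand_alone_benign") {
    stop("BA1 is a stand-alone benign code")
  }
  structure(list(code_id = code_id, direction = direction,
                 strength = strength,
                 points = points_for(direction, strength)),
            class = "evidence_code")
}

#' Population-frequency evidence code
#'
#' Banding on the filter allele frequency (FAF, maximum over the nonfounder
#' populations) and minor allele frequency: BA1 for FAF > 0.001 (stand-alone
#' benign); BS1 (strong) for FAF > 0.0001 to <= 0.001; BS1 at supporting
#' strength for FAF > 0.00002 to <= 0.0001; PM2 at indeterminate strength
#' (0 points) for minor allele frequency > 0 to <= 0.00002; PM2 at
#' supporting strength for variants absent in controls. Exactly one code is
#' returned; a variant with no frequency data is treated as absent in
#' controls.
#'
#' @param faf_max,maf_max Frequencies in \[0,1\], or `NA` when unobserved.
#' @return An [evidence_code()].
#' @export
population_code <- function(faf_max = NA_real_, maf_max = NA_real_) {
  for (f in c(faf_max, maf_max)) {
    if (!is.na(f) && (f < 0 || f > 1)) stop("frequencies must be in [0,1]")
  }
  if (!is.na(faf_max) && faf_max > 0.001) {
    evidence_code("BA1", "stand_alone_benign", "very_strong")
  } else if (!is.na(faf_max) && faf_max > 0.0001) {
    evidence_code("BS1", "benign", "strong")
  } else if (!is.na(faf_max) && faf_max > 0.00002) {
    evidence_code("BS1", "benign", "supporting")
  } else if (!is.na(maf_max) && maf_max > 0 && maf_max <= 0.00002) {
    evidence_code("PM2", "pathogenic", "indeterminate")
  } else {
    # absent in controls (or no frequency data at all)
    evidence_code("PM2", "pathogenic", "supporting")
  }
}

#' Computational (in-silico) evidence code
#'
#' PP3 at supporting strength when the SpliceAI delta-max score is >= 0.2
#' and/or the BayesDel_noAF score is >= 0.30; BP4 at supporting strength
#' when SpliceAI <= 0.1 and BayesDel <= 0.18; no code in the gap zone. PP3
#' is suppressed when a PVS1 (RNA) code is asserted for the variant, since
#' the splicing prediction would double-count the demonstrated splicing
#' defect.
#'
#' @param bayesdel_noaf,spliceai_delta Precomputed scores; `NA` when
#'   unavailable (no code is then assigned).
#' @param pvs1_asserted Logical; set by [classify_variant()].
#' @return An [evidence_code()] or `NULL`.
#' @export
computational_code <- function(bayesdel_noaf = NA_real_,
                               spliceai_delta = NA_real_,
                               pvs1_asserted = FALSE) {
  if (is.na(bayesdel_noaf) || is.na(spliceai_delta)) return(NULL)
  if (spliceai_delta >= 0.2 || bayesdel_noaf >= 0.30) {
    if (pvs1_asserted) return(NULL)
    evidence_code("PP3", "pathogenic", "supporting")
  } else if (spliceai_delta <= 0.1 && bayesdel_noaf <= 0.18) {
    evidence_code("BP4", "benign", "supporting")
  } else {
    NULL
  }
}

#' Apply externally asserted splicing codes
#'
#' Splicing evidence established outside the fitness assay (same-consequence
#' splice variants for PS1, or a splicing reporter assay demonstrating loss
#' of functional transcript for PVS1 at RNA-adjusted strength) is passed
#' through with mutual exclusion enforced: a PVS1 (RNA) assertion suppresses
#' PS1 (splicing) for the same variant, with a warning.
#'
#' @param asserted List of `evidence_code` objects, or a string of
#'   semicolon-separated `code:strength` pairs (e.g.
#'   `"PS1_splicing:moderate"`), or `""` / `NULL` for none.
#' @return List of `evidence_code` objects (possibly empty).
#' @export
apply_asserted_splicing_codes <- function(asserted) {
  codes <- parse_asserted_codes(asserted)
  ids <- vapply(codes, `[[`, character(1L), "code_id")
  if ("PVS1_RNA" %in% ids && "PS1_splicing" %in% ids) {
    warning("PVS1_RNA asserted: dropping co-asserted PS1_splicing")
    codes <- codes[ids != "PS1_splicing"]
  }
  codes
}

# Internal: parse "code:strength;code:strength" assertions
parse_asserted_codes <- function(asserted) {
  if (is.null(asserted) || (is.character(asserted) && !nzchar(asserted)) ||
      (is.atomic(asserted) && all(is.na(asserted)))) {
    return(list())
  }
  if (is.list(asserted)) {
    if (inherits(asserted, "evidence_code")) return(list(asserted))
    return(asserted)
  }
  parts <- strsplit(asserted, ";", fixed = TRUE)[[1L]]
  lapply(trimws(parts[nzchar(trimws(parts))]), function(p) {
    kv <- strsplit(p, ":", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed asserted code: ", p)
    dir <- if (grepl("^B", kv[1L])) "benign" else "pathogenic"
    evidence_code(kv[1L], dir, kv[2L])
  })
}

#' Combine evidence codes under the point-based system
#'
#' Points are summed and mapped to the 5-tier scale: benign at or below -7;
#' likely benign -6 to -2; uncertain -1 to 5; likely pathogenic 6 to 9;
#' pathogenic at 10 or more. A BA1 code short-circuits to benign regardless
#' of the sum.
#'
#' @param codes List of [evidence_code()] objects.
#' @return List: `point_total`, `point_class`.
#' @export
combine_points <- function(codes) {
  pts <- vapply(codes, `[[`, integer(1L), "points")
  total <- sum(pts)
  ids <- vapply(codes, `[[`, character(1L), "code_id")
  cls <- if ("BA1" %in% ids) "benign"
  else if (total <= -7) "benign"
  else if (total <= -2) "likely_benign"
  else if (total <= 5) "uncertain"
  else if (total <= 9) "likely_pathogenic"
  else "pathogenic"
  list(point_total = as.integer(total), point_class = cls)
}

#' Combine evidence codes under the qualitative system
#'
#' Implements the original qualitative combining rules (2015 framework).
#' Codes are counted by direction and strength; indeterminate-strength
#' codes are ignored. Moderate-strength benign codes — absent from the
#' original rules — count as two supporting benign codes, the convention
#' that makes an OddsPath-calibrated BS3-moderate usable. Pathogenic rules:
#' pathogenic for 1 very strong + (1 strong, or >= 2 moderate, or 1 moderate
#' + 1 supporting, or >= 2 supporting), >= 2 strong, or 1 strong +
#' (>= 3 moderate, or 2 moderate + >= 2 supporting, or 1 moderate + >= 4
#' supporting); likely pathogenic for 1 very strong + 1 moderate, 1 strong
#' + 1--2 moderate, 1 strong + >= 2 supporting, >= 3 moderate, 2 moderate +
#' >= 2 supporting, or 1 moderate + >= 4 supporting. Benign rules: BA1
#' stand-alone or >= 2 strong benign give benign; 1 strong benign + 1
#' supporting, or >= 2 supporting benign, give likely benign. Conflicting
#' pathogenic and benign matches yield uncertain.
#'
#' @param codes List of [evidence_code()] objects.
#' @return One of the five class labels.
#' @export
combine_qualitative <- function(codes) {
  ids <- vapply(codes, `[[`, character(1L), "code_id")
  if ("BA1" %in% ids) return("benign")
  dirs <- vapply(codes, `[[`, character(1L), "direction")
  strs <- vapply(codes, `[[`, character(1L), "strength")
  keep <- strs != "indeterminate"
  dirs <- dirs[keep]
  strs <- strs[keep]

  n_of <- function(direction, strength) sum(dirs == direction &
                                              strs == strength)
  vs <- n_of("pathogenic", "very_strong")
  st <- n_of("pathogenic", "strong")
  mo <- n_of("pathogenic", "moderate")
  su <- n_of("pathogenic", "supporting")
  b_st <- n_of("benign", "strong") + n_of("benign", "very_strong")
  # moderate benign counts as two supporting benign
  b_su <- n_of("benign", "supporting") + 2L * n_of("benign", "moderate")

  pathogenic <- (vs >= 1 && (st >= 1 || mo >= 2 || (mo == 1 && su >= 1) ||
                               su >= 2)) ||
    st >= 2 ||
    (st == 1 && (mo >= 3 || (mo == 2 && su >= 2) || (mo == 1 && su >= 4)))
  likely_path <- (vs >= 1 && mo == 1) ||
    (st == 1 && mo >= 1 && mo <= 2) ||
    (st == 1 && su >= 2) ||
    mo >= 3 ||
    (mo == 2 && su >= 2) ||
    (mo == 1 && su >= 4)
  benign <- b_st >= 2
  likely_ben <- (b_st == 1 && b_su >= 1) || b_su >= 2

  path_side <- pathogenic || likely_path
  ben_side <- benign || likely_ben
  if (path_side && ben_side) return("uncertain")
  if (pathogenic) return("pathogenic")
  if (likely_path) return("likely_pathogenic")
  if (benign) return("benign")
  if (likely_ben) return("likely_benign")
  "uncertain"
}

#' Classify one variant from its functional code and annotations
#'
#' Assembles the evidence bundle — the functional PS3/BS3 code, asserted
#' splicing codes (with PVS1/PS1 exclusion), the computational PP3/BP4 code
#' (PP3 suppressed under an asserted PVS1), and the population code — and
#' combines it under both systems. The final class is the shared class when
#' the two systems agree; otherwise the variant stays uncertain and is
#' flagged discordant.
#'
#' @param functional An [evidence_code()] (PS3 or BS3) or `NULL` for a
#'   not-assessable variant.
#' @param ann One-row data.frame (or list) with fields `variant_id`,
#'   `faf_max`, `maf_max`, `bayesdel_noaf`, `spliceai_delta`,
#'   `asserted_codes`.
#' @return One-row data.frame: `variant_id`, `codes` (human-readable
#'   bundle), `point_total`, `point_class`, `qualitative_class`,
#'   `final_class`, `discordant`.
#' @export
classify_variant <- function(functional, ann) {
  splice <- apply_asserted_splicing_codes(ann$asserted_codes %||% "")
  pvs1 <- any(vapply(splice, `[[`, character(1L), "code_id") == "PVS1_RNA")
  codes <- splice
  if (!is.null(functional)) codes <- c(codes, list(functional))
  comp <- computational_code(ann$bayesdel_noaf %||% NA_real_,
                             ann$spliceai_delta %||% NA_real_,
                             pvs1_asserted = pvs1)
  if (!is.null(comp)) codes <- c(codes, list(comp))
  codes <- c(codes, list(population_code(ann$faf_max %||% NA_real_,
                                         ann$maf_max %||% NA_real_)))
  pt <- combine_points(codes)
  qual <- combine_qualitative(codes)
  final <- if (pt$point_class == qual) pt$point_class else "uncertain"
  data.frame(variant_id = ann$variant_id,
             codes = paste(vapply(codes, function(cd) {
               sprintf("%s(%s,%+d)", cd$code_id, cd$strength, cd$points)
             }, character(1L)), collapse = ";"),
             point_total = pt$point_total,
             point_class = pt$point_class,
             qualitative_class = qual,
             final_class = final,
             discordant = pt$point_class != qual,
             stringsAsFactors = FALSE)
}

#' Classify every variant of a panel
#'
#' @param calls Functional-call data.frame from [functional_calls()].
#' @param annotations Annotation data.frame keyed by `variant_id`.
#' @return Classification data.frame, one row per variant in `calls`.
#' @export
classify_panel <- function(calls, annotations) {
  out <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    vid <- calls$variant_id[i]
    ann <- annotations[annotations$variant_id == vid, , drop = FALSE]
    if (nrow(ann) != 1L) stop("annotation row missing for ", vid)
    functional <- if (is.na(calls$overall_code[i])) NULL else {
      evidence_code(calls$overall_code[i],
                    if (calls$overall_code[i] == "BS3") "benign"
                    else "pathogenic",
                    calls$overall_strength[i])
    }
    out[[i]] <- classify_variant(functional, ann)
  }
  do.call(rbind, out)
}
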