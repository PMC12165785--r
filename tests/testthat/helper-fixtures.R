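# Shared fixtures, built in code.

# One sample-counts row
sc_row <- function(variant = 500L, wtprime = 1000L, frameshift = 0L,
                   other = 0L, variant_id = "v1", condition = "day2",
                   replicate_id = 1L) {
  data.frame(variant_id = variant_id, condition = condition,
             replicate_id = replicate_id, variant_reads = variant,
             wtprime_reads = wtprime, frameshift_reads = frameshift,
             other_reads = other,
             total_reads = variant + wtprime + frameshift + other,
             stringsAsFactors = FALSE)
}

# Deterministic multi-replicate counts for one variant: exact ratios, no noise
make_counts <- function(variant_id = "v1", day2 = c(v = 500L, w = 1000L),
                        day12 = list(day12_untreated = c(v = 100L, w = 800L)),
                        n_replicates = 1L) {
  rows <- list()
  for (r in seq_len(n_replicates)) {
    rows[[length(rows) + 1L]] <- sc_row(day2[["v"]], day2[["w"]],
                                        variant_id = variant_id,
                                        condition = "day2", replicate_id = r)
    for (cond in names(day12)) {
      rows[[length(rows) + 1L]] <- sc_row(day12[[cond]][["v"]],
                                          day12[[cond]][["w"]],
                                          variant_id = variant_id,
                                          condition = cond, replicate_id = r)
    }
  }
  do.call(rbind, rows)
}

# A small edit definition over a 12-mer amplicon
demo_edits <- function(variant_id = "v1") {
  edit_definition(variant_id,
                  reference_amplicon = "ACGTACGTACGT",
                  variant_amplicon   = "ACGTTCGTACGT",
                  wtprime_amplicon   = "ACGTACGAACGT")
}

# Enumerate every evidence bundle the engine can emit: optional functional
# code, optional splicing assertion (PVS1 excludes PP3), optional
# computational code, exactly one population code.
enumerate_bundles <- function() {
  functional <- list(NULL,
                     evidence_code("PS3", "pathogenic", "moderate"),
                     evidence_code("PS3", "pathogenic", "indeterminate"),
                     evidence_code("BS3", "benign", "moderate"))
  splicing <- list(NULL,
                   evidence_code("PS1_splicing", "pathogenic", "moderate"),
                   evidence_code("PVS1_RNA", "pathogenic", "strong"))
  comp <- list(NULL,
               evidence_code("PP3", "pathogenic", "supporting"),
               evidence_code("BP4", "benign", "supporting"))
  pop <- list(evidence_code("BA1", "stand_alone_benign", "very_strong"),
              evidence_code("BS1", "benign", "strong"),
              evidence_code("BS1", "benign", "supporting"),
              evidence_code("PM2", "pathogenic", "indeterminate"),
              evidence_code("PM2", "pathogenic", "supporting"))
  bundles <- list()
  for (f in functional) for (s in splicing) for (cc in comp) for (p in pop) {
    if (!is.null(s) && s$code_id == "PVS1_RNA" &&
        !is.null(cc) && cc$code_id == "PP3") next
    b <- Filter(Negate(is.null), list(f, s, cc, p))
    bundles[[length(bundles) + 1L]] <- b
  }
  bundles
}

# Memoized end-to-end run at the study conditions (9 + 14 controls, 54
# query variants, 7,500 reads, 3 replicates)
study_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_pipeline(default_config(seed = 101L))
    cache
  }
})
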