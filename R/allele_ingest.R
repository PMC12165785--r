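#' Define the expected edited amplicons for one variant
#'
#' An edit definition ties a variant to its reference amplicon and to the two
#' expected repair products: the variant-edited amplicon and the WT'-edited
#' amplicon (the synonymous internal normalization edit). Classification of
#' allele rows is by exact full-amplicon match against these sequences;
#' fuzzy alignment belongs to the upstream amplicon aligner, whose allele
#' table we consume.
#'
#' @param variant_id Variant identifier (HGVS c. string or any label).
#' @param reference_amplicon,variant_amplicon,wtprime_amplicon DNA strings
#'   over \{A, C, G, T\}; must be non-empty and pairwise distinct.
#' @return A list of class `edit_definition`.
#' @export
edit_definition <- function(variant_id, reference_amplicon, variant_amplicon,
                            wtprime_amplicon) {
  seqs <- c(reference = reference_amplicon, variant = variant_amplicon,
            wtprime = wtprime_amplicon)
  if (any(!nzchar(seqs))) {
    stop("edit_definition: amplicon sequences must be non-empty")
  }
  if (any(grepl("[^ACGT]", seqs))) {
    stop("edit_definition: amplicons must be over the alphabet {A,C,G,T}")
  }
  if (anyDuplicated(seqs)) {
    stop("edit_definition: reference, variant and WT' amplicons must be ",
         "pairwise distinct")
  }
  structure(list(variant_id = variant_id,
                 reference_amplicon = reference_amplicon,
                 variant_amplicon = variant_amplicon,
                 wtprime_amplicon = wtprime_amplicon),
            class = "edit_definition")
}

#' Parse an amplicon allele-count table
#'
#' Reads a tab-delimited allele table in the dialect produced by standard
#' amplicon editing-outcome tools: one row per distinct aligned read
#' sequence with its read count and the number of inserted and deleted
#' bases relative to the reference.
#'
#' @param source Path to a tab-delimited file with columns
#'   `Aligned_Sequence`, `Reads`, `n_inserted`, `n_deleted` (extra columns
#'   are ignored).
#' @return A data.frame with those four columns; `Reads`, `n_inserted` and
#'   `n_deleted` are integer and non-negative. Rows with zero reads are
#'   retained.
#' @export
parse_allele_table <- function(source) {
  if (!file.exists(source)) stop("allele table not found: ", source)
  tab <- utils::read.delim(source, stringsAsFactors = FALSE,
                           check.names = FALSE)
  required <- c("Aligned_Sequence", "Reads", "n_inserted", "n_deleted")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("allele table ", source, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(tab) == 0L) stop("allele table ", source, " has no rows")
  for (col in c("Reads", "n_inserted", "n_deleted")) {
    v <- tab[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != floor(v))) {
      stop("column '", col, "' in ", source,
           " must contain non-negative integers")
    }
    tab[[col]] <- as.integer(v)
  }
  tab[required]
}

#' Classify allele rows into read classes for one sample
#'
#' Each row is assigned to exactly one class: exact sequence match to the
#' variant-edited amplicon counts as `variant`; exact match to the WT'
#' amplicon as `wtprime`; any other row is `frameshift` when its net indel
#' length is not a multiple of 3, i.e. `(n_inserted - n_deleted) %% 3 != 0`,
#' and `other` otherwise. Unedited reference reads and substitution-only
#' mismatches therefore fall into `other`.
#'
#' @param rows Data.frame of allele rows as from [parse_allele_table()].
#' @param edits An [edit_definition()].
#' @param condition One of [CONDITIONS].
#' @param replicate_id Replicate label (integer or string).
#' @return A one-row data.frame (a `SampleCounts` record): `variant_id`,
#'   `condition`, `replicate_id`, the four class counts and `total_reads`.
#'   The class counts always sum to `total_reads` (partition property).
#' @export
classify_alleles <- function(rows, edits, condition, replicate_id) {
  stopifnot(inherits(edits, "edit_definition"))
  condition <- match.arg(condition, CONDITIONS)
  is_variant <- rows$Aligned_Sequence == edits$variant_amplicon
  is_wtprime <- rows$Aligned_Sequence == edits$wtprime_amplicon
  if (any(is_variant & is_wtprime)) {
    stop("allele row matches both edited amplicons; corrupt input for ",
         edits$variant_id)
  }
  net_indel <- rows$n_inserted - rows$n_deleted
  is_frameshift <- !is_variant & !is_wtprime & (net_indel %% 3L != 0L)
  is_other <- !is_variant & !is_wtprime & !is_frameshift
  counts <- c(variant = sum(rows$Reads[is_variant]),
              wtprime = sum(rows$Reads[is_wtprime]),
              frameshift = sum(rows$Reads[is_frameshift]),
              other = sum(rows$Reads[is_other]))
  data.frame(variant_id = edits$variant_id,
             condition = condition,
             replicate_id = replicate_id,
             variant_reads = counts[["variant"]],
             wtprime_reads = counts[["wtprime"]],
             frameshift_reads = counts[["frameshift"]],
             other_reads = counts[["other"]],
             total_reads = sum(counts),
             stringsAsFactors = FALSE)
}

#' Minimum-read-depth quality control
#'
#' A sample passes QC when its total classified read count reaches the
#' minimum depth (default 7,500 reads, the assay's per-sample requirement).
#' Failing samples are excluded from ratio analysis by the pipeline and
#' logged in the run manifest.
#'
#' @param sc A sample-counts data.frame (one or more rows) as produced by
#'   [classify_alleles()] or [simulate_counts()].
#' @param min_reads Minimum total reads per sample. Default 7500.
#' @return `sc` with logical column `qc_pass` and character column
#'   `qc_reason` (`NA` for passing samples) appended.
#' @export
qc_check <- function(sc, min_reads = 7500L) {
  stopifnot(is.numeric(min_reads), min_reads >= 0)
  pass <- sc$total_reads >= min_reads
  sc$qc_pass <- pass
  sc$qc_reason <- ifelse(pass, NA_character_,
                         sprintf("total_reads %d < %d", sc$total_reads,
                                 as.integer(min_reads)))
  sc
}

#' Ingest a directory of allele tables
#'
#' Parses every allele table listed in a manifest (as written by
#' [write_allele_tables()]) and classifies each into sample counts.
#'
#' @param manifest Data.frame with columns `file`, `variant_id`, `condition`,
#'   `replicate_id`, or the path of a manifest TSV.
#' @param edit_defs Named list of [edit_definition()] objects, keyed by
#'   `variant_id`.
#' @param dir Directory against which relative `file` entries are resolved.
#' @return Sample-counts data.frame with one row per sample.
#' @export
ingest_samples <- function(manifest, edit_defs, dir = ".") {
  if (is.character(manifest)) {
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  }
  out <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    ed <- edit_defs[[m$variant_id]]
    if (is.null(ed)) stop("no edit definition for variant ", m$variant_id)
    path <- if (file.exists(m$file)) m$file else file.path(dir, m$file)
    rows <- parse_allele_table(path)
    out[[i]] <- classify_alleles(rows, ed, m$condition, m$replicate_id)
  }
  do.call(rbind, out)
}
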