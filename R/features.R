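#' Extract a coding-potential feature schema from transcript sequences
#'
#' Three schemas are supported, mirroring the feature sets of the classifiers
#' they feed:
#' * `"cpat"` — maximum ORF length (nt), ORF coverage, Fickett TESTCODE
#'   score, hexamer usage-bias score (4 features; logistic regression).
#' * `"plek"` — the weighted k-mer frequency profile for k = 1..5
#'   (1364 features; SVM).
#' * `"lncfinder-lite"` — ORF length and coverage, mean coding and noncoding
#'   hexamer log-frequencies over the ORF, their difference, GC fraction, and
#'   the EIIP spectrum features (11 features; SVM). This is a
#'   composition/physicochemical subset; RNA secondary-structure features are
#'   not computed, but externally computed columns can be appended via
#'   `extra_features`.
#'
#' ORF-based features use the longest forward-strand ORF, accepting an
#' unterminated ORF when no complete one exists.
#'
#' @param seqs Tibble with columns `transcript_id`, `sequence`.
#' @param schema One of `"cpat"`, `"plek"`, `"lncfinder-lite"`.
#' @param hexamer_table A [build_hexamer_table()] result; required by the
#'   `"cpat"` and `"lncfinder-lite"` schemas.
#' @param extra_features Optional tibble keyed by `transcript_id` with
#'   additional numeric columns (e.g. externally computed structure
#'   features), joined onto the schema.
#' @return Tibble: `transcript_id` plus the schema's numeric feature columns
#'   in a fixed, documented order. Carries the schema id in attribute
#'   `schema`.
#' @export
extract_features <- function(seqs, schema = c("cpat", "plek", "lncfinder-lite"),
                             hexamer_table = NULL, extra_features = NULL) {
  schema <- match.arg(schema)
  validate_sequences(seqs)
  if (schema %in% c("cpat", "lncfinder-lite") && is.null(hexamer_table)) {
    stop("schema '", schema, "' requires a hexamer_table", call. = FALSE)
  }
  out <- switch(
    schema,
    "cpat" = {
      orfs <- find_longest_orf(seqs, require_stop = FALSE)
      tibble(transcript_id = seqs$transcript_id,
             orf_length_nt = as.numeric(orfs$orf_length_nt),
             orf_coverage = orfs$orf_coverage,
             fickett_score = fickett_score(seqs)$fickett_score,
             hexamer_score = hexamer_score(seqs, hexamer_table)$hexamer_score)
    },
    "plek" = kmer_profile(seqs, k_min = 1L, k_max = 5L),
    "lncfinder-lite" = {
      orfs <- find_longest_orf(seqs, require_stop = FALSE)
      hx <- hexamer_logfreq_means(seqs, hexamer_table)
      gc <- Biostrings::letterFrequency(as_dna(seqs), "GC", as.prob = TRUE)[, 1]
      dplyr::bind_cols(
        tibble(transcript_id = seqs$transcript_id,
               orf_length_nt = as.numeric(orfs$orf_length_nt),
               orf_coverage = orfs$orf_coverage,
               orf_coding_logfreq = hx$orf_coding_logfreq,
               orf_noncoding_logfreq = hx$orf_noncoding_logfreq,
               hexamer_score = hx$hexamer_score,
               gc_fraction = unname(gc)),
        eiip_spectrum_features(seqs)[-1])
    })
  if (!is.null(extra_features)) {
    stopifnot("transcript_id" %in% names(extra_features))
    out <- dplyr::left_join(out, extra_features, by = "transcript_id")
  }
  if (any(!is.finite(as.matrix(out[-1])))) {
    stop("non-finite feature values produced", call. = FALSE)
  }
  attr(out, "schema") <- schema
  out
}

#' Write a feature matrix as TSV
#'
#' One header row of feature names with a leading `transcript_id` column.
#'
#' @param features An [extract_features()] result.
#' @param path Output path.
#' @export
write_features <- function(features, path) {
  readr::write_tsv(features, path)
  invisible(path)
}
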