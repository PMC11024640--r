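#' Build a hexamer usage-bias table from labeled training sequences
#'
#' The coding background counts in-frame hexamers (step 3) over each coding
#' sequence's longest ORF; the noncoding background counts all overlapping
#' hexamers (step 1) over each noncoding sequence. Counts get a pseudocount,
#' are normalized to sum to one over all 4096 hexamers, and are stored as
#' natural-log frequencies. Sequences shorter than six residues (or coding
#' sequences without an ORF of at least six residues) contribute nothing.
#'
#' @param coding Tibble of mRNA sequences (`transcript_id`, `sequence`).
#' @param noncoding Tibble of lncRNA (or other noncoding) sequences.
#' @param pseudocount Positive smoothing constant added to every count.
#' @return A `hexamer_table`: a tibble with columns `hexamer`,
#'   `coding_logfreq`, `noncoding_logfreq` and attributes recording the
#'   pseudocount and the number of hexamers tallied per background.
#' @export
build_hexamer_table <- function(coding, noncoding, pseudocount = 1) {
  validate_sequences(coding)
  validate_sequences(noncoding)
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1L, pseudocount > 0)
  cnt_c <- orf_hexamer_counts(coding)
  cnt_n <- colSums(Biostrings::oligonucleotideFrequency(as_dna(noncoding),
                                                        width = 6L, step = 1L))
  new_hexamer_table(cnt_c, cnt_n, pseudocount)
}

new_hexamer_table <- function(cnt_c, cnt_n, pseudocount) {
  tbl <- tibble(
    hexamer = names(cnt_c),
    coding_logfreq = unname(log((cnt_c + pseudocount) /
                                  (sum(cnt_c) + 4096 * pseudocount))),
    noncoding_logfreq = unname(log((cnt_n + pseudocount) /
                                     (sum(cnt_n) + 4096 * pseudocount))))
  structure(tbl,
            class = c("hexamer_table", class(tbl)),
            pseudocount = pseudocount,
            n_coding_hexamers = sum(cnt_c),
            n_noncoding_hexamers = sum(cnt_n))
}

# in-frame (step 3) hexamer tally over each sequence's longest ORF;
# incomplete ORFs are accepted so that stop-less training sequences still count
orf_hexamer_counts <- function(seqs) {
  orfs <- find_longest_orf(seqs, require_stop = FALSE)
  has <- orfs$orf_length_nt >= 6L
  if (!any(has)) {
    return(setNames(rep(0, 4096),
                    Biostrings::mkAllStrings(c("A", "C", "G", "T"), 6L)))
  }
  x <- as_dna(seqs[has, , drop = FALSE])
  x <- Biostrings::subseq(x, start = orfs$orf_start[has], end = orfs$orf_end[has])
  colSums(Biostrings::oligonucleotideFrequency(x, width = 6L, step = 3L))
}

#' Hexamer usage-bias score
#'
#' Mean log-likelihood ratio `coding_logfreq - noncoding_logfreq` over the
#' scorable hexamers of each transcript: in-frame hexamers of the longest ORF
#' when that ORF is at least six residues long, otherwise all overlapping
#' hexamers of the whole sequence. Hexamers containing `N` are skipped; a
#' transcript with no scorable hexamer scores 0.
#'
#' @param seqs Tibble with columns `transcript_id`, `sequence`.
#' @param table A [build_hexamer_table()] result.
#' @return Tibble with columns `transcript_id`, `hexamer_score`.
#' @export
hexamer_score <- function(seqs, table) {
  counts <- hexamer_count_matrix(seqs)
  logratio <- hexamer_logratio(table)
  n <- rowSums(counts)
  score <- unname(as.vector(counts %*% logratio) / ifelse(n == 0, 1, n))
  score[n == 0] <- 0
  tibble(transcript_id = seqs$transcript_id, hexamer_score = score)
}

hexamer_logratio <- function(table) {
  stopifnot(inherits(table, "hexamer_table"))
  setNames(table$coding_logfreq - table$noncoding_logfreq, table$hexamer)
}

# per-transcript hexamer counts under the scoring convention above
hexamer_count_matrix <- function(seqs) {
  validate_sequences(seqs)
  orfs <- find_longest_orf(seqs, require_stop = FALSE)
  x <- as_dna(seqs)
  in_orf <- orfs$orf_length_nt >= 6L
  counts <- matrix(0, nrow = nrow(seqs), ncol = 4096,
                   dimnames = list(seqs$transcript_id,
                                   Biostrings::mkAllStrings(c("A", "C", "G", "T"), 6L)))
  if (any(in_orf)) {
    sub <- Biostrings::subseq(x[in_orf], start = orfs$orf_start[in_orf],
                              end = orfs$orf_end[in_orf])
    counts[in_orf, ] <- Biostrings::oligonucleotideFrequency(sub, 6L, step = 3L)
  }
  if (any(!in_orf)) {
    counts[!in_orf, ] <- Biostrings::oligonucleotideFrequency(x[!in_orf], 6L,
                                                              step = 1L)
  }
  counts
}

# per-transcript mean coding/noncoding log-frequencies over scorable hexamers
hexamer_logfreq_means <- function(seqs, table) {
  counts <- hexamer_count_matrix(seqs)
  n <- rowSums(counts)
  denom <- ifelse(n == 0, 1, n)
  mc <- unname(as.vector(counts %*% setNames(table$coding_logfreq,
                                             table$hexamer)) / denom)
  mn <- unname(as.vector(counts %*% setNames(table$noncoding_logfreq,
                                             table$hexamer)) / denom)
  mc[n == 0] <- 0
  mn[n == 0] <- 0
  tibble(transcript_id = seqs$transcript_id,
         orf_coding_logfreq = mc, orf_noncoding_logfreq = mn,
         hexamer_score = mc - mn)
}

#' Write / read a hexamer table as TSV
#'
#' Columns: `hexamer`, `coding_logfreq`, `noncoding_logfreq`.
#'
#' @param table A `hexamer_table`.
#' @param path File path.
#' @return `path` (writer) or a `hexamer_table` (reader).
#' @export
write_hexamer_table <- function(table, path) {
  stopifnot(inherits(table, "hexamer_table"))
  readr::write_tsv(as_tibble(table), path)
  invisible(path)
}

#' @rdname write_hexamer_table
#' @export
read_hexamer_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           hexamer = readr::col_character(),
                           coding_logfreq = readr::col_double(),
                           noncoding_logfreq = readr::col_double()))
  if (nrow(tbl) != 4096L) stop("hexamer table must have 4096 rows", call. = FALSE)
  structure(tbl, class = c("hexamer_table", class(tbl)),
            pseudocount = NA_real_,
            n_coding_hexamers = NA_real_, n_noncoding_hexamers = NA_real_)
}
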