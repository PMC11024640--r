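#' Find the longest open reading frame in each transcript
#'
#' Scans the three forward reading frames for the longest ATG-initiated ORF.
#' ORF length includes the stop codon when the ORF is complete. With
#' `require_stop = FALSE`, an ATG running to the last full codon of its frame
#' without encountering a stop is also eligible (reported as incomplete).
#' Ties are broken by smallest start position, then smallest frame. Transcripts
#' without any ORF get `orf_length_nt = 0` and `orf_start = orf_end = 0`.
#'
#' Coordinates are 1-based inclusive; `orf_frame` is 0, 1 or 2.
#'
#' @param seqs Tibble with columns `transcript_id`, `sequence`.
#' @param require_stop Only accept ORFs terminated by an in-frame stop codon.
#' @return Tibble with columns `transcript_id`, `orf_start`, `orf_end`,
#'   `orf_length_nt`, `orf_frame`, `orf_complete`, `orf_coverage`.
#' @examples
#' find_longest_orf(tibble::tibble(transcript_id = "t1", sequence = "ATGAAATAG"))
#' @export
find_longest_orf <- function(seqs, require_stop = TRUE) {
  validate_sequences(seqs)
  res <- lapply(seqs$sequence, orf_scan_one, require_stop = require_stop)
  out <- dplyr::bind_rows(res)
  out$transcript_id <- seqs$transcript_id
  out$orf_coverage <- out$orf_length_nt / nchar(seqs$sequence)
  dplyr::relocate(out, "transcript_id")
}

#' ORF coverage of transcripts
#'
#' Fraction of the transcript covered by its longest ORF
#' (`orf_length_nt / transcript length`); 0 when no ORF exists.
#'
#' @inheritParams find_longest_orf
#' @param orfs Optional precomputed result of [find_longest_orf()]; computed
#'   when missing.
#' @return Tibble with columns `transcript_id`, `orf_coverage`.
#' @export
orf_coverage <- function(seqs, orfs = NULL, require_stop = TRUE) {
  validate_sequences(seqs)
  if (is.null(orfs)) orfs <- find_longest_orf(seqs, require_stop = require_stop)
  stopifnot(identical(orfs$transcript_id, seqs$transcript_id))
  tibble(transcript_id = seqs$transcript_id,
         orf_coverage = orfs$orf_length_nt / nchar(seqs$sequence))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# single-sequence scanner; vectorised over codons within each frame
orf_scan_one <- function(seq, require_stop = TRUE) {
  L <- nchar(seq)
  best <- list(start = 0L, end = 0L, len = 0L,
               frame = NA_integer_, complete = FALSE)
  consider <- function(start, end, len, frame, complete) {
    if (len > best$len ||
        (len == best$len && len > 0L &&
         (start < best$start ||
          (start == best$start && frame < best$frame)))) {
      best <<- list(start = start, end = end, len = len,
                    frame = frame, complete = complete)
    }
  }
  for (frame in 0:2) {
    n_cod <- (L - frame) %/% 3L
    if (n_cod < 1L) next
    cps <- frame + (seq_len(n_cod) - 1L) * 3L + 1L
    codons <- substring(seq, cps, cps + 2L)
    atg <- which(codons == "ATG")
    if (length(atg) == 0L) next
    stp <- which(codons %in% STOP_CODONS)
    # first stop strictly after each ATG (ATG itself is never a stop)
    j <- findInterval(atg, stp) + 1L
    closing <- ifelse(j <= length(stp), stp[j], NA_integer_)
    for (i in seq_along(atg)) {
      a <- atg[[i]]
      s <- closing[[i]]
      if (!is.na(s)) {
        consider(cps[[a]], cps[[s]] + 2L, (s - a + 1L) * 3L, frame, TRUE)
      } else if (!require_stop) {
        consider(cps[[a]], cps[[n_cod]] + 2L, (n_cod - a + 1L) * 3L, frame, FALSE)
      }
    }
  }
  tibble(orf_start = best$start, orf_end = best$end,
         orf_length_nt = best$len, orf_frame = best$frame,
         orf_complete = best$complete)
}
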