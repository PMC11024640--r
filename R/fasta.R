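#' Read transcript sequences from a FASTA file
#'
#' Sequences are upper-cased and `U` residues are mapped to `T` on ingest, so
#' cDNA and RNA FASTA files are treated alike. Only the residues
#' `A`, `C`, `G`, `T`, `N` are accepted.
#'
#' @param path Path to a (possibly multi-line) FASTA file.
#' @return A tibble with columns `transcript_id` and `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  seqs <- toupper(as.character(x))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  tbl <- tibble(transcript_id = ids, sequence = unname(seqs))
  validate_sequences(tbl)
  tbl
}

#' Write transcript sequences to a FASTA file
#'
#' @param seqs A tibble with columns `transcript_id` and `sequence`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  validate_sequences(seqs, allow_empty = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    s <- seqs$sequence[[i]]
    chunks <- substring(s, seq(1L, nchar(s), by = width),
                        pmin(seq(1L, nchar(s), by = width) + width - 1L, nchar(s)))
    writeLines(c(paste0(">", seqs$transcript_id[[i]]), chunks), con, sep = "\n")
  }
  invisible(path)
}

# shared sanity checks for the sequence-tibble representation
validate_sequences <- function(seqs, allow_empty = FALSE) {
  stopifnot(is.data.frame(seqs),
            all(c("transcript_id", "sequence") %in% names(seqs)))
  if (!allow_empty && nrow(seqs) == 0L) {
    stop("empty sequence set", call. = FALSE)
  }
  if (anyDuplicated(seqs$transcript_id)) {
    stop("transcript ids must be unique", call. = FALSE)
  }
  if (nrow(seqs) > 0L) {
    if (any(nchar(seqs$sequence) < 1L)) {
      stop("sequences must have length >= 1", call. = FALSE)
    }
    if (any(grepl("[^ACGTN]", seqs$sequence))) {
      stop("sequences may only contain A, C, G, T, N", call. = FALSE)
    }
  }
  invisible(seqs)
}

# tibble -> DNAStringSet (names kept)
as_dna <- function(seqs) {
  x <- Biostrings::DNAStringSet(seqs$sequence)
  names(x) <- seqs$transcript_id
  x
}
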