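#' Read transcript models from GTF/GFF
#'
#' Exon records are collected into the package's tidy transcript
#' representation: one row per exon with 1-based inclusive coordinates.
#'
#' @param path A GTF or GFF3 file.
#' @return Tibble with columns `transcript_id`, `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, sorted by transcript then start.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "exon"]
  tbl <- tibble(transcript_id = as.character(gr$transcript_id),
                gene_id = as.character(gr$gene_id),
                chrom = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr),
                end = GenomicRanges::end(gr),
                strand = as.character(GenomicRanges::strand(gr)))
  validate_exons(tbl)
  dplyr::arrange(tbl, .data$transcript_id, .data$start)
}

#' Write transcript models as GTF
#'
#' Emits one `transcript` line and its `exon` lines per transcript, in
#' deterministic order (transcripts sorted by id, exons by start).
#'
#' @param exons Exon tibble (`transcript_id`, `gene_id`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @export
write_gtf <- function(exons, path, source = "plantlnc") {
  validate_exons(exons)
  exons <- dplyr::arrange(exons, .data$transcript_id, .data$start)
  spans <- transcript_spans(exons)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(spans))) {
    tx <- spans$transcript_id[[i]]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     spans$gene_id[[i]], tx)
    writeLines(paste(spans$chrom[[i]], source, "transcript", spans$start[[i]],
                     spans$end[[i]], ".", spans$strand[[i]], ".", attrs,
                     sep = "\t"), con)
    ex <- exons[exons$transcript_id == tx, , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      writeLines(paste(ex$chrom[[j]], source, "exon", ex$start[[j]],
                       ex$end[[j]], ".", ex$strand[[j]], ".",
                       sprintf('%s exon_number "%d";', attrs, j),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read interval annotation (e.g. transposable elements) from BED
#'
#' BED's 0-based half-open coordinates are converted to the package's 1-based
#' inclusive convention. The BED name column carries the family label.
#'
#' @param path A BED file (>= 4 columns: chrom, start, end, name).
#' @return Tibble: `chrom`, `start`, `end`, `family`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr),
         end = GenomicRanges::end(gr),
         family = if (!is.null(gr$name)) as.character(gr$name) else
           paste0("interval_", seq_along(gr)))
}

validate_exons <- function(exons) {
  need <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")
  stopifnot(is.data.frame(exons), all(need %in% names(exons)))
  if (nrow(exons) > 0L) {
    stopifnot(all(exons$strand %in% c("+", "-")),
              all(exons$end >= exons$start))
    # exons of one transcript must be disjoint
    bad <- exons %>%
      dplyr::arrange(.data$transcript_id, .data$start) %>%
      dplyr::group_by(.data$transcript_id) %>%
      dplyr::filter(dplyr::n() > 1L,
                    .data$start <= dplyr::lag(.data$end,
                                              default = .data$start[1] - 1L)) %>%
      dplyr::ungroup()
    if (nrow(bad) > 0L) {
      stop("overlapping exons within transcript ", bad$transcript_id[[1]],
           call. = FALSE)
    }
  }
  invisible(exons)
}

# one row per transcript: span, exon count, exonic length
transcript_spans <- function(exons) {
  exons %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::summarise(gene_id = dplyr::first(.data$gene_id),
                     chrom = dplyr::first(.data$chrom),
                     strand = dplyr::first(.data$strand),
                     start = min(.data$start), end = max(.data$end),
                     n_exons = dplyr::n(),
                     exonic_length = sum(.data$end - .data$start + 1L),
                     .groups = "drop")
}

# one row per gene: span and strand-aware TSS/TTS
gene_models <- function(ref_exons) {
  ref_exons %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(chrom = dplyr::first(.data$chrom),
                     strand = dplyr::first(.data$strand),
                     start = min(.data$start), end = max(.data$end),
                     .groups = "drop") %>%
    dplyr::mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end),
                  tts = ifelse(.data$strand == "+", .data$end, .data$start))
}

exons_granges <- function(exons) {
  GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start, end = exons$end),
    strand = exons$strand,
    transcript_id = exons$transcript_id,
    gene_id = exons$gene_id)
}

#' Extract spliced transcript sequences from a genome
#'
#' Concatenates exon sequences in genomic order and reverse-complements
#' minus-strand transcripts.
#'
#' @param exons Exon tibble.
#' @param genome A named `DNAStringSet` or path to a genome FASTA.
#' @return Sequence tibble (`transcript_id`, `sequence`).
#' @export
extract_transcript_seqs <- function(exons, genome) {
  validate_exons(exons)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  exons <- dplyr::arrange(exons, .data$transcript_id, .data$start)
  ids <- unique(exons$transcript_id)
  seqs <- vapply(ids, function(tx) {
    ex <- exons[exons$transcript_id == tx, , drop = FALSE]
    chrom <- ex$chrom[[1]]
    if (!chrom %in% names(genome)) {
      stop("chromosome ", chrom, " absent from genome", call. = FALSE)
    }
    pieces <- as.character(Biostrings::extractAt(
      genome[[chrom]], IRanges::IRanges(ex$start, ex$end)))
    s <- paste(pieces, collapse = "")
    if (ex$strand[[1]] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }, character(1))
  tibble(transcript_id = ids, sequence = unname(seqs))
}
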