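#' Simulation configuration
#'
#' Settings shared by the synthetic transcript and genome generators. All
#' generators are pure functions of this configuration: the same config
#' (seed included) reproduces byte-identical output, and the global random
#' state is left untouched.
#'
#' @param seed Integer seed.
#' @param n_mrna,n_lnc Number of mRNA-like / lncRNA-like records.
#' @param length_range Transcript length range in nt (min must be >= 200 so
#'   the length filter is exercised only by explicitly planted short decoys).
#' @param gc Background GC fraction in (0, 1).
#' @param codon_bias Named positive weights over the 61 sense codons used to
#'   draw ORF codons; the default is skewed toward a 20-codon preferred
#'   subset, which gives mRNAs a detectable hexamer-usage signal.
#' @param max_lnc_orf_nt Longest ORF allowed in a simulated lncRNA (nt).
#' @param orf_coverage_range ORF coverage range for simulated mRNAs.
#' @param genome_plan Layout constants for [simulate_genome()]: `gene_gap`
#'   (bp between gene blocks), `decoy_gap` (bp between decoy loci) and
#'   `lnc_exon` (planted lncRNA exon size, bp).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_mrna = 1000L, n_lnc = 1000L,
                       length_range = c(400L, 3000L), gc = 0.45,
                       codon_bias = default_codon_bias(),
                       max_lnc_orf_nt = 120L,
                       orf_coverage_range = c(0.5, 0.9),
                       genome_plan = list(gene_gap = 8000L, decoy_gap = 3000L,
                                          lnc_exon = 300L)) {
  stopifnot(n_mrna >= 0L, n_lnc >= 0L, length_range[1] >= 200L,
            length_range[1] <= length_range[2], gc > 0, gc < 1,
            all(codon_bias > 0), max_lnc_orf_nt >= 30L,
            orf_coverage_range[1] >= 0, orf_coverage_range[2] <= 1)
  structure(list(seed = as.integer(seed), n_mrna = as.integer(n_mrna),
                 n_lnc = as.integer(n_lnc),
                 length_range = as.integer(length_range), gc = gc,
                 codon_bias = codon_bias,
                 max_lnc_orf_nt = as.integer(max_lnc_orf_nt),
                 orf_coverage_range = orf_coverage_range,
                 genome_plan = genome_plan),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_codon_bias <- function() {
  codons <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 3L)
  sense <- setdiff(codons, STOP_CODONS)
  preferred <- c("GCT", "TGC", "GAT", "GAA", "TTT", "GGT", "CAT", "ATT",
                 "AAG", "CTT", "ATG", "AAT", "CCT", "CAG", "AGA", "TCT",
                 "ACT", "GTT", "TGG", "TAT")
  w <- setNames(rep(1, length(sense)), sense)
  w[preferred] <- 8
  w
}

base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

# sample one value from an integer range (safe for degenerate ranges)
sample_range <- function(lo, hi) {
  rng <- seq.int(lo, hi)
  rng[sample.int(length(rng), 1L)]
}

random_dna <- function(len, gc) {
  p <- base_probs(gc)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

random_orf <- function(n_codons, codon_bias) {
  interior <- sample(names(codon_bias), n_codons - 2L, replace = TRUE,
                     prob = codon_bias)
  paste0("ATG", paste(interior, collapse = ""),
         sample(STOP_CODONS, 1L))
}

#' Simulate mRNA-like transcripts
#'
#' Each record is a GC-matched 5'UTR, an ATG-initiated ORF whose codons are
#' drawn from the configured codon-bias weights and which ends with an
#' in-frame stop, and a 3'UTR; ORF coverage is uniform over
#' `orf_coverage_range`.
#'
#' @param cfg A [sim_config()].
#' @return List: `sequences` (tibble `transcript_id`, `sequence`) and `truth`
#'   (tibble with the planted ORF geometry and `label = "mRNA"`).
#' @export
simulate_mrna <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 1L, {
    rows <- lapply(seq_len(cfg$n_mrna), function(i) {
      L <- sample_range(cfg$length_range[1], cfg$length_range[2])
      cov <- runif(1L, cfg$orf_coverage_range[1], cfg$orf_coverage_range[2])
      n_cod <- max(4L, min(floor(L * cov / 3), floor(L / 3)))
      orf <- random_orf(n_cod, cfg$codon_bias)
      rest <- L - 3L * n_cod
      utr5 <- sample_range(0L, rest)
      seq <- paste0(if (utr5 > 0) random_dna(utr5, cfg$gc) else "",
                    orf,
                    if (rest - utr5 > 0) random_dna(rest - utr5, cfg$gc) else "")
      tibble(transcript_id = sprintf("mrna_%05d", i), sequence = seq,
             planted_orf_nt = 3L * n_cod, planted_orf_start = utr5 + 1L)
    })
    out <- dplyr::bind_rows(rows)
  })
  if (cfg$n_mrna == 0L) {
    out <- tibble(transcript_id = character(), sequence = character(),
                  planted_orf_nt = integer(), planted_orf_start = integer())
  }
  list(sequences = out[c("transcript_id", "sequence")],
       truth = dplyr::mutate(out[-2], label = "mRNA"))
}

#' Simulate lncRNA-like transcripts
#'
#' GC-matched random sequences whose longest ORF (forward frames, complete or
#' running to the sequence end) is kept below `max_lnc_orf_nt` by repeatedly
#' truncating any over-long ORF with an early in-frame stop codon.
#'
#' @param cfg A [sim_config()].
#' @return List: `sequences` and `truth` (tibble with `label = "lncRNA"`).
#' @export
simulate_lncrna <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 2L, {
    rows <- lapply(seq_len(cfg$n_lnc), function(i) {
      L <- sample_range(cfg$length_range[1], cfg$length_range[2])
      tibble(transcript_id = sprintf("lnc_%05d", i),
             sequence = lnc_like_sequence(L, cfg))
    })
    out <- dplyr::bind_rows(rows)
  })
  if (cfg$n_lnc == 0L) {
    out <- tibble(transcript_id = character(), sequence = character())
  }
  list(sequences = out,
       truth = dplyr::mutate(out["transcript_id"], label = "lncRNA"))
}

# random sequence with all ORFs (stop-terminated or open-ended) shorter than
# cfg$max_lnc_orf_nt
lnc_like_sequence <- function(len, cfg) {
  seq <- random_dna(len, cfg$gc)
  for (iter in seq_len(200L)) {
    orf <- orf_scan_one(seq, require_stop = FALSE)
    if (orf$orf_length_nt < cfg$max_lnc_orf_nt) return(seq)
    # truncate the offending ORF with an early in-frame stop
    k <- max(1L, floor(cfg$max_lnc_orf_nt / 3) - 2L)
    at <- orf$orf_start + 3L * k
    substr(seq, at, at + 2L) <- "TAA"
  }
  stop("could not suppress long ORFs; increase max_lnc_orf_nt", call. = FALSE)
}

#' Simulate a toy genome with planted truth
#'
#' Lays out six reference genes on one chromosome and plants, one per
#' positional class, lncRNA loci satisfying the class geometry (an antisense
#' monoexonic locus over a gene exon, an intronic locus, a divergent
#' bidirectional locus within the TSS window, upstream and downstream loci
#' within the window, and a deep intergenic locus overlapping a transposable
#' element). Decoy candidates exercise every removal branch: a sub-200-nt
#' transcript, a non-antisense monoexonic transcript, a same-strand
#' exon-overlapping transcript, a re-assembled known mRNA, a protein-coding
#' transcript (long biased ORF), and a transcript with a strong protein
#' homology hit; two kept loci carry deliberately sub-threshold hits
#' (identity exactly at the cutoff, e-value above it). Writes standard
#' FASTA/GTF/BED/TSV files plus a truth table recording every candidate's
#' intended fate.
#'
#' @param cfg A [sim_config()] (the seed and GC settings are used).
#' @param outdir Output directory for `genome.fa`, `reference.gtf`,
#'   `candidates.gtf`, `candidates.fa`, `te.bed`, `hits.tsv`, `truth.tsv`.
#' @return List with the component tibbles (`reference`, `candidates`,
#'   `sequences`, `te`, `hits`, `truth`) and `paths` to the written files
#'   (when `outdir` is given).
#' @export
simulate_genome <- function(cfg = sim_config(), outdir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  gp <- cfg$genome_plan
  gap <- gp$gene_gap
  dgap <- gp$decoy_gap

  ref <- list(); cand <- list(); te <- list()
  exon_row <- function(tx, gene, s, e, strand) {
    tibble(transcript_id = tx, gene_id = gene, chrom = "chr1",
           start = as.integer(s), end = as.integer(e), strand = strand)
  }
  cur <- 2001L

  # gene 1 (+) with antisense and sense-overlap candidates
  g1 <- cur
  ref$G1 <- dplyr::bind_rows(exon_row("G1.t1", "G1", g1, g1 + 599L, "+"),
                             exon_row("G1.t1", "G1", g1 + 999L, g1 + 1599L, "+"))
  cand$L_anti <- exon_row("L_anti", "LOC_anti", g1 + 200L, g1 + 499L, "-")
  cand$D_sense <- dplyr::bind_rows(
    exon_row("D_sense", "LOC_dsense", g1 + 1099L, g1 + 1398L, "+"),
    exon_row("D_sense", "LOC_dsense", g1 + 1449L, g1 + 1548L, "+"))
  cur <- g1 + 1599L + gap

  # gene 2 (-) with an intronic candidate
  g2 <- cur
  ref$G2 <- dplyr::bind_rows(exon_row("G2.t1", "G2", g2, g2 + 499L, "-"),
                             exon_row("G2.t1", "G2", g2 + 1499L, g2 + 2099L, "-"))
  cand$L_intronic <- dplyr::bind_rows(
    exon_row("L_intronic", "LOC_intronic", g2 + 599L, g2 + 798L, "+"),
    exon_row("L_intronic", "LOC_intronic", g2 + 899L, g2 + 1098L, "+"))
  cur <- g2 + 2099L + gap

  # bidirectional locus divergent from gene 3's TSS
  lb <- cur
  cand$L_bidi <- dplyr::bind_rows(
    exon_row("L_bidi", "LOC_bidi", lb, lb + 299L, "-"),
    exon_row("L_bidi", "LOC_bidi", lb + 399L, lb + 698L, "-"))
  g3 <- lb + 1199L
  ref$G3 <- dplyr::bind_rows(exon_row("G3.t1", "G3", g3, g3 + 699L, "+"),
                             exon_row("G3.t1", "G3", g3 + 899L, g3 + 1499L, "+"))
  cur <- g3 + 1499L + gap

  # upstream locus ahead of gene 4 (same strand, so not bidirectional)
  lu <- cur
  cand$L_up <- dplyr::bind_rows(
    exon_row("L_up", "LOC_up", lu, lu + 299L, "+"),
    exon_row("L_up", "LOC_up", lu + 399L, lu + 598L, "+"))
  g4 <- lu + 1899L
  ref$G4 <- dplyr::bind_rows(exon_row("G4.t1", "G4", g4, g4 + 599L, "+"),
                             exon_row("G4.t1", "G4", g4 + 799L, g4 + 1399L, "+"))
  cur <- g4 + 1399L + gap

  # gene 5 with a downstream locus
  g5 <- cur
  ref$G5 <- dplyr::bind_rows(exon_row("G5.t1", "G5", g5, g5 + 599L, "+"),
                             exon_row("G5.t1", "G5", g5 + 799L, g5 + 1399L, "+"))
  g5e <- g5 + 1399L
  cand$L_down <- dplyr::bind_rows(
    exon_row("L_down", "LOC_down", g5e + 501L, g5e + 800L, "+"),
    exon_row("L_down", "LOC_down", g5e + 901L, g5e + 1200L, "+"))
  cur <- g5e + 1200L + gap

  # deep intergenic locus, partially TE-derived
  li <- cur
  cand$L_inter <- dplyr::bind_rows(
    exon_row("L_inter", "LOC_inter", li, li + 299L, "+"),
    exon_row("L_inter", "LOC_inter", li + 399L, li + 698L, "+"))
  te$TE1 <- tibble(chrom = "chr1", start = li + 100L, end = li + 149L,
                   family = "LTR/Copia")
  cur <- li + 698L + dgap + 2000L

  # decoys
  cand$D_short <- exon_row("D_short", "LOC_dshort", cur, cur + 149L, "+")
  cur <- cur + 149L + dgap
  cand$D_mono <- exon_row("D_mono", "LOC_dmono", cur, cur + 399L, "+")
  cur <- cur + 399L + dgap
  cand$D_coding <- dplyr::bind_rows(
    exon_row("D_coding", "LOC_dcoding", cur, cur + 449L, "+"),
    exon_row("D_coding", "LOC_dcoding", cur + 549L, cur + 998L, "+"))
  cur <- cur + 998L + dgap
  cand$D_homol <- dplyr::bind_rows(
    exon_row("D_homol", "LOC_dhomol", cur, cur + 299L, "+"),
    exon_row("D_homol", "LOC_dhomol", cur + 399L, cur + 698L, "+"))
  cur <- cur + 698L + dgap
  te$TE2 <- tibble(chrom = "chr1", start = cur, end = cur + 199L,
                   family = "DNA/MuDR")
  cur <- cur + 199L + 2000L

  # gene 6 plus a re-assembled copy of its transcript
  g6 <- cur
  ref$G6 <- dplyr::bind_rows(exon_row("G6.t1", "G6", g6, g6 + 499L, "+"),
                             exon_row("G6.t1", "G6", g6 + 699L, g6 + 1299L, "+"))
  cand$D_known <- dplyr::bind_rows(
    exon_row("D_known", "LOC_dknown", g6, g6 + 499L, "+"),
    exon_row("D_known", "LOC_dknown", g6 + 699L, g6 + 1299L, "+"))
  genome_len <- g6 + 1299L + 2000L

  reference <- dplyr::bind_rows(ref)
  candidates <- dplyr::bind_rows(cand)
  te_tbl <- dplyr::bind_rows(te)

  spliced_len <- function(ex) sum(ex$end - ex$start + 1L)
  genome <- withr::with_seed(cfg$seed + 3L, {
    chars <- strsplit(random_dna(genome_len, cfg$gc), "", fixed = TRUE)[[1]]
    plant <- function(chars, ex, spliced) {
      if (ex$strand[[1]] == "-") {
        spliced <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(spliced)))
      }
      ex <- ex[order(ex$start), , drop = FALSE]
      pos <- 1L
      for (j in seq_len(nrow(ex))) {
        w <- ex$end[[j]] - ex$start[[j]] + 1L
        chars[ex$start[[j]]:ex$end[[j]]] <-
          strsplit(substr(spliced, pos, pos + w - 1L), "", fixed = TRUE)[[1]]
        pos <- pos + w
      }
      chars
    }
    coding_seq <- function(len) {
      n_cod <- floor(len * 0.8 / 3)
      orf <- random_orf(n_cod, cfg$codon_bias)
      rest <- len - nchar(orf)
      utr5 <- rest %/% 2L
      paste0(random_dna(utr5, cfg$gc), orf, random_dna(rest - utr5, cfg$gc))
    }
    for (g in ref) chars <- plant(chars, g, coding_seq(spliced_len(g)))
    lnc_ids <- c("L_anti", "L_intronic", "L_bidi", "L_up", "L_down",
                 "L_inter", "D_mono", "D_short", "D_homol")
    for (id in lnc_ids) {
      chars <- plant(chars, cand[[id]], lnc_like_sequence(spliced_len(cand[[id]]), cfg))
    }
    chars <- plant(chars, cand$D_coding, coding_seq(spliced_len(cand$D_coding)))
    paste(chars, collapse = "")
  })
  genome_tbl <- tibble(transcript_id = "chr1", sequence = genome)
  sequences <- extract_transcript_seqs(candidates,
                                       setNames(Biostrings::DNAStringSet(genome), "chr1"))

  hits <- tibble(
    query_id = c("D_homol", "L_inter", "L_down"),
    subject_id = c("sp|P00001|FAKE1", "sp|P00002|FAKE2", "sp|P00003|FAKE3"),
    pident = c(85.0, 80.0, 90.0),
    length = c(180L, 150L, 120L), mismatch = c(10L, 20L, 8L),
    gapopen = c(1L, 2L, 1L), qstart = c(1L, 1L, 1L),
    qend = c(180L, 150L, 120L), sstart = c(1L, 1L, 1L),
    send = c(180L, 150L, 120L),
    evalue = c(1e-10, 1e-10, 1e-4), bitscore = c(200.0, 150.0, 120.0))

  truth <- tibble(
    transcript_id = c("L_anti", "L_intronic", "L_bidi", "L_up", "L_down",
                      "L_inter", "D_short", "D_mono", "D_sense", "D_known",
                      "D_coding", "D_homol"),
    fate = c(rep("kept", 6L), "removed_length", "removed_monoexonic",
             "removed_sense_overlap", "removed_sense_overlap",
             "removed_coding_potential", "removed_protein_homology"),
    lnc_class = c("ANTISENSE_EXONIC", "INTRONIC", "BIDIRECTIONAL", "UPSTREAM",
                  "DOWNSTREAM", "INTERGENIC", rep(NA_character_, 6L)),
    te_derived = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
                   rep(NA, 6L)),
    schema_version = "plantlnc-truth-1")

  out <- list(reference = reference, candidates = candidates,
              sequences = sequences, genome = genome_tbl, te = te_tbl,
              hits = hits, truth = truth, paths = NULL)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      genome = file.path(outdir, "genome.fa"),
      reference = file.path(outdir, "reference.gtf"),
      candidates = file.path(outdir, "candidates.gtf"),
      sequences = file.path(outdir, "candidates.fa"),
      te = file.path(outdir, "te.bed"),
      hits = file.path(outdir, "hits.tsv"),
      truth = file.path(outdir, "truth.tsv"))
    write_fasta(genome_tbl, paths$genome)
    write_gtf(reference, paths$reference, source = "plantlnc_sim")
    write_gtf(candidates, paths$candidates, source = "plantlnc_sim")
    write_fasta(sequences, paths$sequences)
    writeLines(sprintf("chr1\t%d\t%d\t%s\t0\t+", te_tbl$start - 1L,
                       te_tbl$end, te_tbl$family), paths$te)
    readr::write_tsv(hits, paths$hits, col_names = FALSE)
    readr::write_tsv(truth, paths$truth)
    out$paths <- paths
  }
  out
}
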