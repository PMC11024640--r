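#' Pipeline configuration
#'
#' Thresholds for the identification/characterization stages. Defaults follow
#' the published pipeline settings: minimum transcript length 200 nt,
#' monoexonic transcripts kept only when antisense to a reference exon,
#' a 2000-bp window for the proximal positional classes, protein-homology
#' cutoffs of identity > 80 and e-value < 1e-5 (strict inequalities), a 1-bp
#' minimum TE overlap, and an 80% identity threshold for redundancy removal.
#'
#' @param min_length_nt Minimum exonic length kept.
#' @param monoex_mode One of `"antisense_only"`, `"keep_all"`,
#'   `"discard_all"` — handling of monoexonic candidates.
#' @param window_bp Window for upstream/downstream/bidirectional classes.
#' @param identity_cutoff,evalue_cutoff Homology-filter thresholds.
#' @param te_min_overlap_bp Minimum exonic TE overlap to call a lncRNA
#'   TE-derived.
#' @param dedup_identity Pairwise identity threshold for [deduplicate()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_length_nt = 200L,
                            monoex_mode = c("antisense_only", "keep_all",
                                            "discard_all"),
                            window_bp = 2000L,
                            identity_cutoff = 80,
                            evalue_cutoff = 1e-5,
                            te_min_overlap_bp = 1L,
                            dedup_identity = 0.80) {
  monoex_mode <- match.arg(monoex_mode)
  stopifnot(min_length_nt > 0, window_bp >= 0, identity_cutoff > 0,
            evalue_cutoff > 0, te_min_overlap_bp > 0,
            dedup_identity > 0, dedup_identity < 1)
  structure(list(min_length_nt = min_length_nt, monoex_mode = monoex_mode,
                 window_bp = window_bp, identity_cutoff = identity_cutoff,
                 evalue_cutoff = evalue_cutoff,
                 te_min_overlap_bp = te_min_overlap_bp,
                 dedup_identity = dedup_identity),
            class = "pipeline_config")
}

#' Filter assembled candidates against a reference annotation
#'
#' Removes, in order of precedence per transcript: (1) transcripts whose
#' exonic length is below `min_length_nt`; (2) monoexonic transcripts
#' according to `monoex_mode` (`antisense_only` keeps a monoexonic candidate
#' only when one of its exons overlaps a reference exon on the opposite
#' strand); (3) transcripts with any same-strand exon-level overlap of a
#' known mRNA exon. Antisense exon overlap is never a removal cause — it is a
#' positional class. Each removed transcript appears exactly once in the
#' removal log with its first failing rule.
#'
#' @param candidates Exon tibble of assembled candidates.
#' @param reference Exon tibble of known mRNAs.
#' @param cfg A [pipeline_config()].
#' @return List: `kept` (exon tibble) and `removed` (tibble `transcript_id`,
#'   `reason` in `{"length", "monoexonic", "sense_overlap"}`).
#' @export
filter_candidates <- function(candidates, reference, cfg = pipeline_config()) {
  validate_exons(candidates)
  validate_exons(reference)
  spans <- transcript_spans(candidates)
  unknown <- setdiff(unique(candidates$chrom), unique(reference$chrom))
  if (length(unknown) > 0L) {
    warning("chromosomes absent from reference: ",
            paste(unknown, collapse = ", "),
            "; transcripts there have no reference context", call. = FALSE)
  }
  cand_gr <- exons_granges(candidates)
  ref_gr <- exons_granges(reference)
  same <- GenomicRanges::findOverlaps(cand_gr, ref_gr, ignore.strand = FALSE)
  anti_gr <- cand_gr
  GenomicRanges::strand(anti_gr) <-
    ifelse(as.character(GenomicRanges::strand(cand_gr)) == "+", "-", "+")
  anti <- GenomicRanges::findOverlaps(anti_gr, ref_gr, ignore.strand = FALSE)
  sense_ids <- unique(cand_gr$transcript_id[S4Vectors::queryHits(same)])
  anti_ids <- unique(cand_gr$transcript_id[S4Vectors::queryHits(anti)])

  reason <- rep(NA_character_, nrow(spans))
  short <- spans$exonic_length < cfg$min_length_nt
  reason[short] <- "length"
  mono <- spans$n_exons == 1L
  mono_fail <- switch(cfg$monoex_mode,
                      keep_all = rep(FALSE, nrow(spans)),
                      discard_all = mono,
                      antisense_only = mono & !(spans$transcript_id %in% anti_ids))
  reason[is.na(reason) & mono_fail] <- "monoexonic"
  reason[is.na(reason) & spans$transcript_id %in% sense_ids] <- "sense_overlap"

  removed <- tibble(transcript_id = spans$transcript_id[!is.na(reason)],
                    reason = reason[!is.na(reason)])
  kept_ids <- spans$transcript_id[is.na(reason)]
  list(kept = candidates[candidates$transcript_id %in% kept_ids, , drop = FALSE],
       removed = removed)
}

#' Read protein-homology hits in 12-column tabular alignment format
#'
#' Standard tabular alignment columns (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore); extra trailing columns
#' are tolerated.
#'
#' @param path Path to the tab-separated hits file (no header).
#' @return Tibble with at least `query_id`, `subject_id`, `pident`, `evalue`.
#' @export
read_alignment_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(query_id = character(), subject_id = character(),
                  pident = numeric(), evalue = numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 12L)) {
    stop("malformed alignment line ", which(nfield < 12L)[1],
         ": expected >= 12 tab-separated columns", call. = FALSE)
  }
  pident <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  evalue <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 11L)))
  bad <- which(is.na(pident) | is.na(evalue) | pident < 0 | pident > 100 |
                 evalue < 0)
  if (length(bad) > 0L) {
    stop("malformed alignment line ", bad[1], ": bad pident/evalue",
         call. = FALSE)
  }
  tibble(query_id = vapply(parts, `[[`, "", 1L),
         subject_id = vapply(parts, `[[`, "", 2L),
         pident = pident, evalue = evalue)
}

#' Remove candidates with strong protein homology
#'
#' A candidate is flagged as potentially coding iff ANY of its hits has
#' `pident > identity_cutoff` AND `evalue < evalue_cutoff` (both strict).
#' Candidates without hits are kept.
#'
#' @param candidates Tibble with a `transcript_id` column (exon tibble or
#'   sequence tibble).
#' @param hits A [read_alignment_hits()] tibble.
#' @param cfg A [pipeline_config()].
#' @return List: `kept` (subset of `candidates`) and `flagged_coding`
#'   (tibble `transcript_id`).
#' @export
homology_filter <- function(candidates, hits, cfg = pipeline_config()) {
  stopifnot("transcript_id" %in% names(candidates))
  strong <- hits$pident > cfg$identity_cutoff & hits$evalue < cfg$evalue_cutoff
  flagged <- unique(hits$query_id[strong])
  flagged <- flagged[flagged %in% candidates$transcript_id]
  list(kept = candidates[!candidates$transcript_id %in% flagged, , drop = FALSE],
       flagged_coding = tibble(transcript_id = flagged))
}

LNC_CLASSES <- c("ANTISENSE_EXONIC", "INTRONIC", "BIDIRECTIONAL",
                 "UPSTREAM", "DOWNSTREAM", "INTERGENIC")

#' Six-way positional classification of lncRNAs
#'
#' Each lncRNA receives exactly one class, the first that matches in
#' precedence order:
#' 1. `ANTISENSE_EXONIC` — exon overlap with a gene's exon on the opposite
#'    strand;
#' 2. `INTRONIC` — overlaps a gene's span with no exon-exon overlap (either
#'    strand);
#' 3. `BIDIRECTIONAL` — no gene-span overlap; the lncRNA lies on the opposite
#'    strand of the nearest gene, upstream of and transcribed divergently
#'    from it, with its TSS within `window_bp` of that gene's TSS;
#' 4. `UPSTREAM` — no overlap; wholly 5' of a gene with the gap from the
#'    lncRNA 3' end to the gene TSS at most `window_bp`;
#' 5. `DOWNSTREAM` — no overlap; wholly 3' of a gene with the gap from the
#'    gene TTS to the lncRNA 5' end at most `window_bp`;
#' 6. `INTERGENIC` — otherwise.
#' The partner is the gene triggering the class (nearest by distance on ties,
#' then lexicographically smallest `gene_id`); distances are gap widths in bp
#' (0 for the overlap classes).
#'
#' @param lncs Exon tibble of lncRNA transcripts.
#' @param reference Exon tibble of known mRNAs (genes derived from
#'   `gene_id`). With zero genes everything is `INTERGENIC`.
#' @param cfg A [pipeline_config()].
#' @return Tibble: `transcript_id`, `lnc_class`, `partner_gene`
#'   (`NA` for `INTERGENIC`), `distance_bp`.
#' @export
classify_positions <- function(lncs, reference, cfg = pipeline_config()) {
  validate_exons(lncs)
  spans <- transcript_spans(lncs)
  if (nrow(reference) == 0L) {
    return(tibble(transcript_id = spans$transcript_id,
                  lnc_class = "INTERGENIC",
                  partner_gene = NA_character_, distance_bp = NA_integer_))
  }
  validate_exons(reference)
  genes <- gene_models(reference)
  res <- lapply(seq_len(nrow(spans)), function(i) {
    classify_one_position(spans[i, ], lncs[lncs$transcript_id ==
                                             spans$transcript_id[[i]], ],
                          genes, reference, cfg)
  })
  dplyr::bind_rows(res)
}

# gap in bases between two 1-based inclusive intervals/positions
gap_bp <- function(left_end, right_start) right_start - left_end - 1L

classify_one_position <- function(span, lnc_exons, genes, ref_exons, cfg) {
  g <- genes[genes$chrom == span$chrom, , drop = FALSE]
  out <- function(cls, partner, dist) {
    tibble(transcript_id = span$transcript_id, lnc_class = cls,
           partner_gene = partner, distance_bp = dist)
  }
  if (nrow(g) == 0L) return(out("INTERGENIC", NA_character_, NA_integer_))

  span_olap <- g$start <= span$end & g$end >= span$start
  if (any(span_olap)) {
    cand <- g[span_olap, , drop = FALSE]
    # exon-exon overlap per overlapping gene, by strand relation
    anti_genes <- character()
    exon_olap_genes <- character()
    for (j in seq_len(nrow(cand))) {
      ge <- ref_exons[ref_exons$gene_id == cand$gene_id[[j]], , drop = FALSE]
      hit <- outer(lnc_exons$start, ge$end, `<=`) &
        outer(lnc_exons$end, ge$start, `>=`)
      if (any(hit)) {
        exon_olap_genes <- c(exon_olap_genes, cand$gene_id[[j]])
        if (cand$strand[[j]] != span$strand) {
          anti_genes <- c(anti_genes, cand$gene_id[[j]])
        }
      }
    }
    if (length(anti_genes) > 0L) {
      return(out("ANTISENSE_EXONIC", sort(anti_genes)[1], 0L))
    }
    intronic <- setdiff(cand$gene_id, exon_olap_genes)
    if (length(intronic) > 0L) {
      return(out("INTRONIC", sort(intronic)[1], 0L))
    }
    # remaining span-overlapping genes had same-strand exon overlap
    # (normally filtered out earlier); fall through to proximal rules
  }

  no_olap <- g[!span_olap, , drop = FALSE]
  if (nrow(no_olap) == 0L) return(out("INTERGENIC", NA_character_, NA_integer_))
  # gap to each non-overlapping gene
  gaps <- ifelse(no_olap$end < span$start,
                 gap_bp(no_olap$end, span$start),
                 gap_bp(span$end, no_olap$start))

  # rule 3: divergent transcription from near the nearest gene's TSS
  ord <- order(gaps, no_olap$gene_id)
  nearest <- no_olap[ord[1], , drop = FALSE]
  lnc_tss <- if (span$strand == "+") span$start else span$end
  if (nearest$strand != span$strand) {
    upstream_of_gene <- if (nearest$strand == "+") {
      span$end < nearest$start && span$strand == "-"
    } else {
      span$start > nearest$end && span$strand == "+"
    }
    if (upstream_of_gene && abs(nearest$tss - lnc_tss) <= cfg$window_bp) {
      return(out("BIDIRECTIONAL", nearest$gene_id, abs(nearest$tss - lnc_tss)))
    }
  }

  # rule 4: wholly 5' of a gene, lnc 3' end within window of the gene TSS
  lnc_3p <- if (span$strand == "+") span$end else span$start
  lnc_5p <- if (span$strand == "+") span$start else span$end
  up_ok <- ifelse(no_olap$strand == "+",
                  span$end < no_olap$start,
                  span$start > no_olap$end)
  up_dist <- abs(no_olap$tss - lnc_3p)
  up_hit <- up_ok & up_dist <= cfg$window_bp
  if (any(up_hit)) {
    cand <- no_olap[up_hit, , drop = FALSE]
    d <- up_dist[up_hit]
    j <- order(d, cand$gene_id)[1]
    return(out("UPSTREAM", cand$gene_id[[j]], as.integer(d[[j]])))
  }

  # rule 5: wholly 3' of a gene, gene TTS within window of the lnc 5' end
  down_ok <- ifelse(no_olap$strand == "+",
                    span$start > no_olap$end,
                    span$end < no_olap$start)
  down_dist <- abs(lnc_5p - no_olap$tts)
  down_hit <- down_ok & down_dist <= cfg$window_bp
  if (any(down_hit)) {
    cand <- no_olap[down_hit, , drop = FALSE]
    d <- down_dist[down_hit]
    j <- order(d, cand$gene_id)[1]
    return(out("DOWNSTREAM", cand$gene_id[[j]], as.integer(d[[j]])))
  }
  out("INTERGENIC", NA_character_, NA_integer_)
}

#' Transposable-element origin of lncRNAs
#'
#' Exonic overlap with the union of TE intervals (strand-agnostic). A lncRNA
#' is TE-derived iff its total exonic TE overlap reaches
#' `te_min_overlap_bp`; all families of intersecting TEs are reported.
#'
#' @param lncs Exon tibble of lncRNA transcripts.
#' @param te TE interval tibble from [read_bed()] (`chrom`, `start`, `end`,
#'   `family`).
#' @param cfg A [pipeline_config()].
#' @return Tibble: `transcript_id`, `te_overlap_bp`, `te_fraction`,
#'   `te_families` (comma-separated, sorted), `is_te_derived`.
#' @export
te_origin <- function(lncs, te, cfg = pipeline_config()) {
  validate_exons(lncs)
  spans <- transcript_spans(lncs)
  if (nrow(te) == 0L) {
    return(tibble(transcript_id = spans$transcript_id, te_overlap_bp = 0L,
                  te_fraction = 0, te_families = "", is_te_derived = FALSE))
  }
  te_gr <- GenomicRanges::GRanges(te$chrom, IRanges::IRanges(te$start, te$end),
                                  strand = "*", family = te$family)
  te_union <- GenomicRanges::reduce(te_gr, ignore.strand = TRUE)
  lnc_gr <- exons_granges(lncs)
  ov_union <- GenomicRanges::findOverlaps(lnc_gr, te_union, ignore.strand = TRUE)
  olap_w <- GenomicRanges::width(IRanges::pintersect(
    lnc_gr[S4Vectors::queryHits(ov_union)],
    te_union[S4Vectors::subjectHits(ov_union)], ignore.strand = TRUE))
  bp <- tapply(olap_w, lnc_gr$transcript_id[S4Vectors::queryHits(ov_union)], sum)
  ov_fam <- GenomicRanges::findOverlaps(lnc_gr, te_gr, ignore.strand = TRUE)
  fams <- tapply(te_gr$family[S4Vectors::subjectHits(ov_fam)],
                 lnc_gr$transcript_id[S4Vectors::queryHits(ov_fam)],
                 function(x) paste(sort(unique(x)), collapse = ","))
  overlap <- as.integer(bp[spans$transcript_id])
  overlap[is.na(overlap)] <- 0L
  families <- as.character(fams[spans$transcript_id])
  families[is.na(families)] <- ""
  tibble(transcript_id = spans$transcript_id,
         te_overlap_bp = overlap,
         te_fraction = overlap / spans$exonic_length,
         te_families = families,
         is_te_derived = overlap >= cfg$te_min_overlap_bp)
}

#' Greedy redundancy removal (CD-HIT-EST-style)
#'
#' Sequences are sorted by length descending (ties by id); each sequence
#' joins the first representative whose pairwise identity with it exceeds the
#' threshold, otherwise it becomes a new representative. Identity is the
#' number of matched columns of the best local alignment (match +1,
#' mismatch -1, gap open -2, gap extend -1) divided by the length of the
#' shorter sequence.
#'
#' @param seqs Sequence tibble.
#' @param identity Identity threshold in (0, 1); default 0.80.
#' @return List: `representatives` (sequence tibble) and `clusters` (tibble
#'   `transcript_id`, `representative_id`).
#' @export
deduplicate <- function(seqs, identity = 0.80) {
  stopifnot(identity > 0, identity < 1)
  if (nrow(seqs) == 0L) {
    return(list(representatives = seqs,
                clusters = tibble(transcript_id = character(),
                                  representative_id = character())))
  }
  validate_sequences(seqs)
  ord <- order(-nchar(seqs$sequence), seqs$transcript_id)
  seqs <- seqs[ord, , drop = FALSE]
  reps <- integer(0)
  assign <- character(nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    placed <- FALSE
    for (r in reps) {
      pid <- pairwise_identity(seqs$sequence[[i]], seqs$sequence[[r]])
      if (pid > identity) {
        assign[[i]] <- seqs$transcript_id[[r]]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[[i]] <- seqs$transcript_id[[i]]
    }
  }
  list(representatives = seqs[reps, , drop = FALSE],
       clusters = tibble(transcript_id = seqs$transcript_id,
                         representative_id = assign))
}

# matched columns of best local alignment / length of the shorter sequence
pairwise_identity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 2, gapExtension = 1)
  Biostrings::nmatch(al) / min(nchar(a), nchar(b))
}

#' Run the full lncRNA identification and characterization pipeline
#'
#' Stages, applied in order: candidate filtering against the reference
#' annotation; coding-potential prediction with the stringent two-model
#' ensemble; protein-homology filtering; six-way positional classification;
#' TE origin. The summary reports counts entering and leaving each stage and
#' satisfies the conservation law
#' `input = kept + sum(removed per stage)`.
#'
#' @param candidates_gtf Assembled candidate models (GTF path or exon tibble).
#' @param tx_fasta Candidate spliced sequences (FASTA path or sequence
#'   tibble).
#' @param reference_gtf Known mRNA annotation (GTF path or exon tibble).
#' @param model_a,model_b Trained member models (`lnc_model` objects or paths
#'   from [write_model()]); both must bundle a hexamer table when their
#'   schema needs one.
#' @param hits Protein-homology hits (path to 12-column tabular file or
#'   tibble); `NULL` skips the homology stage.
#' @param te TE annotation (BED path or tibble); `NULL` skips TE origin.
#' @param cfg A [pipeline_config()].
#' @param outdir Output directory; when non-`NULL`, writes `lncRNA.gtf`,
#'   `lncRNA.fa`, `classification.tsv` and `summary.tsv`.
#' @return List with `lncrna` (exon tibble), `sequences`, `classification`
#'   (per-lncRNA class/partner/distance/TE columns), `summary` (stage
#'   counts), `removed` (transcript/stage/reason log), and `calls` (ensemble
#'   scores for all stage-1 survivors).
#' @export
run_pipeline <- function(candidates_gtf, tx_fasta, reference_gtf,
                         model_a, model_b, hits = NULL, te = NULL,
                         cfg = pipeline_config(), outdir = NULL) {
  candidates <- if (is.character(candidates_gtf)) read_gtf(candidates_gtf) else candidates_gtf
  reference <- if (is.character(reference_gtf)) read_gtf(reference_gtf) else reference_gtf
  seqs <- if (is.character(tx_fasta)) read_fasta(tx_fasta) else tx_fasta
  if (is.character(model_a)) model_a <- read_model(model_a)
  if (is.character(model_b)) model_b <- read_model(model_b)
  if (is.character(hits)) hits <- read_alignment_hits(hits)
  if (is.character(te)) te <- read_bed(te)

  n_in <- length(unique(candidates$transcript_id))
  missing_seq <- setdiff(unique(candidates$transcript_id), seqs$transcript_id)
  if (length(missing_seq) > 0L) {
    stop("stage filter: no sequence for transcript ", missing_seq[[1]],
         call. = FALSE)
  }

  # stage 1: structural filter
  flt <- filter_candidates(candidates, reference, cfg)
  kept1 <- flt$kept
  removed <- dplyr::mutate(flt$removed, stage = "filter")
  ids1 <- unique(kept1$transcript_id)

  # stage 2: ensemble coding-potential prediction
  calls <- NULL
  if (length(ids1) > 0L) {
    s1 <- seqs[match(ids1, seqs$transcript_id), , drop = FALSE]
    fa <- extract_features(s1, model_a$spec$schema,
                           hexamer_table = model_a$hexamer_table)
    fb <- extract_features(s1, model_b$spec$schema,
                           hexamer_table = model_b$hexamer_table)
    calls <- ensemble_classify(fa, fb, model_a, model_b)
    coding_ids <- calls$transcript_id[calls$label == "mRNA"]
  } else {
    coding_ids <- character()
  }
  removed <- dplyr::bind_rows(removed,
                              tibble(transcript_id = coding_ids,
                                     reason = "coding_potential",
                                     stage = "ensemble"))
  kept2 <- kept1[!kept1$transcript_id %in% coding_ids, , drop = FALSE]

  # stage 3: protein homology
  if (!is.null(hits)) {
    hf <- homology_filter(kept2, hits, cfg)
    kept3 <- hf$kept
    removed <- dplyr::bind_rows(removed,
                                tibble(transcript_id = hf$flagged_coding$transcript_id,
                                       reason = "protein_homology",
                                       stage = "homology"))
  } else {
    kept3 <- kept2
  }

  # stages 4-5: classification and TE origin
  ids3 <- unique(kept3$transcript_id)
  if (length(ids3) > 0L) {
    classification <- classify_positions(kept3, reference, cfg)
    if (!is.null(te)) {
      classification <- dplyr::left_join(classification, te_origin(kept3, te, cfg),
                                         by = "transcript_id")
    } else {
      classification <- dplyr::mutate(classification, te_overlap_bp = 0L,
                                      te_fraction = 0, te_families = "",
                                      is_te_derived = FALSE)
    }
  } else {
    classification <- tibble(transcript_id = character(),
                             lnc_class = character(),
                             partner_gene = character(),
                             distance_bp = integer(), te_overlap_bp = integer(),
                             te_fraction = numeric(), te_families = character(),
                             is_te_derived = logical())
  }

  n2 <- length(unique(kept2$transcript_id))
  stage_in <- c(n_in, length(ids1), n2, length(ids3))
  stage_kept <- c(length(ids1), n2, length(ids3), length(ids3))
  smry <- tibble(stage = c("filter", "ensemble", "homology", "classify"),
                 n_in = stage_in, kept = stage_kept,
                 removed = stage_in - stage_kept)

  out_seqs <- seqs[seqs$transcript_id %in% ids3, , drop = FALSE]
  result <- list(lncrna = kept3, sequences = out_seqs,
                 classification = classification, summary = smry,
                 removed = removed, calls = calls)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (nrow(kept3) > 0L) {
      write_gtf(kept3, file.path(outdir, "lncRNA.gtf"))
    } else {
      writeLines(character(), file.path(outdir, "lncRNA.gtf"))
    }
    write_fasta(out_seqs, file.path(outdir, "lncRNA.fa"))
    readr::write_tsv(classification, file.path(outdir, "classification.tsv"))
    readr::write_tsv(smry, file.path(outdir, "summary.tsv"))
  }
  result
}
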