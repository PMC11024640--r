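test_that("generators are pure functions of their configuration", {
  cfg <- sim_config(seed = 17, n_mrna = 20, n_lnc = 20)
  expect_identical(simulate_mrna(cfg), simulate_mrna(cfg))
  expect_identical(simulate_lncrna(cfg), simulate_lncrna(cfg))
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$candidates, g2$candidates)
  # and the global RNG state is untouched
  withr::with_seed(1, before <- runif(1))
  withr::with_seed(1, {
    invisible(simulate_mrna(cfg))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("simulated mRNAs carry long codon-biased ORFs", {
  cfg <- sim_config(seed = 23, n_mrna = 40, n_lnc = 0)
  sim <- simulate_mrna(cfg)
  orfs <- find_longest_orf(sim$sequences, require_stop = TRUE)
  lens <- nchar(sim$sequences$sequence)
  expect_true(all(orfs$orf_length_nt >= 0.5 * lens))
  expect_true(all(orfs$orf_length_nt >= sim$truth$planted_orf_nt))
  expect_true(all(lens >= cfg$length_range[1] & lens <= cfg$length_range[2]))
})

test_that("simulated lncRNAs lack long ORFs and match the target GC", {
  cfg <- sim_config(seed = 29, n_mrna = 0, n_lnc = 150)
  sim <- simulate_lncrna(cfg)
  orfs <- find_longest_orf(sim$sequences, require_stop = FALSE)
  expect_true(all(orfs$orf_length_nt < cfg$max_lnc_orf_nt))
  gc <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(sim$sequences$sequence), "GC", as.prob = TRUE)
  expect_lt(abs(mean(gc) - cfg$gc), 0.02)
  expect_true(all(nchar(sim$sequences$sequence) >= 200))
})

test_that("empty generation produces valid empty FASTA", {
  cfg <- sim_config(seed = 1, n_mrna = 0, n_lnc = 0)
  sim <- simulate_mrna(cfg)
  expect_equal(nrow(sim$sequences), 0L)
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(sim$sequences, path)
  expect_equal(file.size(path), 0)
})

test_that("the planted genome is internally consistent", {
  g <- simulate_genome(sim_config(seed = 11), outdir = withr::local_tempdir())
  # candidate sequences re-extracted from the genome FASTA match the shipped
  # candidate FASTA (format round trip)
  seqs <- extract_transcript_seqs(g$candidates, g$paths$genome)
  fa <- read_fasta(g$paths$sequences)
  expect_equal(dplyr::arrange(seqs, transcript_id),
               dplyr::arrange(fa, transcript_id))
  # each planted class locus is recovered by positional classification alone
  kept <- g$truth$transcript_id[g$truth$fate == "kept"]
  cls <- classify_positions(
    g$candidates[g$candidates$transcript_id %in% kept, ], g$reference)
  truth_cls <- g$truth[match(cls$transcript_id, g$truth$transcript_id), ]
  expect_equal(cls$lnc_class, truth_cls$lnc_class)
  expect_setequal(cls$lnc_class, c("ANTISENSE_EXONIC", "INTRONIC",
                                   "BIDIRECTIONAL", "UPSTREAM", "DOWNSTREAM",
                                   "INTERGENIC"))
  # structural filter reproduces the planted decoy fates
  flt <- filter_candidates(g$candidates, g$reference, pipeline_config())
  planted <- g$truth[g$truth$fate %in% c("removed_length",
                                         "removed_monoexonic",
                                         "removed_sense_overlap"), ]
  got <- flt$removed[match(planted$transcript_id,
                           flt$removed$transcript_id), ]
  expect_equal(paste0("removed_", got$reason), planted$fate)
  expect_equal(nrow(flt$removed), nrow(planted))
})
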