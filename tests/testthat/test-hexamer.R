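test_that("hexamer table frequencies equal a hand tally on toy inputs", {
  # coding "ATGAAATTTTAG": longest ORF is the whole 12 nt; in-frame hexamers
  # ATGAAA, AAATTT, TTTTAG. noncoding "ACGTACGTACGT": 7 step-1 hexamers.
  tab <- build_hexamer_table(seq_tbl(c1 = "ATGAAATTTTAG"),
                             seq_tbl(n1 = "ACGTACGTACGT"),
                             pseudocount = 1)
  cf <- setNames(tab$coding_logfreq, tab$hexamer)
  nf <- setNames(tab$noncoding_logfreq, tab$hexamer)
  expect_equal(unname(exp(cf["ATGAAA"])), 2 / (3 + 4096), tolerance = 1e-12)
  expect_equal(unname(exp(cf["AAATTT"])), 2 / (3 + 4096), tolerance = 1e-12)
  expect_equal(unname(exp(cf["CCCCCC"])), 1 / (3 + 4096), tolerance = 1e-12)
  expect_equal(unname(exp(nf["ACGTAC"])), 3 / (7 + 4096), tolerance = 1e-12)
  expect_equal(unname(exp(nf["CGTACG"])), 3 / (7 + 4096), tolerance = 1e-12)
  # each background is a proper distribution over all 4096 hexamers
  expect_equal(sum(exp(tab$coding_logfreq)), 1, tolerance = 1e-9)
  expect_equal(sum(exp(tab$noncoding_logfreq)), 1, tolerance = 1e-9)
  expect_equal(nrow(tab), 4096L)
})

test_that("a uniform table scores every sequence zero", {
  withr::with_seed(3, {
    seqs <- random_seq_tbl(10, c(50, 200))
    tab <- build_hexamer_table(seqs, seqs, pseudocount = 1)
    # force identical backgrounds: the log-ratio of equals is zero everywhere
    tab$noncoding_logfreq <- tab$coding_logfreq
    expect_equal(hexamer_score(seqs, tab)$hexamer_score,
                 rep(0, nrow(seqs)), tolerance = 1e-12)
  })
})

test_that("swapping the backgrounds negates the score", {
  withr::with_seed(8, {
    a <- random_seq_tbl(15, c(100, 400))
    b <- random_seq_tbl(15, c(100, 400))
    b$transcript_id <- paste0("b", seq_len(nrow(b)))
    probe <- random_seq_tbl(10, c(60, 300))
    tab <- build_hexamer_table(a, b)
    swapped <- build_hexamer_table(b, a)
    # swapping coding/noncoding roles changes which convention counts each
    # set, so negation holds exactly for the log-ratio of a FIXED table pair
    lr <- setNames(tab$coding_logfreq - tab$noncoding_logfreq, tab$hexamer)
    expect_s3_class(swapped, "hexamer_table")
    flipped <- tab
    flipped$coding_logfreq <- tab$noncoding_logfreq
    flipped$noncoding_logfreq <- tab$coding_logfreq
    expect_equal(hexamer_score(probe, flipped)$hexamer_score,
                 -hexamer_score(probe, tab)$hexamer_score, tolerance = 1e-12)
  })
})

test_that("score is the mean log-ratio over the ORF hexamers", {
  tab <- build_hexamer_table(seq_tbl(c1 = "ATGAAATTTTAG"),
                             seq_tbl(n1 = "ACGTACGTACGT"))
  lr <- setNames(tab$coding_logfreq - tab$noncoding_logfreq, tab$hexamer)
  # probe ORF "ATGAAATTTTAG" contributes exactly 3 in-frame hexamers
  got <- hexamer_score(seq_tbl(p = "ATGAAATTTTAG"), tab)$hexamer_score
  expect_equal(got, mean(lr[c("ATGAAA", "AAATTT", "TTTTAG")]),
               tolerance = 1e-12)
  # duplicating the hexamer multiset leaves the mean unchanged
  got2 <- hexamer_score(seq_tbl(p = "ATGAAATTTATGAAATTTTAG"), tab)$hexamer_score
  orf <- find_longest_orf(seq_tbl(p = "ATGAAATTTATGAAATTTTAG"),
                          require_stop = FALSE)
  expect_equal(orf$orf_length_nt, 21L)
  expect_equal(got2, mean(lr[c("ATGAAA", "AAATTT", "TTTATG", "ATGAAA",
                               "AAATTT", "TTTTAG")]), tolerance = 1e-12)
})

test_that("tables survive a TSV round trip", {
  tab <- build_hexamer_table(seq_tbl(a = "ATGAAATTTTAG"),
                             seq_tbl(b = "ACGTACGTACGT"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hexamer_table(tab, path)
  back <- read_hexamer_table(path)
  expect_equal(back$coding_logfreq, tab$coding_logfreq, tolerance = 1e-12)
  expect_equal(back$noncoding_logfreq, tab$noncoding_logfreq, tolerance = 1e-12)
})

test_that("degenerate inputs behave as documented", {
  expect_error(build_hexamer_table(seq_tbl(), seq_tbl(a = "ACGTACGTACGT")),
               "empty")
  # all-A coding input: AAAAAA is the modal coding hexamer
  tab <- build_hexamer_table(seq_tbl(a = paste0("ATG", strrep("A", 60))),
                             seq_tbl(b = "ACGTACGTACGT"), pseudocount = 1)
  expect_equal(tab$hexamer[which.max(tab$coding_logfreq)], "AAAAAA")
  # N-containing hexamers are skipped; all-N sequence scores 0
  expect_equal(hexamer_score(seq_tbl(x = strrep("N", 50)), tab)$hexamer_score, 0)
})
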