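# two small models over different schemas, trained on shared sequences
train_pair <- function(n = 120, seed = 31) {
  cfg <- sim_config(seed = seed, n_mrna = n, n_lnc = n,
                    length_range = c(300L, 800L))
  m <- simulate_mrna(cfg)$sequences
  l <- simulate_lncrna(cfg)$sequences
  list(pos = l, neg = m,
       a = train_coding_model(l, m, model_spec("logistic", "cpat"), seed = seed),
       b = train_coding_model(l, m, model_spec("svm_rbf", "lncfinder-lite"),
                              seed = seed))
}

test_that("the ensemble implements the intersection rule exactly", {
  pair <- train_pair()
  withr::with_seed(77, {
    cfg <- sim_config(seed = 78, n_mrna = 40, n_lnc = 40,
                      length_range = c(300L, 800L))
    test <- dplyr::bind_rows(simulate_lncrna(cfg)$sequences,
                             simulate_mrna(cfg)$sequences)
  })
  fa <- extract_features(test, "cpat", pair$a$hexamer_table)
  fb <- extract_features(test, "lncfinder-lite", pair$b$hexamer_table)
  ens <- ensemble_classify(fa, fb, pair$a, pair$b)
  ca <- classify(fa, pair$a)
  cb <- classify(fb, pair$b)
  want <- ifelse(ca$label == "lncRNA" & cb$label == "lncRNA", "lncRNA", "mRNA")
  expect_equal(ens$label, want)
  # positive set is the intersection of the member positive sets
  expect_setequal(ens$transcript_id[ens$label == "lncRNA"],
                  intersect(ca$transcript_id[ca$label == "lncRNA"],
                            cb$transcript_id[cb$label == "lncRNA"]))
})

test_that("ensemble FP and TP sets are bounded by both members", {
  pair <- train_pair()
  # random truth assignments make the bound a pure set-theoretic property
  withr::with_seed(55, {
    cfg <- sim_config(seed = 56, n_mrna = 30, n_lnc = 30,
                      length_range = c(300L, 600L))
    test <- dplyr::bind_rows(simulate_lncrna(cfg)$sequences,
                             simulate_mrna(cfg)$sequences)
    fa <- extract_features(test, "cpat", pair$a$hexamer_table)
    fb <- extract_features(test, "lncfinder-lite", pair$b$hexamer_table)
    ens <- ensemble_classify(fa, fb, pair$a, pair$b)
    ca <- classify(fa, pair$a)
    cb <- classify(fb, pair$b)
    for (rep in 1:10) {
      truth <- sample(c("lncRNA", "mRNA"), nrow(test), replace = TRUE)
      fp <- function(lbl) sum(lbl == "lncRNA" & truth == "mRNA")
      tp <- function(lbl) sum(lbl == "lncRNA" & truth == "lncRNA")
      expect_lte(fp(ens$label), min(fp(ca$label), fp(cb$label)))
      expect_lte(tp(ens$label), min(tp(ca$label), tp(cb$label)))
    }
  })
})

test_that("mismatched transcript sets are rejected", {
  pair <- train_pair(n = 30)
  cfg <- sim_config(seed = 5, n_mrna = 4, n_lnc = 4,
                    length_range = c(300L, 400L))
  t1 <- simulate_lncrna(cfg)$sequences
  fa <- extract_features(t1, "cpat", pair$a$hexamer_table)
  fb <- extract_features(t1[1:3, ], "lncfinder-lite", pair$b$hexamer_table)
  expect_error(ensemble_classify(fa, fb, pair$a, pair$b), "same transcripts")
})
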