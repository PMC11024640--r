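# Independent oracles used across the test suite. These deliberately use
# naive enumeration / direct arithmetic, not the package's code paths.

seq_tbl <- function(...) {
  s <- c(...)
  if (length(s) == 0L) {
    return(tibble::tibble(transcript_id = character(), sequence = character()))
  }
  if (is.null(names(s))) names(s) <- paste0("t", seq_along(s))
  tibble::tibble(transcript_id = names(s), sequence = unname(s))
}

random_seq_tbl <- function(n, len_range, p = c(0.25, 0.25, 0.25, 0.25)) {
  tibble::tibble(
    transcript_id = paste0("r", seq_len(n)),
    sequence = vapply(seq_len(n), function(i) {
      rng <- seq.int(len_range[1], len_range[2])
      L <- rng[sample.int(length(rng), 1L)]
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p),
            collapse = "")
    }, character(1)))
}

# exhaustive ORF enumeration: every ATG in every frame, scanned codon by codon
oracle_longest_orf <- function(seq, require_stop = TRUE) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  stops <- c("TAA", "TAG", "TGA")
  best <- c(start = 0L, len = 0L, frame = NA, complete = FALSE)
  for (frame in 0:2) {
    starts <- seq(frame + 1L, L - 2L, by = 3L)
    if (frame + 3L > L) next
    codons <- vapply(starts, function(p) paste(chars[p:(p + 2L)], collapse = ""),
                     character(1))
    for (ai in which(codons == "ATG")) {
      hit_len <- 0L
      complete <- FALSE
      for (ci in ai:length(codons)) {
        if (codons[[ci]] %in% stops) {
          hit_len <- (ci - ai + 1L) * 3L
          complete <- TRUE
          break
        }
      }
      if (!complete && !require_stop) {
        hit_len <- (length(codons) - ai + 1L) * 3L
      }
      if (hit_len > best[["len"]] ||
          (hit_len == best[["len"]] && hit_len > 0L &&
           starts[[ai]] < best[["start"]])) {
        best <- c(start = starts[[ai]], len = hit_len, frame = frame,
                  complete = complete)
      }
    }
  }
  best
}

# the five evaluation formulas, written straight from their definitions
oracle_metrics <- function(tp, tn, fp, fn) {
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (fp + tn > 0) tn / (fp + tn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  c(sensitivity = sens, specificity = spec,
    accuracy = (tp + tn) / (tp + tn + fp + fn), precision = prec, f1 = f1)
}

# O(n^2) Mann-Whitney AUC estimator: P(pos > neg) + 0.5 P(tie)
oracle_auc_pairwise <- function(scores, truth) {
  pos <- scores[truth == "lncRNA"]
  neg <- scores[truth == "mRNA"]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# brute-force total overlap (bp) between one interval set and the union of
# another, by per-base membership
oracle_overlap_bp <- function(exons, tes) {
  if (nrow(tes) == 0L || nrow(exons) == 0L) return(0L)
  te_bases <- unique(unlist(mapply(seq, tes$start, tes$end, SIMPLIFY = FALSE)))
  ex_bases <- unique(unlist(mapply(seq, exons$start, exons$end, SIMPLIFY = FALSE)))
  length(intersect(te_bases, ex_bases))
}

# planted duplicate groups: representatives plus lightly mutated copies
planted_duplicates <- function(n_groups = 8, copies = 2, len = 200,
                               mut_rate = 0.05, seed = 61) {
  withr::with_seed(seed, {
    rows <- list()
    for (g in seq_len(n_groups)) {
      base <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                    collapse = "")
      rows[[length(rows) + 1]] <- tibble::tibble(
        transcript_id = sprintf("g%02d_rep", g), sequence = base)
      for (cp in seq_len(copies)) {
        chars <- strsplit(base, "", fixed = TRUE)[[1]]
        idx <- sample(len, ceiling(len * mut_rate))
        chars[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE)
        rows[[length(rows) + 1]] <- tibble::tibble(
          transcript_id = sprintf("g%02d_cp%d", g, cp),
          sequence = paste(chars, collapse = ""))
      }
    }
    dplyr::bind_rows(rows)
  })
}

# all-pairs greedy clustering from a precomputed identity matrix, replicating
# the published greedy rule independently of the package's incremental code
oracle_dedup_reps <- function(seqs, identity) {
  ord <- order(-nchar(seqs$sequence), seqs$transcript_id)
  s <- seqs[ord, , drop = FALSE]
  n <- nrow(s)
  idm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        idm[i, j] <- idm[j, i] <-
          plantlnc:::pairwise_identity(s$sequence[[i]], s$sequence[[j]])
      }
    }
  }
  reps <- integer(0)
  for (i in seq_len(n)) {
    hit <- reps[idm[i, reps] > identity]
    if (length(hit) == 0L) reps <- c(reps, i)
  }
  sort(s$transcript_id[reps])
}
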