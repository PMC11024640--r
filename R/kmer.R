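#' Weighted k-mer frequency profile
#'
#' For each `k` in `[k_min, k_max]` and each of the `4^k` k-mers, the value is
#' the sliding-window frequency (count / number of counted windows) scaled by
#' `w_k = 1 / 4^(k_max - k)`, so longer k-mers carry full weight and shorter
#' ones are down-weighted. Windows containing `N` are excluded from both the
#' counts and the denominator. The defaults `k_min = 1`, `k_max = 5` give the
#' 1364-dimensional profile used by the k-mer SVM schema.
#'
#' @param seqs Tibble with columns `transcript_id`, `sequence`; every sequence
#'   must be at least `k_max` residues long.
#' @param k_min,k_max k-mer size range, `1 <= k_min <= k_max <= 6`.
#' @return Tibble: `transcript_id` plus one `kmer_<word>` column per k-mer,
#'   ordered by increasing k and alphabetically within k.
#' @export
kmer_profile <- function(seqs, k_min = 1L, k_max = 5L) {
  validate_sequences(seqs)
  stopifnot(k_min >= 1L, k_min <= k_max, k_max <= 6L)
  if (any(nchar(seqs$sequence) < k_max)) {
    stop("all sequences must be at least k_max residues long", call. = FALSE)
  }
  x <- as_dna(seqs)
  blocks <- lapply(seq(k_min, k_max), function(k) {
    m <- Biostrings::oligonucleotideFrequency(x, width = k, step = 1L)
    denom <- rowSums(m)
    w <- 1 / 4^(k_max - k)
    out <- m / ifelse(denom == 0, 1, denom) * w
    colnames(out) <- paste0("kmer_", colnames(m))
    out
  })
  dplyr::bind_cols(tibble(transcript_id = seqs$transcript_id),
                   as_tibble(do.call(cbind, blocks)))
}
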