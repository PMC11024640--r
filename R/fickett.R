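# Classic TESTCODE lookup tables (Fickett 1982), as redistributed with CPAT.
# Rows indexed by decreasing value bins; lookup takes the first bin whose
# threshold the observed value meets.
FICKETT <- local({
  pos_breaks <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
  cont_breaks <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0)
  pos_prob <- rbind(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
  cont_prob <- rbind(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.58, 0.44, 0.51, 0.69),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.20),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
  pos_weight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  cont_weight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  list(pos_breaks = pos_breaks, cont_breaks = cont_breaks,
       pos_prob = pos_prob, cont_prob = cont_prob,
       pos_weight = pos_weight, cont_weight = cont_weight)
})

#' Fickett TESTCODE score
#'
#' The classic coding-potential statistic combining position-dependent base
#' asymmetry and base composition. For each base the position value is the
#' maximum of its counts over the three codon positions divided by the
#' minimum plus one, and the content value is its overall fraction; both are
#' mapped through the published lookup tables to coding probabilities and
#' combined with the published weights. `N` residues are removed before
#' computing either statistic.
#'
#' @param seqs Tibble with columns `transcript_id`, `sequence`; each sequence
#'   must retain at least 3 non-`N` residues.
#' @return Tibble with columns `transcript_id`, `fickett_score`.
#' @export
fickett_score <- function(seqs) {
  validate_sequences(seqs)
  tibble(transcript_id = seqs$transcript_id,
         fickett_score = vapply(seqs$sequence, fickett_one, numeric(1),
                                USE.NAMES = FALSE))
}

fickett_one <- function(seq) {
  seq <- gsub("N", "", seq, fixed = TRUE)
  if (nchar(seq) < 3L) {
    stop("Fickett score needs >= 3 non-N residues", call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  phase <- (seq_along(chars) - 1L) %% 3L
  score <- 0
  for (b in bases) {
    hits <- chars == b
    cnt <- c(sum(hits & phase == 0L), sum(hits & phase == 1L),
             sum(hits & phase == 2L))
    pos_val <- max(cnt) / (min(cnt) + 1)
    cont_val <- sum(hits) / length(chars)
    pos_p <- FICKETT$pos_prob[b, which(pos_val >= FICKETT$pos_breaks)[1]]
    cont_p <- FICKETT$cont_prob[b, which(cont_val >= FICKETT$cont_breaks)[1]]
    score <- score + pos_p * FICKETT$pos_weight[[b]] +
      cont_p * FICKETT$cont_weight[[b]]
  }
  score
}
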