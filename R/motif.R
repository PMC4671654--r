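# PRDM9 recombination-hotspot motif scanning.
#
# The degenerate 13-mer consensus 5'-CCNCCNTNNCCNC-3' has 8 informative
# (non-N) positions.  With a uniform background, thresholding a consensus
# PWM at a fraction of its maximum score reduces to counting informative
# matches, so the per-site score is (matched informative positions) / 8 and
# the default threshold 0.85 admits at most one informative mismatch.

.PRDM9_FWD <- "CCNCCNTNNCCNC"
.PRDM9_REV <- "GNGGNNANGGNGG"  # reverse complement of the consensus

.motif_informative <- function(pattern) {
  ch <- strsplit(pattern, "")[[1]]
  idx <- which(ch != "N")
  list(offsets = idx - 1L, chars = ch[idx], width = length(ch))
}

.scan_one_strand <- function(chars, pattern) {
  info <- .motif_informative(pattern)
  L <- length(chars)
  n <- L - info$width + 1L
  if (n < 1L) return(data.frame(position = integer(0), score = numeric(0)))
  score <- integer(n)
  for (i in seq_along(info$offsets)) {
    off <- info$offsets[i]
    score <- score + (chars[(1L + off):(n + off)] == info$chars[i])
  }
  data.frame(position = seq_len(n) - 1L, score = score / length(info$offsets))
}

#' Scan a sequence for PRDM9 hotspot motif matches
#'
#' Scores every position on both strands against the degenerate 13-mer
#' consensus; a hit requires a score fraction strictly above `threshold`
#' (0.85 admits at most one informative mismatch out of 8). Overlapping
#' hits on opposite strands are counted separately.
#'
#' @param seq Character sequence (length >= 13).
#' @param threshold Score fraction threshold (default 0.85).
#' @return `data.frame` of `MotifHit`s: `position` (0-based start of the
#'   13-mer on the forward strand), `strand`, `score_fraction`.
#' @export
scan_prdm9 <- function(seq, threshold = 0.85) {
  if (nchar(seq) < 13L) stop("sequence shorter than the 13-mer motif")
  chars <- strsplit(toupper(seq), "")[[1]]
  fwd <- .scan_one_strand(chars, .PRDM9_FWD)
  rev <- .scan_one_strand(chars, .PRDM9_REV)
  hits <- rbind(
    if (nrow(fwd)) data.frame(position = fwd$position, strand = "+",
                              score_fraction = fwd$score),
    if (nrow(rev)) data.frame(position = rev$position, strand = "-",
                              score_fraction = rev$score)
  )
  hits <- hits[hits$score_fraction > threshold, , drop = FALSE]
  hits <- hits[order(hits$position, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
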