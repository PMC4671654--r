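# Detection of paralogous LCR blocks by k-mer self-alignment.
#
# Exact k-mer anchors between the sequence and itself (both orientations,
# trivial diagonal excluded) are chained collinearly and merged into blocks.
# Because paralog copies diverge by substitutions at a fraction of a
# percent, most k-mers survive intact and anchors lie on near-constant
# (anti)diagonals, so chaining within a small band with a maximum gap
# recovers the full duplication blocks.

#' Detect paralogous blocks by self-alignment
#'
#' @param seq Character sequence (length >= `2 * min_block`).
#' @param k Anchor k-mer length (default 31).
#' @param min_block Minimum block length in bp (default 10,000).
#' @param min_identity Minimum block identity (default 0.9).
#' @param max_gap Maximum anchor gap within a chain in bp (default 2,000).
#' @param band Diagonal band width in bp for chaining (default 50).
#' @param max_occ K-mers occurring more often than this are dropped as
#'   repeats (default 10).
#' @return List with `pairs` (`data.frame`: `a_start`, `a_end`, `b_start`,
#'   `b_end`, `orientation`, `identity`, `n_anchors`; 0-based half-open,
#'   `a` before `b`) and `blocks` (`data.frame`: distinct block intervals
#'   with a `family` id grouping blocks linked by paralogy, and
#'   `family_size`). Both empty when nothing is found.
#' @export
detect_paralogs <- function(seq, k = 31L, min_block = 10000L,
                            min_identity = 0.9, max_gap = 2000L,
                            band = 50L, max_occ = 10L) {
  L <- nchar(seq)
  if (L < 2 * min_block) stop("sequence shorter than 2 * min_block")
  seq <- toupper(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))

  pos <- seq_len(L - k + 1L)
  fwd <- data.table::data.table(kmer = substring(seq, pos, pos + k - 1L),
                                pos = pos)
  rck <- data.table::data.table(kmer = substring(rc, pos, pos + k - 1L),
                                # forward-strand start of the k-mer matched
                                # by position i of the reverse complement
                                pos = L - pos - k + 2L)

  # forward-forward anchors (same orientation)
  cnt <- fwd[, .N, by = "kmer"]
  dup <- cnt[cnt$N >= 2L & cnt$N <= max_occ, ]
  ff <- fwd[fwd$kmer %in% dup$kmer, ]
  ff_pairs <- merge(ff, ff, by = "kmer", allow.cartesian = TRUE)
  ff_pairs <- ff_pairs[ff_pairs$pos.x < ff_pairs$pos.y, ]
  ff_pairs <- data.table::data.table(a = ff_pairs$pos.x, b = ff_pairs$pos.y,
                                     diag = ff_pairs$pos.y - ff_pairs$pos.x)
  ff_pairs <- ff_pairs[ff_pairs$diag >= k, ]

  # forward-reverse anchors (opposite orientation)
  cnt_f <- fwd[, .N, by = "kmer"]
  cnt_r <- rck[, .N, by = "kmer"]
  shared <- merge(cnt_f, cnt_r, by = "kmer")
  shared <- shared[shared$N.x <= max_occ & shared$N.y <= max_occ, ]
  fr <- merge(fwd[fwd$kmer %in% shared$kmer, ],
              rck[rck$kmer %in% shared$kmer, ],
              by = "kmer", allow.cartesian = TRUE)
  fr_pairs <- data.table::data.table(a = pmin(fr$pos.x, fr$pos.y),
                                     b = pmax(fr$pos.x, fr$pos.y))
  fr_pairs <- fr_pairs[fr_pairs$b - fr_pairs$a >= k, ]
  fr_pairs <- unique(fr_pairs)
  fr_pairs$diag <- fr_pairs$a + fr_pairs$b  # anti-diagonal

  chain <- function(pairs, orientation) {
    if (nrow(pairs) == 0L) return(NULL)
    data.table::setorderv(pairs, c("diag", "a"))
    brk <- c(TRUE, diff(pairs$diag) > band | diff(pairs$a) > max_gap)
    pairs$chain <- cumsum(brk)
    agg <- pairs[, list(a_start = min(a) - 1L, a_end = max(a) + k - 1L,
                        b_start = min(b) - 1L, b_end = max(b) + k - 1L,
                        n_anchors = .N),
                 by = "chain"]
    agg$orientation <- orientation
    agg
  }
  a <- b <- diag <- NULL  # NSE placeholders for data.table
  chains <- rbind(chain(ff_pairs, "+"), chain(fr_pairs, "-"))
  if (is.null(chains) || nrow(chains) == 0L)
    return(list(pairs = .empty_pairs(), blocks = .empty_blocks()))
  chains <- chains[(chains$a_end - chains$a_start) >= min_block &
                     (chains$b_end - chains$b_start) >= min_block, ]
  if (nrow(chains) == 0L)
    return(list(pairs = .empty_pairs(), blocks = .empty_blocks()))

  chains$identity <- vapply(seq_len(nrow(chains)), function(i)
    .block_identity(seq, rc, L, chains$a_start[i], chains$a_end[i],
                    chains$b_start[i], chains$b_end[i],
                    chains$orientation[i]),
    numeric(1))
  chains <- chains[chains$identity >= min_identity, ]
  if (nrow(chains) == 0L)
    return(list(pairs = .empty_pairs(), blocks = .empty_blocks()))

  pairs <- data.frame(a_start = chains$a_start, a_end = chains$a_end,
                      b_start = chains$b_start, b_end = chains$b_end,
                      orientation = chains$orientation,
                      identity = chains$identity,
                      n_anchors = chains$n_anchors,
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$a_start, pairs$b_start), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, blocks = .group_blocks(pairs))
}

.empty_pairs <- function() {
  data.frame(a_start = integer(0), a_end = integer(0), b_start = integer(0),
             b_end = integer(0), orientation = character(0),
             identity = numeric(0), n_anchors = integer(0))
}

.empty_blocks <- function() {
  data.frame(start = integer(0), end = integer(0), family = integer(0),
             family_size = integer(0))
}

# ungapped identity along the chain's (anti)diagonal; valid because paralog
# divergence is substitution-dominated at these scales
.block_identity <- function(seq, rc, L, a_start, a_end, b_start, b_end,
                            orientation) {
  n <- min(a_end - a_start, b_end - b_start)
  a_chars <- strsplit(substr(seq, a_start + 1L, a_start + n), "")[[1]]
  if (orientation == "+") {
    b_chars <- strsplit(substr(seq, b_start + 1L, b_start + n), "")[[1]]
  } else {
    # forward interval [b_end - n, b_end) read on the reverse strand
    rs <- L - b_end + 1L
    b_chars <- strsplit(substr(rc, rs, rs + n - 1L), "")[[1]]
  }
  mean(a_chars == b_chars)
}

# Group block intervals into families: blocks from different pairs that
# overlap reciprocally (>= 50%) are the same copy; copies linked by a
# paralog pair join one family.
.group_blocks <- function(pairs) {
  ivs <- rbind(
    data.frame(start = pairs$a_start, end = pairs$a_end, pair = seq_len(nrow(pairs))),
    data.frame(start = pairs$b_start, end = pairs$b_end, pair = seq_len(nrow(pairs)))
  )
  n <- nrow(ivs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  # merge interval records describing the same physical copy
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ov <- min(ivs$end[i], ivs$end[j]) - max(ivs$start[i], ivs$start[j])
    if (ov > 0 &&
        ov >= 0.5 * (ivs$end[i] - ivs$start[i]) &&
        ov >= 0.5 * (ivs$end[j] - ivs$start[j])) union_(i, j)
  }
  copy_id <- vapply(seq_len(n), find, integer(1))
  copy_start <- tapply(ivs$start, copy_id, min)
  copy_end <- tapply(ivs$end, copy_id, max)
  ids <- as.integer(names(copy_start))

  # families: link the two copies of each pair
  fparent <- seq_along(ids)
  ffind <- function(i) { while (fparent[i] != i) i <- fparent[i]; i }
  funion <- function(i, j) {
    ri <- ffind(i); rj <- ffind(j)
    if (ri != rj) fparent[rj] <<- ri
  }
  half <- nrow(pairs)
  for (pidx in seq_len(half)) {
    ca <- match(copy_id[pidx], ids)
    cb <- match(copy_id[pidx + half], ids)
    funion(ca, cb)
  }
  fam <- vapply(seq_along(ids), ffind, integer(1))
  fam <- match(fam, unique(fam))
  out <- data.frame(start = as.integer(copy_start),
                    end = as.integer(copy_end),
                    family = fam,
                    stringsAsFactors = FALSE)
  out$family_size <- as.integer(table(fam)[as.character(fam)])
  out <- out[order(out$family, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
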