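# Synthetic haplotype sequences with planted LCR architecture.
#
# One master sequence per LCR family is generated and written into every
# copy position (respecting orientation), then each copy is mutated
# independently at the paralog divergence rate.  The 45 kb master is embedded
# inside the 358 kb master at the offset the reference architecture implies,
# so the containments 45PROX in 358PROX and 45DIST in 358DIST arise
# automatically.  SwaI (ATTTAAAT) recognition sites are scrubbed from the
# assembled sequence and planted at configured positions, so in-silico
# digests are fully determined by the site layout.

.BASES <- c("A", "C", "G", "T")
.SWAI <- "ATTTAAAT"
.SWAI_CHARS <- strsplit(.SWAI, "")[[1]]

.rand_chars <- function(n) sample(.BASES, n, replace = TRUE)

# substitute bases at rate `delta`; substitutions go to one of the 3 others
.mutate_chars <- function(x, delta) {
  if (delta <= 0) return(x)
  idx <- which(stats::runif(length(x)) < delta)
  if (length(idx) == 0L) return(x)
  code <- match(x[idx], .BASES) - 1L
  x[idx] <- .BASES[((code + sample(1:3, length(idx), replace = TRUE)) %% 4L) + 1L]
  x
}

.revcomp_chars <- function(x) {
  rev(chartr("ACGT", "TGCA", x))
}

#' Default SwaI site layout for the synthetic reference
#'
#' Deterministic positions with irregular spacing (mean ~24 kb, jitter
#' +/- 8 kb from a fixed linear-congruential sequence), so that fragment
#' patterns change detectably under both deletions and inversions.
#'
#' @param arch A `LocusArchitecture`.
#' @return Sorted integer vector of site start positions (reference frame).
#' @export
default_swai_sites <- function(arch) {
  span <- arch$locus_end - arch$locus_start
  k <- seq_len(floor((span - 24000) / 24000))
  jitter <- (as.numeric(k) * 2654435761) %% 16001 - 8000
  pos <- arch$locus_start + 12000 + (k - 1L) * 24000 + jitter
  pos <- pos[pos > arch$locus_start + 1000 & pos < arch$locus_end - 1008]
  sort(as.integer(round(pos)))
}

# Assemble the reference (H1) character vector plus the stuffer sequence.
# Deterministic under p$seed.
.synth_reference_parts <- function(arch, p) {
  el <- arch$elements
  iv <- function(name) el[el$name == name, ]
  L <- arch$locus_end - arch$locus_start
  to_local <- function(x) x - arch$locus_start

  .with_seed(.stream_seed(p, "sequence"), {
    seq <- .rand_chars(L)

    p358 <- iv("358PROX"); d358 <- iv("358DIST")
    p45 <- iv("45PROX"); m45i <- iv("45MID"); d45 <- iv("45DIST")

    m45 <- .rand_chars(m45i$end - m45i$start)
    m358 <- .rand_chars(max(p358$end - p358$start, d358$end - d358$start))
    # embed the 45 master at the offset 45PROX occupies inside 358PROX
    off45 <- p45$start - p358$start
    m358[(off45 + 1):(off45 + length(m45))] <- m45

    write_copy <- function(seq, target, master, orientation) {
      n <- target$end - target$start
      copy <- .mutate_chars(master[seq_len(n)], p$paralog_divergence)
      if (orientation == -1L) copy <- .revcomp_chars(copy)
      seq[(to_local(target$start) + 1):(to_local(target$end))] <- copy
      seq
    }
    seq <- write_copy(seq, p358, m358, p358$orientation)
    seq <- write_copy(seq, d358, m358, d358$orientation)
    seq <- write_copy(seq, m45i, m45, m45i$orientation)

    stuffer <- .rand_chars(arch$stuffer_length)

    # scrub recognition sites everywhere (reference and stuffer), then plant
    seq <- .scrub_swai(seq)
    stuffer <- .scrub_swai(stuffer)
    sites <- if (is.null(p$swai_sites)) default_swai_sites(arch) else
      sort(as.integer(p$swai_sites))
    for (s in to_local(sites)) seq[(s + 1):(s + 8)] <- .SWAI_CHARS

    for (m in p$motif_positions) {
      mm <- to_local(m)
      seq[(mm + 1):(mm + 13)] <- strsplit("CCACCATAACCAC", "")[[1]]
    }

    list(seq = seq, stuffer = stuffer, sites = sites)
  })
}

# disrupt every SwaI occurrence (on either strand it is palindromic) by
# flipping its 4th base T -> G
.scrub_swai <- function(x) {
  s <- paste(x, collapse = "")
  repeat {
    hits <- gregexpr(.SWAI, s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) break
    for (h in hits) x[h + 3L] <- "G"
    s <- paste(x, collapse = "")
  }
  x
}

#' Synthesize the sequence of an SV haplotype
#'
#' Builds the seeded synthetic reference for the locus architecture and
#' renders the haplotype by walking its segment map: reference segments are
#' copied (reverse-complemented on minus strand) and stuffer segments insert
#' the 5936Ins sequence. The same `SimParams` always yields the same
#' reference, so sequences of different haplotypes are mutually consistent.
#'
#' @param arch A `LocusArchitecture`.
#' @param hap A `Haplotype` (defaults to H1, the reference itself).
#' @param p A [sim_params()] object.
#' @return A single character string of A/C/G/T.
#' @export
synth_haplotype_sequence <- function(arch, hap = make_haplotype("H1", arch),
                                     p = sim_params()) {
  stopifnot(inherits(arch, "LocusArchitecture"), inherits(hap, "Haplotype"))
  parts <- .synth_reference_parts(arch, p)
  segs <- hap$segments
  out <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    if (s$type == "stuffer") {
      out[[i]] <- parts$stuffer
    } else {
      lo <- s$ref_start - arch$locus_start
      hi <- s$ref_end - arch$locus_start
      piece <- parts$seq[(lo + 1):hi]
      if (s$strand == -1L) piece <- .revcomp_chars(piece)
      out[[i]] <- piece
    }
  }
  paste(unlist(out), collapse = "")
}
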