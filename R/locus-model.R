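# Coordinate-level model of the NPHP1 locus and its SV haplotypes.
#
# All coordinates are 0-based half-open (UCSC table convention: printed start
# is 0-based, printed end is 1-based), so length = end - start.

#' Default coordinate table for the NPHP1 locus
#'
#' Returns the reference (H1) coordinates of the five low-copy-repeat (LCR)
#' copies and the \emph{NPHP1} gene on hg19 chr2. The three ~45 kb copies
#' (45PROX, 45MID, 45DIST) and the two ~358 kb copies (358PROX, 358DIST) are
#' named by position relative to the gene; 45PROX is embedded in 358PROX and
#' 45DIST in 358DIST. Orientation is the sign of each copy relative to its
#' family consensus.
#'
#' @return A `data.frame` with columns `name`, `family`, `chrom`, `start`,
#'   `end`, `orientation` (+1/-1).
#' @export
nphp1_coordinates <- function() {
  data.frame(
    name        = c("358PROX", "45PROX", "NPHP1", "45MID", "358DIST", "45DIST"),
    family      = c("358K", "45K", "gene", "45K", "358K", "45K"),
    chrom       = "chr2",
    start       = c(110494431L, 110688765L, 110880913L, 110983704L,
                    111033787L, 111153516L),
    end         = c(110852754L, 110733137L, 110962639L, 111031088L,
                    111392192L, 111197896L),
    orientation = c(1L, 1L, 1L, 1L, -1L, -1L),
    stringsAsFactors = FALSE
  )
}

#' Build the reference (H1) locus architecture
#'
#' Validates a coordinate table and assembles the architecture of the
#' reference haplotype: element order, family membership, the containment of
#' the 45 kb copies within the 358 kb copies, and the stuffer (5936Ins)
#' length used by deletion alleles.
#'
#' @param config Coordinate table as from [nphp1_coordinates()].
#' @param locus_start,locus_end Bounds of the modelled locus (0-based
#'   half-open). Defaults cover ~1.68 Mb around the gene.
#' @param stuffer_length Length in bp of the insertion found at 45 kb LCR
#'   deletion junctions (default 5936).
#' @return An object of class `LocusArchitecture`.
#' @export
build_reference_architecture <- function(config = nphp1_coordinates(),
                                         locus_start = 110080914L,
                                         locus_end = 111762639L,
                                         stuffer_length = 5936L) {
  required <- c("name", "family", "chrom", "start", "end", "orientation")
  if (!all(required %in% names(config)))
    stop("coordinate table must have columns: ", paste(required, collapse = ", "))
  if (any(config$start < 0) || any(config$start >= config$end))
    stop("invalid interval: need 0 <= start < end")
  if (length(unique(config$chrom)) != 1L)
    stop("all elements must lie on one chromosome")

  elements <- config[order(config$start), , drop = FALSE]
  rownames(elements) <- NULL

  contains <- function(outer, inner) {
    o <- elements[elements$name == outer, ]
    i <- elements[elements$name == inner, ]
    nrow(o) == 1L && nrow(i) == 1L && o$start <= i$start && i$end <= o$end
  }
  if (!contains("358PROX", "45PROX") || !contains("358DIST", "45DIST"))
    stop("containment violated: 45PROX must lie within 358PROX and 45DIST within 358DIST")

  gene <- elements[elements$family == "gene", ]
  if (nrow(gene) != 1L) stop("exactly one gene element required")
  p358 <- elements[elements$name == "358PROX", ]
  m45  <- elements[elements$name == "45MID", ]
  if (nrow(p358) == 1L && nrow(m45) == 1L &&
      !(gene$start >= p358$end && gene$end <= m45$start))
    stop("gene must lie between 358PROX end and 45MID start")

  fam45 <- elements[elements$family == "45K", ]
  if (nrow(fam45) > 1L) {
    len <- fam45$end - fam45$start
    if (max(len) / min(len) > 1.10)
      stop("45K family copy lengths differ by more than 10%")
  }

  if (locus_start > min(elements$start) || locus_end < max(elements$end))
    stop("locus bounds must contain every element")

  structure(
    list(
      chrom = elements$chrom[1L],
      locus_start = as.integer(locus_start),
      locus_end = as.integer(locus_end),
      elements = elements,
      gene = gene,
      stuffer_length = as.integer(stuffer_length)
    ),
    class = "LocusArchitecture"
  )
}

#' @export
print.LocusArchitecture <- function(x, ...) {
  cat(sprintf("LocusArchitecture: %s:%d-%d (%.2f Mb), stuffer %d bp\n",
              x$chrom, x$locus_start, x$locus_end,
              (x$locus_end - x$locus_start) / 1e6, x$stuffer_length))
  print(x$elements)
  invisible(x)
}

## ---- haplotypes -----------------------------------------------------------

# A haplotype is an ordered list of segments mapping haplotype coordinates to
# the reference frame.  Each segment is (ref_start, ref_end, strand, type):
# type "ref" segments copy reference sequence (revcomp when strand == -1);
# type "stuffer" segments insert the 5936Ins novel sequence (no reference
# footprint).  All structural transforms are segment-list rewrites, so
# sequence synthesis, ESP projection and in-silico digestion all share one
# coordinate mapping.

.hap_segment_df <- function(ref_start, ref_end, strand, type) {
  data.frame(ref_start = as.numeric(ref_start), ref_end = as.numeric(ref_end),
             strand = as.integer(strand), type = type,
             stringsAsFactors = FALSE)
}

.new_haplotype <- function(arch, segments, label = "custom",
                           lost_copies = character(), inversion = FALSE) {
  structure(
    list(arch = arch, segments = segments, label = label,
         lost_copies = sort(lost_copies), inversion = inversion),
    class = "Haplotype"
  )
}

#' Lookup table of the seven known SV haplotypes
#'
#' H1 is the reference; the others combine loss of 45PROX and/or 45DIST
#' (each replaced by the stuffer) with the NPHP1 inversion between the two
#' 358 kb LCRs.
#' @keywords internal
.haplotype_defs <- function() {
  list(
    H1 = list(lost = character(),             inv = FALSE),
    H2 = list(lost = "45PROX",                inv = TRUE),
    H3 = list(lost = character(),             inv = TRUE),
    H4 = list(lost = c("45PROX", "45DIST"),   inv = TRUE),
    H5 = list(lost = "45PROX",                inv = FALSE),
    H6 = list(lost = "45DIST",                inv = TRUE),
    H7 = list(lost = c("45PROX", "45DIST"),   inv = FALSE)
  )
}

#' Construct one of the known SV haplotypes
#'
#' @param label One of `"H1"`..`"H7"`.
#' @param arch A [build_reference_architecture()] object.
#' @return A `Haplotype`.
#' @examples
#' arch <- build_reference_architecture()
#' h2 <- make_haplotype("H2", arch)
#' count45(h2)  # 2
#' @export
make_haplotype <- function(label, arch = build_reference_architecture()) {
  defs <- .haplotype_defs()
  if (!label %in% names(defs)) stop("unknown haplotype label: ", label)
  def <- defs[[label]]
  hap <- .new_haplotype(
    arch,
    .hap_segment_df(arch$locus_start, arch$locus_end, 1L, "ref"),
    label = label
  )
  for (cp in def$lost) hap <- delete_45_with_stuffer(hap, cp)
  if (def$inv) hap <- apply_inversion(hap)
  hap$label <- label
  hap
}

#' Number of 45 kb LCR copies on a haplotype
#' @param hap A `Haplotype`.
#' @return Integer copy count (3 on the reference).
#' @export
count45 <- function(hap) {
  stopifnot(inherits(hap, "Haplotype"))
  3L - length(hap$lost_copies)
}

#' Total haplotype length in bp
#' @param hap A `Haplotype`.
#' @export
hap_length <- function(hap) {
  segs <- hap$segments
  sum(ifelse(segs$type == "stuffer", hap$arch$stuffer_length,
             segs$ref_end - segs$ref_start))
}

# haplotype-frame offsets of each segment
.seg_offsets <- function(hap) {
  segs <- hap$segments
  len <- ifelse(segs$type == "stuffer", hap$arch$stuffer_length,
                segs$ref_end - segs$ref_start)
  off <- cumsum(c(0, len))[seq_len(nrow(segs))]
  cbind(offset = off, length = len)
}

# Merge adjacent reference segments that are contiguous on the same strand,
# so structurally equivalent haplotypes share one canonical segment list.
.normalize_segments <- function(segs) {
  i <- 1L
  while (i < nrow(segs)) {
    a <- segs[i, ]; b <- segs[i + 1L, ]
    mergeable <- a$type == "ref" && b$type == "ref" && a$strand == b$strand &&
      ((a$strand == 1L && a$ref_end == b$ref_start) ||
         (a$strand == -1L && a$ref_start == b$ref_end))
    if (mergeable) {
      segs$ref_start[i] <- min(a$ref_start, b$ref_start)
      segs$ref_end[i] <- max(a$ref_end, b$ref_end)
      segs <- segs[-(i + 1L), , drop = FALSE]
    } else i <- i + 1L
  }
  rownames(segs) <- NULL
  segs
}

# Split any "ref" segment containing reference position p (strictly inside)
# into two, preserving haplotype order.
.split_at_ref <- function(hap, p) {
  segs <- hap$segments
  out <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    if (s$type == "ref" && p > s$ref_start && p < s$ref_end) {
      left  <- .hap_segment_df(s$ref_start, p, s$strand, "ref")
      right <- .hap_segment_df(p, s$ref_end, s$strand, "ref")
      out[[i]] <- if (s$strand == 1L) rbind(left, right) else rbind(right, left)
    } else {
      out[[i]] <- s
    }
  }
  hap$segments <- do.call(rbind, out)
  rownames(hap$segments) <- NULL
  hap
}

#' Apply the NPHP1 inversion to a haplotype
#'
#' Reverses the segment strictly between the inner boundaries of the two
#' 358 kb LCRs (358PROX end, 358DIST start): element order is reversed and
#' orientations are negated. Applying it twice restores the original.
#'
#' @param hap A `Haplotype`; both 358 kb copies must be present (they always
#'   are for H1-H7).
#' @return The inverted `Haplotype`.
#' @export
apply_inversion <- function(hap) {
  stopifnot(inherits(hap, "Haplotype"))
  arch <- hap$arch
  b1 <- arch$elements$end[arch$elements$name == "358PROX"]
  b2 <- arch$elements$start[arch$elements$name == "358DIST"]
  if (length(b1) != 1L || length(b2) != 1L)
    stop("unsupported transform: both 358K copies are required")
  hap <- .split_at_ref(hap, b1)
  hap <- .split_at_ref(hap, b2)
  segs <- hap$segments
  # middle = segments whose reference footprint lies within [b1, b2)
  mid <- which((segs$type == "stuffer" |
                  (segs$ref_start >= b1 & segs$ref_end <= b2)) &
                 .segment_between(segs, b1, b2))
  if (length(mid) == 0L) stop("no segment between the 358K copies")
  mid <- seq(min(mid), max(mid))
  inv <- segs[rev(mid), , drop = FALSE]
  inv$strand <- -inv$strand
  hap$segments <- .normalize_segments(
    rbind(segs[seq_len(min(mid) - 1L), , drop = FALSE],
          inv,
          segs[setdiff(seq_len(nrow(segs)), seq_len(max(mid))), ,
               drop = FALSE]))
  hap$inversion <- !hap$inversion
  hap$label <- "custom"
  hap
}

# helper: flag segments positioned between ref coords b1 and b2 in the
# haplotype ordering (stuffers inherit position from flanking ref segments)
.segment_between <- function(segs, b1, b2) {
  n <- nrow(segs)
  ok <- logical(n)
  for (i in seq_len(n)) {
    if (segs$type[i] == "ref") {
      ok[i] <- segs$ref_start[i] >= b1 && segs$ref_end[i] <= b2
    } else {
      # stuffer: between iff neighbours are
      lo <- if (i > 1L) segs$ref_start[i - 1L] >= b1 else TRUE
      hi <- if (i < n) segs$ref_end[i + 1L] <= b2 else TRUE
      ok[i] <- lo && hi
    }
  }
  ok
}

#' Delete a 45 kb LCR copy, inserting the stuffer at the junction
#'
#' Removes the full named copy and inserts a stuffer of
#' `arch$stuffer_length` bp at the junction, so the net length change is
#' `-(copy length - stuffer_length)` (about -38.4 kb with defaults).
#'
#' @param hap A `Haplotype`.
#' @param which `"45PROX"` or `"45DIST"`.
#' @return The modified `Haplotype`.
#' @export
delete_45_with_stuffer <- function(hap, which = c("45PROX", "45DIST")) {
  stopifnot(inherits(hap, "Haplotype"))
  which <- match.arg(which)
  if (which %in% hap$lost_copies) stop("copy already lost: ", which)
  el <- hap$arch$elements[hap$arch$elements$name == which, ]
  if (nrow(el) != 1L) stop("copy not in architecture: ", which)
  hap <- .split_at_ref(hap, el$start)
  hap <- .split_at_ref(hap, el$end)
  segs <- hap$segments
  inside <- segs$type == "ref" & segs$ref_start >= el$start & segs$ref_end <= el$end
  if (!any(inside)) stop("copy has no footprint on this haplotype: ", which)
  idx <- which(inside)
  if (!all(diff(idx) == 1L)) stop("copy footprint is not contiguous: ", which)
  stuffer <- .hap_segment_df(el$start, el$start, 1L, "stuffer")
  hap$segments <- .normalize_segments(
    rbind(segs[seq_len(min(idx) - 1L), , drop = FALSE],
          stuffer,
          segs[setdiff(seq_len(nrow(segs)), seq_len(max(idx))), ,
               drop = FALSE]))
  hap$lost_copies <- sort(c(hap$lost_copies, which))
  hap$label <- "custom"
  hap
}

#' Elements present on a haplotype, in haplotype coordinates
#'
#' Projects each architecture element through the haplotype's segment map.
#' Elements wholly removed (lost 45 kb copies) are dropped. Orientation is
#' the element's reference orientation times the strand of the segment
#' carrying it, so inverted elements flip sign.
#'
#' @param hap A `Haplotype`.
#' @return `data.frame` with `name`, `family`, `start`, `end` (haplotype
#'   frame, 0-based half-open), `orientation`, ordered by `start`.
#' @export
hap_elements <- function(hap) {
  stopifnot(inherits(hap, "Haplotype"))
  segs <- hap$segments
  offs <- .seg_offsets(hap)
  el <- hap$arch$elements
  rows <- vector("list", nrow(el))
  for (j in seq_len(nrow(el))) {
    e <- el[j, ]
    if (e$name %in% hap$lost_copies) next
    starts <- c(); ends <- c(); ori <- NA_integer_
    for (i in seq_len(nrow(segs))) {
      s <- segs[i, ]
      if (s$type != "ref") next
      ov_s <- max(e$start, s$ref_start); ov_e <- min(e$end, s$ref_end)
      if (ov_s >= ov_e) next
      if (s$strand == 1L) {
        h_s <- offs[i, "offset"] + (ov_s - s$ref_start)
        h_e <- offs[i, "offset"] + (ov_e - s$ref_start)
      } else {
        h_s <- offs[i, "offset"] + (s$ref_end - ov_e)
        h_e <- offs[i, "offset"] + (s$ref_end - ov_s)
      }
      starts <- c(starts, h_s); ends <- c(ends, h_e)
      # orientation from the segment carrying the larger share
      if (is.na(ori) || (ov_e - ov_s) > attr(ori, "w")) {
        ori <- structure(e$orientation * s$strand, w = ov_e - ov_s)
      }
    }
    if (length(starts) == 0L) next
    rows[[j]] <- data.frame(name = e$name, family = e$family,
                            start = min(starts), end = max(ends),
                            orientation = as.integer(ori),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Project a reference interval or position into haplotype coordinates
#' @keywords internal
.project_ref_to_hap <- function(hap, pos) {
  segs <- hap$segments
  offs <- .seg_offsets(hap)
  out <- rep(NA_real_, length(pos))
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    if (s$type != "ref") next
    hit <- which(is.na(out) & pos >= s$ref_start & pos < s$ref_end)
    if (length(hit) == 0L) next
    out[hit] <- if (s$strand == 1L) offs[i, "offset"] + (pos[hit] - s$ref_start)
    else offs[i, "offset"] + (s$ref_end - 1 - pos[hit])
  }
  out
}

# Map a haplotype-frame position to (ref position, strand); stuffer positions
# return NA ref position.
.project_hap_to_ref <- function(hap, pos) {
  segs <- hap$segments
  offs <- .seg_offsets(hap)
  ref <- rep(NA_real_, length(pos))
  strand <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(segs))) {
    lo <- offs[i, "offset"]; hi <- lo + offs[i, "length"]
    hit <- which(pos >= lo & pos < hi)
    if (length(hit) == 0L) next
    if (segs$type[i] == "ref") {
      ref[hit] <- if (segs$strand[i] == 1L) segs$ref_start[i] + (pos[hit] - lo)
      else segs$ref_end[i] - 1 - (pos[hit] - lo)
      strand[hit] <- segs$strand[i]
    }
  }
  list(ref = ref, strand = strand)
}

#' @export
print.Haplotype <- function(x, ...) {
  cat(sprintf("Haplotype %s: count45 = %d, inversion = %s, length = %d bp\n",
              x$label, count45(x), x$inversion, hap_length(x)))
  if (length(x$lost_copies))
    cat("  lost:", paste(x$lost_copies, collapse = ", "), "\n")
  print(hap_elements(x))
  invisible(x)
}

## ---- NAHR susceptibility --------------------------------------------------

#' Classify a haplotype's susceptibility to the NAHR deletion
#'
#' A haplotype is susceptible to the intra-chromosomal NAHR-mediated NPHP1
#' deletion when a pair of 45 kb LCR copies flanks the gene in direct
#' orientation: one copy proximal and one distal to the gene, with equal
#' orientation signs. On the reference, 45PROX and 45MID form such a pair.
#'
#' @param hap A `Haplotype`.
#' @return `"susceptible"` or `"protected"`.
#' @export
classify_nahr_susceptibility <- function(hap) {
  el <- hap_elements(hap)
  gene <- el[el$family == "gene", ]
  if (nrow(gene) != 1L) stop("haplotype lacks a gene element")
  f45 <- el[el$family == "45K", , drop = FALSE]
  if (nrow(f45) < 2L) return("protected")
  prox <- f45[f45$end <= gene$start, , drop = FALSE]
  dist <- f45[f45$start >= gene$end, , drop = FALSE]
  for (i in seq_len(nrow(prox)))
    for (j in seq_len(nrow(dist)))
      if (prox$orientation[i] == dist$orientation[j]) return("susceptible")
  "protected"
}

## ---- genotypes ------------------------------------------------------------

#' Construct a genotype (diploid pair, haploid, or mosaic mixture)
#'
#' @param haps List of `Haplotype` objects (or labels, resolved against
#'   `arch`).
#' @param fractions Mixture fractions summing to 1; default equal.
#' @param ploidy 1 or 2.
#' @param arch Architecture used to resolve label inputs.
#' @return An object of class `Genotype`.
#' @export
make_genotype <- function(haps, fractions = NULL, ploidy = 2L,
                          arch = build_reference_architecture()) {
  if (is.character(haps)) haps <- lapply(haps, make_haplotype, arch = arch)
  stopifnot(all(vapply(haps, inherits, TRUE, "Haplotype")))
  if (is.null(fractions)) fractions <- rep(1 / length(haps), length(haps))
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (!ploidy %in% c(1L, 2L)) stop("ploidy must be 1 or 2")
  structure(list(components = haps, fractions = fractions,
                 ploidy = as.integer(ploidy)),
            class = "Genotype")
}

#' Fraction-weighted diploid 45 kb LCR copy count of a genotype
#' @param g A `Genotype`.
#' @return `ploidy * sum(fraction * count45)`; an integer for non-mosaic
#'   genotypes (4 for H2/H2).
#' @export
total45 <- function(g) {
  stopifnot(inherits(g, "Genotype"))
  g$ploidy * sum(g$fractions * vapply(g$components, count45, integer(1)))
}

#' Per-genotype NAHR protection report
#'
#' @param g A `Genotype`.
#' @return For diploid genotypes one of `"fully_susceptible"`,
#'   `"heterozygous_protective"`, `"fully_protected"`; for haploid input a
#'   named vector of per-haplotype classes.
#' @export
genotype_protection_report <- function(g) {
  stopifnot(inherits(g, "Genotype"))
  cls <- vapply(g$components, classify_nahr_susceptibility, character(1))
  if (g$ploidy == 1L || length(cls) != 2L) {
    names(cls) <- vapply(g$components, function(h) h$label, character(1))
    return(cls)
  }
  n_prot <- sum(cls == "protected")
  c("fully_susceptible", "heterozygous_protective",
    "fully_protected")[n_prot + 1L]
}

#' @export
print.Genotype <- function(x, ...) {
  labs <- vapply(x$components, function(h) h$label, character(1))
  cat(sprintf("Genotype (ploidy %d): %s; total45 = %.2g\n", x$ploidy,
              paste(sprintf("%s (%.2f)", labs, x$fractions), collapse = " / "),
              total45(x)))
  invisible(x)
}
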