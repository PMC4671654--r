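# Classification of fosmid end-sequence pairs (ESPs) and per-individual
# aggregation of SV evidence.

#' Classify fosmid end-sequence pairs
#'
#' Applies distance/orientation rules to each ESP mapped in the reference
#' frame: low mapping quality or unmapped ends are unusable; convergent
#' opposite-strand pairs spanning within `[insert_min, insert_max]` are
#' concordant; opposite-strand spans above `insert_max` indicate a deletion
#' on the donor (the clone jumped a segment missing from it relative to the
#' reference); spans below `insert_min` indicate an insertion; equal-strand
#' pairs indicate an inversion. The `side` locates the pair relative to the
#' gene: `proximal`, `distal`, or `spanning`.
#'
#' @param esps `data.frame` as from [simulate_fosmid_library()] (columns
#'   `clone_id`, `pos1`, `strand1`, `pos2`, `strand2`, `mapq`; an optional
#'   `chrom2` column marks ends on different chromosomes as unusable).
#' @param insert_min,insert_max Concordant span bounds in bp (defaults
#'   32,000 / 48,000, about the insert mean +/- 3 SD).
#' @param min_mapq Minimum mapping quality (default 20).
#' @param arch `LocusArchitecture` used to assign `side`.
#' @return `data.frame`: `clone_id`, `class`, `ref_span`, `side`.
#' @export
classify_esp <- function(esps, insert_min = 32000, insert_max = 48000,
                         min_mapq = 20,
                         arch = build_reference_architecture()) {
  stopifnot(all(c("clone_id", "pos1", "strand1", "pos2", "strand2", "mapq")
                %in% names(esps)))
  n <- nrow(esps)
  lo <- pmin(esps$pos1, esps$pos2)
  hi <- pmax(esps$pos1, esps$pos2)
  span <- hi - lo + 1
  left_strand <- ifelse(esps$pos1 <= esps$pos2, esps$strand1, esps$strand2)
  right_strand <- ifelse(esps$pos1 <= esps$pos2, esps$strand2, esps$strand1)

  unusable <- esps$mapq < min_mapq |
    esps$strand1 == "*" | esps$strand2 == "*" |
    is.na(esps$pos1) | is.na(esps$pos2)
  if (all(c("chrom", "chrom2") %in% names(esps)))
    unusable <- unusable | esps$chrom != esps$chrom2

  opposite <- esps$strand1 != esps$strand2
  convergent <- opposite & left_strand == "+" & right_strand == "-"

  cls <- rep("unusable", n)
  ok <- !unusable
  cls[ok & !opposite] <- "inversion"
  cls[ok & opposite & span > insert_max] <- "deletion"
  cls[ok & opposite & span < insert_min] <- "insertion"
  cls[ok & convergent & span >= insert_min & span <= insert_max] <- "concordant"
  # opposite-strand, in-range but divergent (everted) pairs stay unusable

  gene <- arch$gene
  mid <- (lo + hi) / 2
  side <- ifelse(cls %in% c("concordant", "unusable"), NA_character_,
                 ifelse(lo <= gene$start & hi >= gene$end, "spanning",
                        ifelse(mid < gene$start, "proximal", "distal")))
  data.frame(clone_id = esps$clone_id, class = cls, ref_span = span,
             side = side, stringsAsFactors = FALSE)
}

#' Aggregate ESP calls into per-individual SV evidence
#'
#' @param calls `data.frame` from [classify_esp()] for one individual.
#' @param min_support Minimum number of agreeing clones to assert evidence
#'   (default 1).
#' @return List with `counts` (per class), `deletion` (logical, plus
#'   `deletion_sides`), `inversion` (logical), and `n_usable`.
#' @export
aggregate_individual <- function(calls, min_support = 1L) {
  if (is.null(calls) || nrow(calls) == 0L) {
    return(list(counts = integer(0), deletion = FALSE,
                deletion_sides = character(0), inversion = FALSE,
                n_usable = 0L))
  }
  counts <- table(factor(calls$class,
                         levels = c("concordant", "deletion", "insertion",
                                    "inversion", "unusable")))
  del <- calls[calls$class == "deletion", , drop = FALSE]
  list(counts = c(unclass(counts)),
       deletion = sum(calls$class == "deletion") >= min_support,
       deletion_sides = sort(unique(del$side[!is.na(del$side)])),
       inversion = sum(calls$class == "inversion") >= min_support,
       n_usable = sum(calls$class != "unusable"))
}
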