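# Dosage summaries and copy-number estimation from aCGH log2 ratios and
# read-depth windows.

#' Construct a RegionDosage
#'
#' Ordered per-probe (or per-window) measurements over an interval, either
#' log2 ratios or copy values.
#'
#' @param table `data.frame` with at least `start`, `end`, `value` (probes
#'   ordered by position; `probe_id` and `target` columns are kept when
#'   present).
#' @param kind `"log2ratio"` or `"copynumber"`.
#' @param chrom Chromosome label.
#' @return An object of class `RegionDosage`.
#' @export
region_dosage <- function(table, kind = c("log2ratio", "copynumber"),
                          chrom = "chr2") {
  kind <- match.arg(kind)
  stopifnot(all(c("start", "end", "value") %in% names(table)),
            nrow(table) >= 1)
  table <- table[order(table$start), , drop = FALSE]
  rownames(table) <- NULL
  structure(list(chrom = chrom, start = min(table$start),
                 end = max(table$end), table = table, kind = kind),
            class = "RegionDosage")
}

#' @export
print.RegionDosage <- function(x, ...) {
  cat(sprintf("RegionDosage (%s): %s:%d-%d, %d values\n", x$kind, x$chrom,
              x$start, x$end, nrow(x$table)))
  invisible(x)
}

#' Values of a RegionDosage, optionally restricted to a probe target class
#' @param d A `RegionDosage`.
#' @param target Optional target class (e.g. `"45K"`) to filter on.
#' @return Numeric vector in positional order.
#' @export
dosage_values <- function(d, target = NULL) {
  stopifnot(inherits(d, "RegionDosage"))
  tab <- d$table
  if (!is.null(target)) {
    if (!"target" %in% names(tab)) stop("dosage table has no target column")
    tab <- tab[tab$target %in% target, , drop = FALSE]
  }
  tab$value
}

#' Summarize a dosage region: mean log ratio and DLRS
#'
#' DLRS (derivative log ratio spread) is the sample standard deviation of
#' the differences between adjacent values, divided by sqrt(2) - a spread
#' measure insensitive to real copy-number steps affecting long stretches.
#'
#' @param d A `RegionDosage` or bare numeric vector in positional order.
#' @return List with `mean_lr` and `dlrs` (`NA` with fewer than 2 values).
#' @export
summarize_region <- function(d) {
  v <- if (inherits(d, "RegionDosage")) d$table$value else as.numeric(d)
  if (length(v) < 1L) stop("empty region")
  dlrs <- if (length(v) >= 2L) stats::sd(diff(v)) / sqrt(2) else NA_real_
  list(mean_lr = mean(v), dlrs = dlrs)
}

#' Theoretical log2 ratio for a copy-number pair
#'
#' @param cn_test,cn_ref Non-negative test and reference copy numbers
#'   (`cn_ref > 0`).
#' @return `log2(cn_test / cn_ref)`; `-Inf` when `cn_test` is 0.
#' @export
theoretical_lr <- function(cn_test, cn_ref) {
  if (any(cn_test < 0) || any(cn_ref <= 0))
    stop("copy numbers must be non-negative with cn_ref > 0")
  log2(cn_test / cn_ref)
}

#' Intra-species integer copy number from a mean log2 ratio
#'
#' Assigns the integer copy number whose theoretical log2 ratio against the
#' reference copy number is nearest the observed mean (ties broken toward
#' the smaller copy number). A mean below `log2(0.5 / cn_ref)` - less than
#' half a copy's expected signal - is called copy number 0.
#'
#' @param mean_lr Observed mean log2 ratio (finite).
#' @param cn_ref Reference copy number (default 4, the modal diploid 45 kb
#'   LCR count).
#' @param cn_max Largest copy number considered (default `2 * cn_ref`).
#' @param dlrs Optional DLRS carried through to the call record.
#' @return A `CNCall`: list with `cn`, `mean_lr`, `dlrs`, `rule`.
#' @export
estimate_cn_intra <- function(mean_lr, cn_ref = 4L, cn_max = 2L * cn_ref,
                              dlrs = NA_real_) {
  stopifnot(is.finite(mean_lr))
  if (mean_lr < log2(0.5 / cn_ref)) {
    cn <- 0L
  } else {
    cand <- seq_len(cn_max)
    dist <- abs(mean_lr - log2(cand / cn_ref))
    cn <- cand[which.min(dist)]  # which.min takes the first = smaller c on ties
  }
  structure(list(cn = as.integer(cn), mean_lr = mean_lr, dlrs = dlrs,
                 rule = "intra"), class = "CNCall")
}

#' Inter-species three-way copy-number class from a mean log2 ratio
#'
#' Cross-species hybridization is attenuated by sequence divergence, so
#' integer rounding is not meaningful; instead three classes are called:
#' absent (`mean_lr <= t_absent`, copy number 0), reduced
#' (`t_absent < mean_lr <= t_equal`, half the reference copy number), and
#' equal (`mean_lr > t_equal`, the reference copy number).
#'
#' @param mean_lr Observed mean log2 ratio (finite).
#' @param cn_ref Reference copy number (default 4).
#' @param t_absent Absence threshold (default -1.0).
#' @param t_equal Reduced/equal boundary (default -0.25).
#' @param dlrs Optional DLRS carried through.
#' @return A `CNCall` with `rule = "interspecies"`.
#' @export
classify_cn_interspecies <- function(mean_lr, cn_ref = 4L, t_absent = -1.0,
                                     t_equal = -0.25, dlrs = NA_real_) {
  stopifnot(is.finite(mean_lr))
  cn <- if (mean_lr <= t_absent) 0L
  else if (mean_lr <= t_equal) as.integer(cn_ref / 2)
  else as.integer(cn_ref)
  structure(list(cn = cn, mean_lr = mean_lr, dlrs = dlrs,
                 rule = "interspecies"), class = "CNCall")
}

#' @export
print.CNCall <- function(x, ...) {
  cat(sprintf("CNCall (%s): cn = %d (mean LR %.2f, DLRS %s)\n", x$rule, x$cn,
              x$mean_lr, ifelse(is.na(x$dlrs), "NA", sprintf("%.2f", x$dlrs))))
  invisible(x)
}

#' Tabulate genomic content classes from probe log2 ratios
#'
#' Classifies each probe as absent (`value <= -1`), reduced
#' (`-1 < value <= 0`) or comparable (`value > 0`), sums contiguous probe
#' intervals per class, and reports kb and fractions of the region length.
#'
#' @param d A `RegionDosage` of kind `"log2ratio"`.
#' @param region_length Total region length in bp (defaults to the dosage
#'   extent).
#' @return `data.frame`: `class`, `kb`, `fraction`.
#' @export
tabulate_content_classes <- function(d, region_length = NULL) {
  stopifnot(inherits(d, "RegionDosage"))
  if (d$kind != "log2ratio") stop("content classes need log2ratio input")
  tab <- d$table
  if (nrow(tab) == 0L) stop("empty region")
  if (is.null(region_length)) region_length <- d$end - d$start
  cls <- ifelse(tab$value <= -1, "absent",
                ifelse(tab$value <= 0, "reduced", "comparable"))
  # extend each probe interval to the midpoint with its neighbours so the
  # classified segments tile the region
  n <- nrow(tab)
  mids <- if (n > 1) (tab$end[-n] + tab$start[-1]) / 2 else numeric(0)
  seg_start <- c(tab$start[1], mids)
  seg_end <- c(mids, tab$end[n])
  bp <- tapply(seg_end - seg_start, factor(cls,
               levels = c("absent", "reduced", "comparable")), sum,
               default = 0)
  data.frame(class = names(bp), kb = as.numeric(bp) / 1000,
             fraction = as.numeric(bp) / region_length,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Published aCGH summary of the 45 kb LCR region
#'
#' Bundled table of mean log2 ratios, DLRS and reported integer copy-number
#' estimates of the 45 kb LCR region for 32 DNA samples hybridized against
#' the NA10851 reference (a four-copy genome): 10 unaffected human samples,
#' 8 patients with the recurrent homozygous NPHP1 deletion, and 14 nonhuman
#' primates. Used to validate [estimate_cn_intra()] and
#' [classify_cn_interspecies()]. Two human rows (H1-P22 and PT7) are known
#' discordances where the reported call drew on orthogonal evidence (optical
#' maps; known deletion status with abnormally high DLRS) rather than the
#' log-ratio rule alone.
#'
#' @return `data.frame`: `sample`, `mean_lr`, `cn_printed`, `dlrs`,
#'   `species`, `affected`.
#' @export
acgh_45k_summary <- function() {
  read_pipeline_tsv(system.file("extdata", "acgh_45k_summary.tsv",
                                package = "nphp1sv", mustWork = TRUE))
}

#' Per-window species averages of copy number
#'
#' @param cn_table `data.frame` with columns `start` (window start, aligned
#'   across individuals), `individual`, `species`, `value`.
#' @return `data.frame`: `species`, `start`, `mean_cn`, `n`; windows missing
#'   in some individuals are averaged over those present.
#' @export
window_species_average <- function(cn_table) {
  stopifnot(all(c("start", "individual", "species", "value") %in%
                  names(cn_table)))
  agg <- stats::aggregate(value ~ species + start, data = cn_table,
                          FUN = mean)
  cnt <- stats::aggregate(value ~ species + start, data = cn_table,
                          FUN = length)
  out <- data.frame(species = agg$species, start = agg$start,
                    mean_cn = agg$value, n = cnt$value,
                    stringsAsFactors = FALSE)
  out[order(out$species, out$start), , drop = FALSE]
}
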