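# Generators for the evidence types the pipeline consumes: fosmid
# end-sequence pairs, noisy single-molecule Rmaps, aCGH probe ratios,
# read-depth windows, and population samples.

#' Simulate a fosmid end-sequence-pair library
#'
#' Clones are drawn uniformly from the genotype's haplotype components
#' (weighted by fraction) with insert length Normal(mean, sd) truncated
#' positive, then both ends are projected through the haplotype's segment
#' map into the reference (H1) coordinate frame. Discordance signatures
#' emerge naturally: a clone spanning a lost 45 kb copy maps with its span
#' enlarged by (copy length - stuffer length); a clone spanning an inversion
#' breakpoint maps with equal-strand ends. Ends landing inside the stuffer
#' (absent from the reference) are unmappable and reported with mapq 0.
#'
#' @param g A `Genotype`.
#' @param n_clones Number of clones (> 0).
#' @param p A [sim_params()].
#' @param seed_offset Extra offset added to the fosmid seed stream, so
#'   replicate libraries can be drawn from one parameter set.
#' @return `data.frame` with columns `clone_id`, `chrom`, `pos1`, `strand1`,
#'   `pos2`, `strand2`, `mapq`, and `origin` (simulation truth label).
#' @export
simulate_fosmid_library <- function(g, n_clones, p = sim_params(),
                                    seed_offset = 0L) {
  stopifnot(inherits(g, "Genotype"), n_clones > 0)
  arch <- g$components[[1]]$arch
  .with_seed(.stream_seed(p, "fosmid") + seed_offset, {
    comp <- sample.int(length(g$components), n_clones, replace = TRUE,
                       prob = g$fractions)
    insert <- stats::rnorm(n_clones, p$fosmid_insert_mean, p$fosmid_insert_sd)
    while (any(insert <= 0))
      insert[insert <= 0] <- stats::rnorm(sum(insert <= 0),
                                          p$fosmid_insert_mean,
                                          p$fosmid_insert_sd)
    insert <- round(insert)

    pos1 <- pos2 <- numeric(n_clones)
    str1 <- str2 <- character(n_clones)
    mapq <- integer(n_clones)
    for (ci in seq_along(g$components)) {
      idx <- which(comp == ci)
      if (length(idx) == 0L) next
      hap <- g$components[[ci]]
      L <- hap_length(hap)
      start <- floor(stats::runif(length(idx), 0, pmax(1, L - insert[idx])))
      endpos <- pmin(start + insert[idx] - 1, L - 1)
      p1 <- .project_hap_to_ref(hap, start)
      p2 <- .project_hap_to_ref(hap, endpos)
      # read orientation in haplotype frame: end1 reads +, end2 reads -
      s1 <- ifelse(is.na(p1$strand), NA_integer_, 1L * p1$strand)
      s2 <- ifelse(is.na(p2$strand), NA_integer_, -1L * p2$strand)
      pos1[idx] <- p1$ref; pos2[idx] <- p2$ref
      str1[idx] <- ifelse(is.na(s1), "*", ifelse(s1 == 1L, "+", "-"))
      str2[idx] <- ifelse(is.na(s2), "*", ifelse(s2 == 1L, "+", "-"))
      mapq[idx] <- ifelse(is.na(p1$ref) | is.na(p2$ref), 0L, 60L)
    }
    labels <- vapply(g$components, function(h) h$label, character(1))
    data.frame(clone_id = sprintf("clone%05d", seq_len(n_clones)),
               chrom = arch$chrom, pos1 = pos1, strand1 = str1,
               pos2 = pos2, strand2 = str2, mapq = mapq,
               origin = labels[comp], stringsAsFactors = FALSE)
  })
}

#' Simulate noisy single-molecule Rmaps
#'
#' Perturbs a true fragment list per molecule: each true cut is missed with
#' probability `rmap_p_miss` (merging adjacent fragments), false cuts arrive
#' as Poisson(`rmap_false_rate` x length) at uniform positions, fragment
#' sizes are scaled by Normal(1, `rmap_cv`), and fragments below
#' `rmap_min_frag` are merged into a neighbour.
#'
#' @param rmap True `Rmap` (e.g. from [digest_insilico()]).
#' @param n_molecules Number of molecules to simulate.
#' @param p A [sim_params()].
#' @param seed_offset Extra offset added to the rmap seed stream, so
#'   replicate libraries can be drawn from one parameter set.
#' @return List of `Rmap` objects.
#' @export
simulate_rmaps <- function(rmap, n_molecules, p = sim_params(),
                           seed_offset = 0L) {
  stopifnot(inherits(rmap, "Rmap"), n_molecules >= 1)
  truth <- rmap$fragments
  total_kb <- sum(truth)
  .with_seed(.stream_seed(p, "rmap") + seed_offset, {
    lapply(seq_len(n_molecules), function(i) {
      cuts <- cumsum(truth)[-length(truth)]
      keep <- stats::runif(length(cuts)) >= p$rmap_p_miss
      cuts <- cuts[keep]
      n_false <- stats::rpois(1, p$rmap_false_rate * total_kb * 1000)
      if (n_false > 0)
        cuts <- c(cuts, stats::runif(n_false, 0, total_kb))
      cuts <- sort(cuts)
      frags <- diff(c(0, cuts, total_kb))
      frags <- frags[frags > 0]
      frags <- frags * pmax(0.1, stats::rnorm(length(frags), 1, p$rmap_cv))
      m <- new_rmap(frags, map_id = sprintf("%s_mol%04d", rmap$map_id, i),
                    enzyme = rmap$enzyme)
      merge_small_fragments(m, p$rmap_min_frag / 1000)
    })
  })
}

## ---- aCGH -----------------------------------------------------------------

#' Default aCGH probe design for the locus
#'
#' Mimics a design in which only one copy of each LCR family is tiled (the
#' signal of a probe then sums over all homologous copies): probes tile
#' 45MID (`target = "45K"`), the non-45 portion of 358PROX (`"358K"`), the
#' gene (`"NPHP1"`), and flanking unique sequence (`"unique"`).
#'
#' @param arch A `LocusArchitecture`.
#' @param spacing Probe spacing in bp (default 500).
#' @return `data.frame`: `probe_id`, `chrom`, `start`, `end`, `target`.
#' @export
default_probes <- function(arch, spacing = 500L) {
  el <- arch$elements
  iv <- function(name) el[el$name == name, ]
  tile <- function(start, end, target) {
    s <- seq(start, end - 60L, by = spacing)
    data.frame(chrom = arch$chrom, start = s, end = s + 60L, target = target,
               stringsAsFactors = FALSE)
  }
  m45 <- iv("45MID"); p358 <- iv("358PROX"); p45 <- iv("45PROX")
  gene <- arch$gene
  probes <- rbind(
    tile(m45$start, m45$end, "45K"),
    tile(p358$start, p45$start, "358K"),
    tile(gene$start, gene$end, "NPHP1"),
    tile(arch$locus_start, p358$start, "unique"),
    tile(iv("358DIST")$end, arch$locus_end, "unique")
  )
  probes <- probes[order(probes$start), ]
  probes$probe_id <- sprintf("probe%05d", seq_len(nrow(probes)))
  rownames(probes) <- NULL
  probes[, c("probe_id", "chrom", "start", "end", "target")]
}

# hybridizable dosage of a genotype for a probe target class
.target_dosage <- function(g, target) {
  switch(target,
         "45K" = total45(g),
         "358K" = 2 * g$ploidy,
         g$ploidy)
}

#' Simulate aCGH log2 ratios
#'
#' Per-probe log ratio `log2((test dosage x identity) / ref dosage)` plus
#' Normal(0, `acgh_sigma`) noise. Probes tiling an LCR family count the
#' summed dosage over all homologous copies. The identity factor attenuates
#' test-sample hybridization for diverged (cross-species) DNA. Probes with
#' zero reference dosage are masked (dropped with a warning attribute).
#'
#' @param test,ref `Genotype` objects for test and reference samples.
#' @param probes Probe table as from [default_probes()]; an optional
#'   `identity` column overrides `p$acgh_identity` per probe.
#' @param p A [sim_params()].
#' @param seed_offset Extra offset added to the aCGH seed stream.
#' @return A `RegionDosage` of kind `"log2ratio"`.
#' @export
simulate_acgh <- function(test, ref, probes = NULL, p = sim_params(),
                          seed_offset = 0L) {
  stopifnot(inherits(test, "Genotype"), inherits(ref, "Genotype"))
  arch <- test$components[[1]]$arch
  if (is.null(probes)) probes <- default_probes(arch)
  ident <- if ("identity" %in% names(probes)) probes$identity else
    rep(p$acgh_identity, nrow(probes))
  test_d <- vapply(probes$target, .target_dosage, numeric(1), g = test)
  ref_d <- vapply(probes$target, .target_dosage, numeric(1), g = ref)
  masked <- ref_d <= 0
  .with_seed(.stream_seed(p, "acgh") + seed_offset, {
    lr <- log2((test_d * ident) / ref_d) +
      stats::rnorm(nrow(probes), 0, p$acgh_sigma)
    tab <- data.frame(probe_id = probes$probe_id, chrom = probes$chrom,
                      start = probes$start, end = probes$end,
                      target = probes$target, value = lr,
                      stringsAsFactors = FALSE)[!masked, , drop = FALSE]
    rownames(tab) <- NULL
    region_dosage(tab, kind = "log2ratio", chrom = arch$chrom)
  })
}

#' Simulate windowed read-depth copy number
#'
#' Tiles the locus with fixed-size windows in the reference frame and
#' assigns each window its true paralog-aggregate diploid copy number
#' (windows within a 45 kb copy see the genotype's total 45 kb dosage;
#' windows within a 358 kb copy see the two-copy family dosage; unique
#' windows see the ploidy) plus Normal(0, `readdepth_sigma`) noise.
#'
#' @param g A `Genotype`.
#' @param p A [sim_params()].
#' @param seed_offset Extra offset added to the read-depth seed stream.
#' @return A `RegionDosage` of kind `"copynumber"`.
#' @export
simulate_readdepth <- function(g, p = sim_params(), seed_offset = 0L) {
  stopifnot(inherits(g, "Genotype"))
  arch <- g$components[[1]]$arch
  w <- p$readdepth_window
  starts <- seq(arch$locus_start, arch$locus_end - w, by = w)
  mid <- starts + w / 2
  el <- arch$elements
  in_fam <- function(fam) {
    rows <- el[el$family == fam, , drop = FALSE]
    Reduce(`|`, lapply(seq_len(nrow(rows)), function(i)
      mid >= rows$start[i] & mid < rows$end[i]), logical(length(mid)))
  }
  target <- ifelse(in_fam("45K"), "45K", ifelse(in_fam("358K"), "358K", "unique"))
  truth <- vapply(target, .target_dosage, numeric(1), g = g)
  .with_seed(.stream_seed(p, "readdepth") + seed_offset, {
    cn <- truth + stats::rnorm(length(truth), 0, p$readdepth_sigma)
    tab <- data.frame(probe_id = sprintf("win%05d", seq_along(starts)),
                      chrom = arch$chrom, start = starts, end = starts + w,
                      target = target, value = cn, stringsAsFactors = FALSE)
    region_dosage(tab, kind = "copynumber", chrom = arch$chrom)
  })
}

## ---- populations ----------------------------------------------------------

# count45 per label without building haplotype objects
.count45_label <- function(labels) {
  defs <- .haplotype_defs()
  vapply(labels, function(l) 3L - length(defs[[l]]$lost), integer(1))
}

#' Default per-population SV-haplotype frequencies
#'
#' Haplotype frequencies for YRI, CHB+JPT and CEU chosen so that random
#' union of gametes approximately reproduces the published diploid 45 kb
#' LCR copy-number distributions in those populations (CN2..CN6 at roughly
#' 1-2%, 8-18%, 38-74%, 16-31%, 1-11%): one-copy haplotypes (H7), two-copy
#' haplotypes (H2 dominant, some H5), and three-copy haplotypes (H3 over
#' the minor reference H1).
#'
#' @return Named list of named frequency vectors, one per population.
#' @export
default_population_freqs <- function() {
  list(
    YRI       = c(H1 = 0.08,  H2 = 0.37, H3 = 0.25,  H5 = 0.16, H7 = 0.14),
    `CHB+JPT` = c(H1 = 0.04,  H2 = 0.51, H3 = 0.13,  H5 = 0.22, H7 = 0.10),
    CEU       = c(H1 = 0.025, H2 = 0.56, H3 = 0.075, H5 = 0.24, H7 = 0.10)
  )
}

#' Sample diploid genotypes from per-population haplotype frequencies
#'
#' Individuals are drawn as independent random unions of two haplotypes
#' (Hardy-Weinberg within population).
#'
#' @param freqs Named list: one named numeric vector of haplotype
#'   frequencies per population, each summing to 1 (tolerance 1e-9).
#' @param n Individuals per population (recycled; may be a named vector).
#' @param p A [sim_params()].
#' @return `data.frame`: `individual_id`, `population`, `hap1`, `hap2`,
#'   `count45` (diploid 45 kb LCR copy number).
#' @export
sample_population <- function(freqs, n, p = sim_params()) {
  stopifnot(is.list(freqs), !is.null(names(freqs)))
  for (pop in names(freqs))
    if (abs(sum(freqs[[pop]]) - 1) > 1e-9)
      stop("frequencies for ", pop, " do not sum to 1")
  n <- rep(n, length.out = length(freqs))
  .with_seed(.stream_seed(p, "population"), {
    out <- lapply(seq_along(freqs), function(i) {
      pop <- names(freqs)[i]
      if (n[i] == 0) return(NULL)
      labs <- names(freqs[[pop]])
      h1 <- sample(labs, n[i], replace = TRUE, prob = freqs[[pop]])
      h2 <- sample(labs, n[i], replace = TRUE, prob = freqs[[pop]])
      data.frame(individual_id = sprintf("%s_%04d", pop, seq_len(n[i])),
                 population = pop, hap1 = h1, hap2 = h2,
                 count45 = .count45_label(h1) + .count45_label(h2),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
      out <- data.frame(individual_id = character(0),
                        population = character(0), hap1 = character(0),
                        hap2 = character(0), count45 = integer(0))
    rownames(out) <- NULL
    out
  })
}
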