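# Integration of fosmid, Rmap and dosage evidence into per-sample
# SV-haplotype genotype reports.

#' Map allele evidence to an SV-haplotype label
#'
#' Inverse of the [make_haplotype()] lookup: which of H1..H7 has exactly
#' the given lost 45 kb copies and inversion state.
#'
#' @param lost_copies Character subset of `c("45PROX", "45DIST")`.
#' @param inversion Logical.
#' @return A label `"H1"`..`"H7"`, or `"custom"` (with attribute
#'   `flagged = TRUE`) when no known haplotype matches.
#' @export
allele_to_haplotype <- function(lost_copies = character(), inversion = FALSE) {
  bad <- setdiff(lost_copies, c("45PROX", "45DIST"))
  if (length(bad)) {
    out <- "custom"
    attr(out, "flagged") <- TRUE
    return(out)
  }
  defs <- .haplotype_defs()
  for (lab in names(defs)) {
    d <- defs[[lab]]
    if (setequal(d$lost, lost_copies) && identical(d$inv, inversion))
      return(lab)
  }
  out <- "custom"
  attr(out, "flagged") <- TRUE
  out
}

#' Enumerate diploid genotypes consistent with a total 45 kb copy number
#'
#' All unordered pairs (with repetition) of observed allele labels whose
#' 45 kb copy counts sum to `total45`. With more than two observed labels
#' the sample must be a mosaic mixture of cell populations; each pair is
#' then one candidate mixture component and must still satisfy the dosage
#' constraint.
#'
#' @param total45 Diploid 45 kb LCR copy number (>= 0).
#' @param observed Character vector of observed allele labels (H1..H7).
#' @return `data.frame` with columns `hap1`, `hap2` (possibly 0 rows), with
#'   attribute `mosaic` set when `length(observed) > 2`.
#' @export
enumerate_diploid <- function(total45, observed) {
  stopifnot(total45 >= 0, is.character(observed))
  observed <- sort(unique(observed))
  cnt <- .count45_label(observed)
  rows <- list()
  for (i in seq_along(observed)) for (j in i:length(observed)) {
    if (cnt[i] + cnt[j] == total45)
      rows[[length(rows) + 1L]] <- data.frame(hap1 = observed[i],
                                              hap2 = observed[j],
                                              stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(hap1 = character(0), hap2 = character(0))
  attr(out, "mosaic") <- length(observed) > 2L
  out
}

#' Integrate multi-assay evidence into a genotype report
#'
#' Rmap allele types are the primary structural evidence; fosmid ESP
#' evidence cross-checks them (deletion and inversion support); dosage
#' fixes the diploid total 45 kb copy number, which constrains the set of
#' consistent genotypes. Discordant sources are flagged, never dropped.
#'
#' @param rmap_alleles Character vector of allele-type labels from
#'   [call_haplotype_rmap()], or `NULL`.
#' @param fosmid_evidence List from [aggregate_individual()], or `NULL`.
#' @param cn_call A `CNCall` (diploid 45 kb dosage), or `NULL`.
#' @param sample_id Sample identifier.
#' @param ploidy 1 for functionally haploid samples (CHM), else 2.
#' @param arch `LocusArchitecture` for protection classification.
#' @return An object of class `GenotypeReport`: `sample_id`,
#'   `allele_types`, `genotypes` (data.frame hap1/hap2), `total45`,
#'   `protection` (per consistent genotype), `flags`.
#' @export
integrate_evidence <- function(rmap_alleles = NULL, fosmid_evidence = NULL,
                               cn_call = NULL, sample_id = "sample",
                               ploidy = 2L,
                               arch = build_reference_architecture()) {
  if (is.null(rmap_alleles) && is.null(fosmid_evidence) && is.null(cn_call))
    stop("at least one evidence source is required")
  flags <- list()

  allele_types <- rmap_alleles
  if (is.null(allele_types) && !is.null(fosmid_evidence)) {
    # compose a single allele hypothesis from fosmid classes alone
    lost <- character(0)
    if (isTRUE(fosmid_evidence$deletion)) {
      sides <- fosmid_evidence$deletion_sides
      if ("proximal" %in% sides) lost <- c(lost, "45PROX")
      if ("distal" %in% sides) lost <- c(lost, "45DIST")
      if (length(lost) == 0L) lost <- "45PROX"  # side unresolved
    }
    allele_types <- allele_to_haplotype(lost,
                                        isTRUE(fosmid_evidence$inversion))
    flags$fosmid_only <- TRUE
  }
  allele_types <- sort(unique(allele_types))

  # cross-check rmap vs fosmid
  if (!is.null(rmap_alleles) && !is.null(fosmid_evidence)) {
    defs <- .haplotype_defs()
    any_loss <- any(vapply(allele_types, function(l)
      length(defs[[l]]$lost) > 0, logical(1)))
    any_inv <- any(vapply(allele_types, function(l) defs[[l]]$inv, logical(1)))
    if (isTRUE(fosmid_evidence$deletion) != any_loss)
      flags$fosmid_deletion_discordant <- TRUE
    if (isTRUE(fosmid_evidence$inversion) != any_inv)
      flags$fosmid_inversion_discordant <- TRUE
  }

  total <- if (!is.null(cn_call)) cn_call$cn else NA_integer_

  if (ploidy == 1L) {
    genotypes <- data.frame(hap1 = allele_types, hap2 = NA_character_,
                            stringsAsFactors = FALSE)
    protection <- vapply(allele_types, function(l)
      classify_nahr_susceptibility(make_haplotype(l, arch)), character(1))
  } else if (is.na(total)) {
    genotypes <- data.frame(hap1 = character(0), hap2 = character(0))
    protection <- character(0)
    flags$no_dosage <- TRUE
  } else {
    genotypes <- enumerate_diploid(total, allele_types)
    if (isTRUE(attr(genotypes, "mosaic"))) flags$mosaic <- TRUE
    if (nrow(genotypes) == 0L) flags$inconsistent <- TRUE
    protection <- vapply(seq_len(nrow(genotypes)), function(i)
      genotype_protection_report(
        make_genotype(c(genotypes$hap1[i], genotypes$hap2[i]), arch = arch)),
      character(1))
  }

  structure(list(sample_id = sample_id, allele_types = allele_types,
                 genotypes = genotypes, total45 = total,
                 protection = protection, flags = flags),
            class = "GenotypeReport")
}

#' @export
print.GenotypeReport <- function(x, ...) {
  cat(sprintf("GenotypeReport %s\n", x$sample_id))
  cat("  allele types:", paste(x$allele_types, collapse = ", "), "\n")
  cat("  total45:", x$total45, "\n")
  if (nrow(x$genotypes)) {
    for (i in seq_len(nrow(x$genotypes)))
      cat(sprintf("  genotype: %s/%s (%s)\n", x$genotypes$hap1[i],
                  ifelse(is.na(x$genotypes$hap2[i]), "-", x$genotypes$hap2[i]),
                  if (length(x$protection) >= i) x$protection[i] else ""))
  } else cat("  no consistent genotype\n")
  if (length(x$flags))
    cat("  flags:", paste(names(x$flags), collapse = ", "), "\n")
  invisible(x)
}
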