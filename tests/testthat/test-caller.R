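# Evidence-to-haplotype lookup, diploid enumeration, and integration.

test_that("allele lookup inverts the haplotype definitions", {
  expect_equal(allele_to_haplotype("45PROX", TRUE), "H2")
  expect_equal(allele_to_haplotype(c("45PROX", "45DIST"), FALSE), "H7")
  expect_equal(allele_to_haplotype(), "H1")
  # round-trip over every known haplotype
  arch <- fx_arch()
  for (lab in paste0("H", 1:7)) {
    h <- make_haplotype(lab, arch)
    expect_equal(allele_to_haplotype(h$lost_copies, h$inversion), lab)
  }
  custom <- allele_to_haplotype("not_a_copy", FALSE)
  expect_equal(as.character(custom), "custom")
  expect_true(attr(custom, "flagged"))
})

test_that("diploid enumeration respects the dosage constraint", {
  g <- enumerate_diploid(4, "H2")
  expect_equal(g$hap1, "H2")
  expect_equal(g$hap2, "H2")

  # mosaic case: three observed allele types, diploid dosage three
  g3 <- enumerate_diploid(3, c("H5", "H6", "H7"))
  expect_true(attr(g3, "mosaic"))
  expect_equal(paste(g3$hap1, g3$hap2, sep = "/"), c("H5/H7", "H6/H7"))

  # inconsistent evidence yields an empty set
  expect_equal(nrow(enumerate_diploid(2, "H5")), 0L)

  # exhaustive property: every returned pair sums to total45
  labs <- paste0("H", 1:7)
  cnt <- c(H1 = 3, H2 = 2, H3 = 3, H4 = 1, H5 = 2, H6 = 2, H7 = 1)
  for (total in 0:6) {
    for (m in 1:3) {
      for (pick in utils::combn(labs, m, simplify = FALSE)) {
        g <- enumerate_diploid(total, pick)
        if (nrow(g))
          expect_true(all(cnt[g$hap1] + cnt[g$hap2] == total))
      }
    }
  }
})

test_that("evidence integration reproduces the canonical report patterns", {
  arch <- fx_arch()
  # homozygous H2 with concordant fosmid evidence and diploid dosage 4
  fos <- list(deletion = TRUE, deletion_sides = "proximal",
              inversion = TRUE, n_usable = 100L)
  rep1 <- integrate_evidence(rmap_alleles = "H2", fosmid_evidence = fos,
                             cn_call = estimate_cn_intra(0.06),
                             sample_id = "s1", arch = arch)
  expect_equal(rep1$allele_types, "H2")
  expect_equal(paste(rep1$genotypes$hap1, rep1$genotypes$hap2, sep = "/"),
               "H2/H2")
  expect_equal(rep1$protection, "fully_susceptible")
  expect_length(rep1$flags, 0)

  # haploid sample with a single allele and no dosage
  rep2 <- integrate_evidence(rmap_alleles = "H5", sample_id = "s2",
                             ploidy = 1L, arch = arch)
  expect_equal(rep2$genotypes$hap1, "H5")
  expect_equal(unname(rep2$protection), "protected")

  # mosaic: three allele types constrained to dosage 3
  rep3 <- integrate_evidence(rmap_alleles = c("H5", "H6", "H7"),
                             cn_call = estimate_cn_intra(-0.22),
                             sample_id = "s3", arch = arch)
  expect_equal(rep3$total45, 3L)
  expect_true(isTRUE(rep3$flags$mosaic))
  expect_equal(paste(rep3$genotypes$hap1, rep3$genotypes$hap2, sep = "/"),
               c("H5/H7", "H6/H7"))
  expect_true(all(rep3$protection == "fully_protected"))
})

test_that("discordant evidence sources are flagged, not dropped", {
  arch <- fx_arch()
  # fosmids see a deletion but the rmap call is the reference haplotype
  fos <- list(deletion = TRUE, deletion_sides = "proximal",
              inversion = FALSE, n_usable = 50L)
  rep <- integrate_evidence(rmap_alleles = "H1", fosmid_evidence = fos,
                            cn_call = estimate_cn_intra(0.55),
                            sample_id = "s4", arch = arch)
  expect_true(isTRUE(rep$flags$fosmid_deletion_discordant))
  expect_equal(paste(rep$genotypes$hap1, rep$genotypes$hap2, sep = "/"),
               "H1/H1")

  # dosage inconsistent with the observed allele types
  rep2 <- integrate_evidence(rmap_alleles = "H5",
                             cn_call = estimate_cn_intra(-1.0),
                             sample_id = "s5", arch = arch)
  expect_equal(nrow(rep2$genotypes), 0L)
  expect_true(isTRUE(rep2$flags$inconsistent))

  expect_error(integrate_evidence(), "at least one evidence source")
})

test_that("fosmid-only evidence composes an allele hypothesis", {
  arch <- fx_arch()
  fos <- list(deletion = TRUE, deletion_sides = "proximal",
              inversion = TRUE, n_usable = 30L)
  rep <- integrate_evidence(fosmid_evidence = fos,
                            cn_call = estimate_cn_intra(0.0),
                            sample_id = "s6", arch = arch)
  expect_equal(rep$allele_types, "H2")
  expect_true(isTRUE(rep$flags$fosmid_only))
})
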