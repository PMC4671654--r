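# Coordinate model, structural transforms, and NAHR susceptibility.

test_that("reference architecture matches the locus coordinate table", {
  arch <- fx_arch()
  el <- arch$elements
  expect_equal(sum(el$family == "45K"), 3L)
  expect_equal(sum(el$family == "358K"), 2L)
  # the two 358 kb copies are inverted relative to each other
  ori358 <- el$orientation[el$family == "358K"]
  expect_equal(prod(ori358), -1)
  expect_equal(el$end[el$name == "45PROX"] - el$start[el$name == "45PROX"],
               44372)
  # containments and gene placement
  expect_true(el$start[el$name == "45PROX"] >= el$start[el$name == "358PROX"])
  expect_true(el$end[el$name == "45DIST"] <= el$end[el$name == "358DIST"])
})

test_that("architecture validation rejects broken configurations", {
  cfg <- nphp1_coordinates()
  cfg$start[cfg$name == "45PROX"] <- cfg$start[cfg$name == "358PROX"] - 100L
  expect_error(build_reference_architecture(cfg), "containment")
  cfg2 <- nphp1_coordinates()
  cfg2$end[cfg2$name == "NPHP1"] <- cfg2$end[cfg2$name == "45MID"]
  expect_error(build_reference_architecture(cfg2), "gene")
})

test_that("haplotype lookup gives the expected compositions", {
  arch <- fx_arch()
  comp <- list(H1 = c(3L, FALSE), H2 = c(2L, TRUE), H3 = c(3L, TRUE),
               H4 = c(1L, TRUE), H5 = c(2L, FALSE), H6 = c(2L, TRUE),
               H7 = c(1L, FALSE))
  for (lab in names(comp)) {
    h <- make_haplotype(lab, arch)
    expect_equal(count45(h), comp[[lab]][1], info = lab)
    expect_equal(h$inversion, as.logical(comp[[lab]][2]), info = lab)
    # count45 conservation
    expect_equal(count45(h) + length(h$lost_copies), 3L, info = lab)
  }
  expect_error(make_haplotype("H8", arch), "unknown")
  # H1 is the identity
  h1 <- make_haplotype("H1", arch)
  expect_equal(nrow(h1$segments), 1L)
  expect_equal(hap_length(h1), arch$locus_end - arch$locus_start)
})

test_that("inversion is an involution that reorders the middle elements", {
  arch <- fx_arch()
  h1 <- make_haplotype("H1", arch)
  hi <- apply_inversion(h1)
  expect_equal(hap_length(hi), hap_length(h1))
  expect_equal(count45(hi), count45(h1))
  expect_equal(apply_inversion(hi)$segments, h1$segments)

  el <- hap_elements(hi)
  # order becomes ... 45PROX, 45MID', NPHP1', 45DIST ...
  expect_equal(el$name, c("358PROX", "45PROX", "45MID", "NPHP1", "358DIST",
                          "45DIST"))
  # 45MID flips sign, so 45MID vs 45DIST relative orientation flips - to +
  m <- el$orientation[el$name == "45MID"]
  d <- el$orientation[el$name == "45DIST"]
  expect_equal(m * d, 1)
  # gene is inverted
  expect_equal(el$orientation[el$name == "NPHP1"], -1L)
})

test_that("45 kb deletion changes length by copy length minus stuffer", {
  arch <- fx_arch()
  h1 <- make_haplotype("H1", arch)
  hd <- delete_45_with_stuffer(h1, "45PROX")
  expect_equal(hap_length(hd) - hap_length(h1), -(44372 - 5936))
  expect_error(delete_45_with_stuffer(hd, "45PROX"), "already lost")

  # deleting both copies without inversion composes H7
  h7 <- delete_45_with_stuffer(hd, "45DIST")
  expect_equal(h7$segments, make_haplotype("H7", arch)$segments)
  expect_equal(count45(h7), 1L)

  # degenerate configuration: stuffer as long as the copy, net zero
  arch0 <- build_reference_architecture(stuffer_length = 44372L)
  h0 <- delete_45_with_stuffer(make_haplotype("H1", arch0), "45PROX")
  expect_equal(hap_length(h0), arch0$locus_end - arch0$locus_start)
})

test_that("NAHR susceptibility splits H1-H7 into the known classes", {
  arch <- fx_arch()
  cls <- vapply(paste0("H", 1:7), function(l)
    classify_nahr_susceptibility(make_haplotype(l, arch)), character(1))
  expect_equal(names(cls)[cls == "susceptible"], c("H1", "H2", "H3"))
  expect_equal(names(cls)[cls == "protected"], c("H4", "H5", "H6", "H7"))
})

test_that("genotype protection report covers all diploid combinations", {
  arch <- fx_arch()
  expect_equal(genotype_protection_report(make_genotype(c("H2", "H2"),
                                                        arch = arch)),
               "fully_susceptible")
  expect_equal(genotype_protection_report(make_genotype(c("H5", "H2"),
                                                        arch = arch)),
               "heterozygous_protective")
  expect_equal(genotype_protection_report(make_genotype(c("H5", "H5"),
                                                        arch = arch)),
               "fully_protected")
  # haploid input reports the per-haplotype class
  hap <- genotype_protection_report(make_genotype("H5", ploidy = 1L,
                                                  arch = arch))
  expect_equal(unname(hap), "protected")
})

test_that("genotype invariants hold", {
  arch <- fx_arch()
  expect_equal(total45(make_genotype(c("H2", "H2"), arch = arch)), 4)
  expect_equal(total45(make_genotype(c("H1", "H1"), arch = arch)), 6)
  expect_error(make_genotype(c("H1", "H2"), fractions = c(0.7, 0.2),
                             arch = arch), "sum to 1")
})
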