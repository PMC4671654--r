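# Generators: determinism, planted structure, and error-model expectations.

test_that("sequence synthesis is deterministic and plants paralogy", {
  arch <- fx_arch()
  p <- fx_params()
  s1 <- fx_h1_seq()
  expect_equal(nchar(s1), arch$locus_end - arch$locus_start)
  s1b <- synth_haplotype_sequence(arch, make_haplotype("H1", arch), p)
  expect_identical(s1, s1b)

  # paralog identity ~ 1 - 2*delta (each copy mutated independently);
  # site planting is disabled so only divergence separates the copies
  el <- arch$elements
  psite0 <- sim_params(seed = 42L, swai_sites = integer(0))
  ssite0 <- synth_haplotype_sequence(arch, make_haplotype("H1", arch), psite0)
  off <- function(s, name, n = 40000) {
    st <- el$start[el$name == name] - arch$locus_start
    strsplit(substr(s, st + 1, st + n), "")[[1]]
  }
  ident <- mean(off(ssite0, "45PROX") == off(ssite0, "45MID"))
  expect_gt(ident, 0.994)
  expect_lt(ident, 0.999)

  # zero divergence makes the copies identical
  p0 <- sim_params(seed = 42L, paralog_divergence = 0,
                   swai_sites = integer(0))
  s0 <- synth_haplotype_sequence(arch, make_haplotype("H1", arch), p0)
  expect_identical(off(s0, "45PROX"), off(s0, "45MID"))
})

test_that("SwaI sites land exactly at the configured positions", {
  arch <- fx_arch()
  s1 <- fx_h1_seq()
  found <- as.integer(gregexpr("ATTTAAAT", s1, fixed = TRUE)[[1]]) - 1L +
    arch$locus_start
  expect_equal(found, default_swai_sites(arch))
})

test_that("concordant fosmid spans follow the insert distribution", {
  arch <- fx_arch()
  p <- fx_params()
  g <- make_genotype(c("H1", "H1"), arch = arch)
  esp <- simulate_fosmid_library(g, 5000, p)
  expect_identical(esp, simulate_fosmid_library(g, 5000, p))  # pure function
  calls <- classify_esp(esp, arch = arch)
  # null donor: no inversion signatures at all, and apparent del/ins calls
  # only from the tails of the insert distribution beyond the +/-3.2 sd
  # classification bounds
  expect_equal(sum(calls$class == "inversion"), 0L)
  expect_lt(mean(calls$class != "concordant"), 0.005)
  ks <- suppressWarnings(
    stats::ks.test(calls$ref_span, "pnorm", p$fosmid_insert_mean,
                   p$fosmid_insert_sd))
  expect_gt(ks$p.value, 0.01)
})

test_that("fosmid deletion spans grow by the lost-copy net length", {
  arch <- fx_arch()
  p <- fx_params()
  g <- make_genotype(c("H2", "H2"), arch = arch)
  calls <- classify_esp(simulate_fosmid_library(g, 3000, p), arch = arch)
  del <- calls[calls$class == "deletion", ]
  expect_gt(nrow(del), 10)
  expect_equal(mean(del$ref_span), p$fosmid_insert_mean + 44372 - 5936,
               tolerance = 0.05)
  expect_gt(sum(calls$class == "inversion"), 0)
})

test_that("rmap error model meets its limiting and expectation checks", {
  truth <- new_rmap(c(10, 15, 20, 30, 25), "truth")
  exact <- sim_params(seed = 1, rmap_cv = 0, rmap_p_miss = 0,
                      rmap_false_rate = 0)
  m <- simulate_rmaps(truth, 1, exact)[[1]]
  expect_equal(m$fragments, truth$fragments)

  allmiss <- sim_params(seed = 1, rmap_cv = 0, rmap_p_miss = 1,
                        rmap_false_rate = 0)
  m1 <- simulate_rmaps(truth, 1, allmiss)[[1]]
  expect_equal(m1$fragments, sum(truth$fragments))

  # E[#fragments] = true_cuts*(1-p_miss) + Poisson mean + 1
  p <- sim_params(seed = 9, rmap_cv = 0, rmap_p_miss = 0.1,
                  rmap_false_rate = 1 / 50000, rmap_min_frag = 0)
  mols <- simulate_rmaps(truth, 1500, p)
  nf <- vapply(mols, function(m) length(m$fragments), numeric(1))
  expected <- 4 * 0.9 + sum(truth$fragments) * 1000 / 50000 + 1
  expect_equal(mean(nf), expected, tolerance = 0.03)

  # total map length conserved in expectation
  tot <- vapply(mols, function(m) sum(m$fragments), numeric(1))
  expect_equal(mean(tot), sum(truth$fragments), tolerance = 0.01)
})

test_that("aCGH log ratios follow dosage and identity factors", {
  arch <- fx_arch()
  g4 <- make_genotype(c("H2", "H2"), arch = arch)
  g2 <- make_genotype(c("H7", "H7"), arch = arch)
  noiseless <- sim_params(seed = 1, acgh_sigma = 0)
  d <- simulate_acgh(g2, g4, p = noiseless)
  expect_equal(unique(dosage_values(d, "45K")), -1)    # log2(2/4)
  expect_equal(unique(dosage_values(d, "unique")), 0)

  # identity factor 0.63 at equal copy number: chimp-like intermediate LR
  chimp <- sim_params(seed = 1, acgh_sigma = 0, acgh_identity = 0.63)
  d2 <- simulate_acgh(g4, g4, p = chimp)
  expect_equal(unique(round(dosage_values(d2, "45K"), 2)), -0.67)

  d3 <- simulate_acgh(g4, g4, p = noiseless)
  expect_true(all(dosage_values(d3) == 0))
})

test_that("read-depth windows average to the true copy number", {
  arch <- fx_arch()
  g <- make_genotype(c("H2", "H2"), arch = arch)
  p0 <- sim_params(seed = 1, readdepth_sigma = 0)
  d0 <- simulate_readdepth(g, p0)
  expect_equal(unique(dosage_values(d0, "45K")), 4)
  expect_equal(unique(dosage_values(d0, "unique")), 2)

  p <- fx_params()
  d <- simulate_readdepth(g, p)
  expect_identical(d, simulate_readdepth(g, p))
  v <- dosage_values(d, "45K")
  expect_equal(mean(v), 4, tolerance = 0.01)
})

test_that("population sampling reproduces expected diploid copy counts", {
  p <- fx_params()
  s <- sample_population(list(POP = c(H2 = 1)), 20, p)
  expect_true(all(s$hap1 == "H2" & s$hap2 == "H2"))
  expect_true(all(s$count45 == 4))

  freqs <- list(POP = c(H1 = 0.2, H2 = 0.5, H7 = 0.3))
  s2 <- sample_population(freqs, 4000, p)
  expected <- 2 * sum(freqs$POP * c(3, 2, 1))
  expect_equal(mean(s2$count45), expected, tolerance = 0.02)

  expect_equal(nrow(sample_population(list(POP = c(H2 = 1)), 0, p)), 0L)
  expect_error(sample_population(list(POP = c(H2 = 0.9)), 5, p), "sum to 1")
})
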