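# Paralog detection, pairwise identity, identity profiles, motif scanning.

test_that("detect_paralogs recovers planted duplications with small boundary error", {
  # 260 kb background with a direct 18 kb pair and an inverted 15 kb pair
  set.seed(7)
  bases <- c("A", "C", "G", "T")
  bg <- sample(bases, 260000, replace = TRUE)
  dup <- sample(bases, 18000, replace = TRUE)
  inv <- sample(bases, 15000, replace = TRUE)
  mut <- function(x, d = 0.005) {
    i <- which(runif(length(x)) < d)
    x[i] <- sample(bases, length(i), replace = TRUE)
    x
  }
  bg[20001:38000] <- mut(dup)
  bg[120001:138000] <- mut(dup)
  bg[160001:175000] <- mut(inv)
  bg[220001:235000] <- rev(chartr("ACGT", "TGCA", mut(inv)))
  seq <- paste(bg, collapse = "")

  det <- detect_paralogs(seq)
  expect_equal(nrow(det$pairs), 2L)
  fwd <- det$pairs[det$pairs$orientation == "+", ]
  rev_ <- det$pairs[det$pairs$orientation == "-", ]
  k <- 31
  expect_lte(abs(fwd$a_start - 20000), k)
  expect_lte(abs(fwd$a_end - 38000), k)
  expect_lte(abs(fwd$b_start - 120000), k)
  expect_lte(abs(rev_$a_start - 160000), k)
  expect_lte(abs(rev_$b_end - 235000), k)
  expect_true(all(det$pairs$identity > 0.98))
  expect_equal(sort(unique(det$blocks$family_size)), 2L)
})

test_that("detect_paralogs finds nothing in i.i.d. random sequence", {
  seq <- random_dna(500000, seed = 11)
  det <- detect_paralogs(seq)
  expect_equal(nrow(det$pairs), 0L)
})

test_that("pairwise identity is symmetric and handles orientation", {
  a <- random_dna(2000, seed = 1)
  expect_equal(pairwise_identity(a, a)$identity, 1.0)
  expect_equal(pairwise_identity(a, a)$identity_gapped, 1.0)

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(a)))
  expect_equal(pairwise_identity(a, rc, orientation = "-")$identity, 1.0)

  # planted substitutions at rate delta on both copies: identity in the
  # binomial interval around 1 - 2*delta
  set.seed(3)
  mut <- function(s, d) {
    x <- strsplit(s, "")[[1]]
    i <- which(runif(length(x)) < d)
    x[i] <- sample(c("A", "C", "G", "T"), length(i), replace = TRUE)
    paste(x, collapse = "")
  }
  b1 <- mut(a, 0.0025); b2 <- mut(a, 0.0025)
  pid <- pairwise_identity(b1, b2)
  expect_gte(pid$identity, 0.994)
  expect_lte(pid$identity, 0.9995)
  # symmetry
  expect_equal(pid$identity, pairwise_identity(b2, b1)$identity)
  expect_error(pairwise_identity("", a), "empty")
})

test_that("identity profile counts mismatches per 100-bp window", {
  a <- random_dna(1000, seed = 5)
  expect_equal(identity_profile(a, a), rep(1, 10))
  # one mismatch in the third window
  b <- a
  substr(b, 250, 250) <- if (substr(a, 250, 250) == "A") "C" else "A"
  prof <- identity_profile(a, b)
  expect_equal(prof[3], 0.99)
  expect_equal(prof[-3], rep(1, 9))
  expect_equal(length(identity_profile(a, b, window = 300)), 3L)
  expect_error(identity_profile(substr(a, 1, 50), substr(a, 1, 50)),
               "shorter")
})

test_that("motif scan applies the one-informative-mismatch rule", {
  bg <- random_dna(300, seed = 9)
  plant <- function(instance) paste0(substr(bg, 1, 100), instance,
                                     substr(bg, 101, 300))
  exact <- scan_prdm9(plant("CCACCATAACCAC"))
  expect_equal(nrow(exact), 1L)
  expect_equal(exact$position, 100L)
  expect_equal(exact$strand, "+")
  expect_equal(exact$score_fraction, 1.0)

  one_mm <- scan_prdm9(plant("CCACCATAACCAG"))  # position 13 C->G
  expect_equal(one_mm$score_fraction, 7 / 8)

  two_mm <- scan_prdm9(plant("CCACCAAAACCAG"))  # positions 7 and 13
  expect_equal(nrow(two_mm), 0L)
})

test_that("motif hits are strand-symmetric under reverse complement", {
  seq <- paste0(random_dna(150, seed = 13), "CCACCATAACCAC",
                random_dna(80, seed = 14), "GTGGTTATGGTGG",
                random_dna(150, seed = 15))
  fwd <- scan_prdm9(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  bwd <- scan_prdm9(rc)
  expect_equal(nrow(fwd), nrow(bwd))
  expect_equal(sort(table(fwd$strand)),
               sort(table(bwd$strand)))
  # positions map through L - 13 - pos
  L <- nchar(seq)
  expect_equal(sort(L - 13 - bwd$position), sort(fwd$position))
})
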