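# Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

fx_arch <- function() {
  if (is.null(.fixtures$arch))
    .fixtures$arch <- build_reference_architecture()
  .fixtures$arch
}

fx_params <- function() sim_params(seed = 42L)

# synthetic H1 reference sequence under the fixture seed
fx_h1_seq <- function() {
  if (is.null(.fixtures$h1_seq))
    .fixtures$h1_seq <- synth_haplotype_sequence(
      fx_arch(), make_haplotype("H1", fx_arch()), fx_params())
  .fixtures$h1_seq
}

# in-silico candidate digests of H1..H7 under the fixture seed
fx_candidates <- function() {
  if (is.null(.fixtures$cands))
    .fixtures$cands <- candidate_rmaps(fx_arch(), fx_params())
  .fixtures$cands
}

# brute-force minimum-cost Rmap alignment by exhaustive enumeration of all
# block decompositions (independent oracle for the DP aligner)
brute_force_rmap_cost <- function(q, r, sigma_rel = 0.05, c_cut = 3.0,
                                  delta = 3L) {
  block_cost <- function(sq, sr) {
    sd <- sigma_rel * sr
    if (sd <= 0) return(if (sq == sr) 0 else Inf)
    (sq - sr)^2 / (2 * sd^2)
  }
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    if (i == 0 || j == 0) return(Inf)
    best <- Inf
    for (a in 1:min(delta, i)) for (b in 1:min(delta, j)) {
      sq <- sum(q[(i - a + 1):i]); sr <- sum(r[(j - b + 1):j])
      cost <- rec(i - a, j - b) + block_cost(sq, sr) + c_cut * (a - 1 + b - 1)
      if (cost < best) best <- cost
    }
    best
  }
  rec(length(q), length(r))
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
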