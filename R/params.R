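#' Simulation parameters
#'
#' Bundles every knob of the synthetic-data generators. Each generator is a
#' pure function of its inputs and `seed`: calling it twice with the same
#' parameters yields identical output, and the ambient RNG state is left
#' untouched.
#'
#' @param seed Integer master seed; fixes every downstream draw.
#' @param paralog_divergence Per-base substitution rate applied independently
#'   to each LCR copy relative to its family master (default 0.0025, giving
#'   pairwise paralog identities of roughly 99.5-99.8%, the magnitude seen
#'   between real copies).
#' @param fosmid_insert_mean,fosmid_insert_sd Fosmid insert length model in
#'   bp (default 40,000 / 2,500; fosmid clones carry ~40 kb inserts).
#' @param rmap_cv Relative fragment-sizing error (coefficient of variation)
#'   of single-molecule restriction maps (default 0.05).
#' @param rmap_p_miss Probability that a true restriction cut is missed on a
#'   molecule, merging adjacent fragments (default 0.10).
#' @param rmap_false_rate False-cut rate per bp (default 1/500,000).
#' @param rmap_min_frag Minimum resolvable fragment in bp; smaller fragments
#'   are merged into a neighbour (default 800).
#' @param acgh_sigma Per-probe log2-ratio noise SD (default 0.10).
#' @param acgh_identity Per-probe hybridization attenuation factor in (0, 1]
#'   modelling cross-species sequence divergence (default 1 = same species).
#' @param readdepth_window Read-depth window size in bp (default 500).
#' @param readdepth_sigma Per-window copy-number noise SD (default 0.2).
#' @param swai_sites Optional integer vector of SwaI site positions planted
#'   in the reference frame; `NULL` uses a fixed default layout.
#' @param motif_positions Reference positions at which an exact PRDM9
#'   consensus motif instance is planted (default none).
#' @return An object of class `SimParams`.
#' @export
sim_params <- function(seed = 1L,
                       paralog_divergence = 0.0025,
                       fosmid_insert_mean = 40000,
                       fosmid_insert_sd = 2500,
                       rmap_cv = 0.05,
                       rmap_p_miss = 0.10,
                       rmap_false_rate = 1 / 500000,
                       rmap_min_frag = 800,
                       acgh_sigma = 0.10,
                       acgh_identity = 1.0,
                       readdepth_window = 500L,
                       readdepth_sigma = 0.2,
                       swai_sites = NULL,
                       motif_positions = integer(0)) {
  rates <- c(paralog_divergence = paralog_divergence, rmap_cv = rmap_cv,
             rmap_p_miss = rmap_p_miss, rmap_false_rate = rmap_false_rate)
  bad <- rates < 0 | rates > 1
  if (any(bad))
    stop("rates must lie in [0, 1]: ", paste(names(rates)[bad], collapse = ", "))
  if (acgh_identity <= 0 || acgh_identity > 1)
    stop("acgh_identity must lie in (0, 1]")
  if (readdepth_window < 100) stop("readdepth_window must be >= 100 bp")
  structure(
    list(seed = as.integer(seed),
         paralog_divergence = paralog_divergence,
         fosmid_insert_mean = fosmid_insert_mean,
         fosmid_insert_sd = fosmid_insert_sd,
         rmap_cv = rmap_cv, rmap_p_miss = rmap_p_miss,
         rmap_false_rate = rmap_false_rate, rmap_min_frag = rmap_min_frag,
         acgh_sigma = acgh_sigma, acgh_identity = acgh_identity,
         readdepth_window = as.integer(readdepth_window),
         readdepth_sigma = readdepth_sigma,
         swai_sites = swai_sites,
         motif_positions = as.integer(motif_positions)),
    class = "SimParams"
  )
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Per-generator seed streams derived from the master seed (kept < 2^31).
.stream_seed <- function(p, stream) {
  offs <- c(sequence = 0L, fosmid = 101L, rmap = 202L, acgh = 303L,
            readdepth = 404L, population = 505L)
  (p$seed + offs[[stream]]) %% .Machine$integer.max
}
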