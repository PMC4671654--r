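# Restriction maps (Rmaps): in-silico digestion, error-model alignment, and
# SV-haplotype calling by model selection.

#' Construct an Rmap
#'
#' An Rmap is the ordered list of restriction-fragment lengths (in kb) of a
#' single molecule, a consensus contig, or an in-silico digest.
#'
#' @param fragments_kb Numeric vector of ordered fragment lengths in kb.
#' @param map_id Identifier.
#' @param enzyme Recognition sequence (default SwaI, ATTTAAAT).
#' @return An object of class `Rmap`.
#' @export
new_rmap <- function(fragments_kb, map_id = "map", enzyme = "ATTTAAAT") {
  stopifnot(is.numeric(fragments_kb), length(fragments_kb) >= 1,
            all(fragments_kb > 0))
  structure(list(map_id = map_id, enzyme = enzyme,
                 fragments = as.numeric(fragments_kb)),
            class = "Rmap")
}

#' @export
print.Rmap <- function(x, ...) {
  cat(sprintf("Rmap %s (%s): %d fragments, %.1f kb total\n", x$map_id,
              x$enzyme, length(x$fragments), sum(x$fragments)))
  invisible(x)
}

#' In-silico restriction digest
#'
#' Cuts are placed at recognition-site starts; fragments are the intervals
#' between successive cuts plus the two flanks, reported in kb.
#'
#' @param seq A character sequence to scan, or `NULL` when `sites` is given.
#' @param sites Site start positions in bp (0-based, within `[0, length)`).
#' @param length Total sequence length in bp (required with `sites`).
#' @param enzyme Non-degenerate recognition sequence (default SwaI).
#' @param map_id Identifier for the resulting map.
#' @return An `Rmap`; a site-free sequence yields a single-fragment map.
#' @export
digest_insilico <- function(seq = NULL, sites = NULL, length = NULL,
                            enzyme = "ATTTAAAT", map_id = "insilico") {
  if (grepl("[^ACGT]", enzyme))
    stop("recognition sequence must be non-degenerate (A/C/G/T only)")
  if (!is.null(seq)) {
    length <- nchar(seq)
    hits <- gregexpr(enzyme, seq, fixed = TRUE)[[1]]
    sites <- if (hits[1] == -1L) numeric(0) else as.numeric(hits) - 1
  } else {
    if (is.null(sites) || is.null(length))
      stop("need either `seq` or both `sites` and `length`")
    sites <- sort(as.numeric(sites))
  }
  frags <- diff(c(0, sites, length)) / 1000
  frags <- frags[frags > 0]
  new_rmap(frags, map_id = map_id, enzyme = enzyme)
}

#' Merge fragments below the resolution limit
#'
#' Optical mapping cannot resolve very small fragments (they desorb);
#' fragments below `min_kb` are merged into their left neighbour (right
#' neighbour for a leading fragment).
#'
#' @param rmap An `Rmap`.
#' @param min_kb Minimum fragment size in kb.
#' @return An `Rmap`.
#' @export
merge_small_fragments <- function(rmap, min_kb) {
  f <- rmap$fragments
  repeat {
    i <- which(f < min_kb)
    if (length(i) == 0L || length(f) == 1L) break
    i <- i[1]
    if (i > 1L) {
      f[i - 1L] <- f[i - 1L] + f[i]
    } else {
      f[2L] <- f[2L] + f[1L]
    }
    f <- f[-i]
  }
  rmap$fragments <- f
  rmap
}

#' Align two Rmaps under a sizing/cut error model
#'
#' Global dynamic programming over block pairings: each block aligns a run
#' of `a` query fragments to a run of `b` reference fragments
#' (`a, b <= delta`), with cost
#' `(Sq - Sr)^2 / (2 (sigma_rel * Sr)^2) + c_cut * (a - 1 + b - 1)`.
#' Runs with `b > 1` model cuts missed in the query; `a > 1` models false
#' cuts.
#'
#' @param query,ref `Rmap` objects (or bare numeric fragment vectors in kb).
#' @param sigma_rel Relative sizing error (default 0.05).
#' @param c_cut Penalty per extra cut difference (default 3.0).
#' @param delta Maximum fragments per run (default 3).
#' @return An object of class `RmapAlignment`: `cost`, `blocks` (query/ref
#'   fragment index runs), `cuts_missed`, `cuts_false`.
#' @export
align_rmap <- function(query, ref, sigma_rel = 0.05, c_cut = 3.0, delta = 3L) {
  q <- if (inherits(query, "Rmap")) query$fragments else as.numeric(query)
  r <- if (inherits(ref, "Rmap")) ref$fragments else as.numeric(ref)
  if (length(q) == 0L || length(r) == 0L) stop("maps must be non-empty")
  res <- .rmap_align_cpp(q, r, sigma_rel, c_cut, as.integer(delta))
  blocks <- data.frame(q_start = res$q_start, q_end = res$q_end,
                       r_start = res$r_start, r_end = res$r_end)
  structure(
    list(cost = res$cost, blocks = blocks,
         cuts_missed = sum(blocks$r_end - blocks$r_start),
         cuts_false = sum(blocks$q_end - blocks$q_start)),
    class = "RmapAlignment"
  )
}

#' @export
print.RmapAlignment <- function(x, ...) {
  cat(sprintf("RmapAlignment: cost %.3f, %d blocks, %d missed / %d false cuts\n",
              x$cost, nrow(x$blocks), x$cuts_missed, x$cuts_false))
  invisible(x)
}

#' Consensus Rmap from molecules of common origin
#'
#' Molecules pre-clustered by origin are summarized by their medoid (the
#' molecule with minimal total alignment cost to the others); fragment sizes
#' of the medoid are then refined by averaging the sizes of 1:1-aligned
#' query fragments across all molecules.
#'
#' @param maps List of `Rmap` objects from one origin.
#' @param sigma_rel,c_cut,delta Alignment parameters, see [align_rmap()].
#' @return An `Rmap` consensus.
#' @export
consensus_rmap <- function(maps, sigma_rel = 0.05, c_cut = 3.0, delta = 3L) {
  stopifnot(length(maps) >= 1L)
  if (length(maps) == 1L) return(maps[[1]])
  k <- length(maps)
  total <- numeric(k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      a <- align_rmap(maps[[j]], maps[[i]], sigma_rel, c_cut, delta)
      total[i] <- total[i] + if (is.finite(a$cost)) a$cost else 1e6
    }
  }
  medoid <- maps[[which.min(total)]]
  nf <- length(medoid$fragments)
  sizes <- vector("list", nf)
  for (mp in maps) {
    al <- align_rmap(mp, medoid, sigma_rel, c_cut, delta)
    if (!is.finite(al$cost)) next
    one2one <- al$blocks$q_start == al$blocks$q_end &
      al$blocks$r_start == al$blocks$r_end
    for (b in which(one2one)) {
      j <- al$blocks$r_start[b]
      sizes[[j]] <- c(sizes[[j]], mp$fragments[al$blocks$q_start[b]])
    }
  }
  frags <- medoid$fragments
  for (j in seq_len(nf)) if (length(sizes[[j]]) > 0) frags[j] <- mean(sizes[[j]])
  new_rmap(frags, map_id = paste0("consensus_", medoid$map_id),
           enzyme = medoid$enzyme)
}

#' Candidate Rmaps for the seven SV haplotypes
#'
#' In-silico digests of the synthetic sequences of H1..H7 under one
#' architecture and parameter set, for use as model-selection candidates.
#'
#' @param arch A `LocusArchitecture`.
#' @param p A `SimParams` (fixes the planted site layout).
#' @param labels Haplotype labels (default H1..H7).
#' @return Named list of `Rmap` objects.
#' @export
candidate_rmaps <- function(arch, p = sim_params(),
                            labels = paste0("H", 1:7)) {
  out <- lapply(labels, function(l) {
    hseq <- synth_haplotype_sequence(arch, make_haplotype(l, arch), p)
    digest_insilico(hseq, map_id = l)
  })
  names(out) <- labels
  out
}

#' Call SV haplotypes from consensus Rmaps by model selection
#'
#' Each consensus map is assigned the candidate haplotype whose in-silico
#' Rmap aligns with minimal cost; a call is flagged ambiguous when the
#' runner-up candidate lies within `margin` of the best cost. The union of
#' distinct unambiguous labels across consensus maps is the allele-type set
#' (more than two labels indicates mosaicism).
#'
#' @param consensus_maps List of `Rmap` consensus maps (one per allele).
#' @param candidates Named list of candidate `Rmap`s, as from
#'   [candidate_rmaps()].
#' @param sigma_rel,c_cut,delta Alignment parameters.
#' @param margin Ambiguity margin on alignment cost (default 5).
#' @return List with `calls` (data.frame: map_id, best, cost, runner_up,
#'   margin, ambiguous), `allele_types` (character), and `unresolved` flag
#'   (TRUE when every consensus map is ambiguous).
#' @export
call_haplotype_rmap <- function(consensus_maps, candidates,
                                sigma_rel = 0.05, c_cut = 3.0, delta = 3L,
                                margin = 5.0) {
  if (inherits(consensus_maps, "Rmap")) consensus_maps <- list(consensus_maps)
  stopifnot(length(candidates) >= 2L, !is.null(names(candidates)))
  rows <- lapply(consensus_maps, function(cm) {
    costs <- vapply(candidates, function(cand)
      align_rmap(cm, cand, sigma_rel, c_cut, delta)$cost, numeric(1))
    ord <- order(costs)
    best <- names(candidates)[ord[1]]
    runner <- names(candidates)[ord[2]]
    gap <- costs[ord[2]] - costs[ord[1]]
    data.frame(map_id = cm$map_id, best = best, cost = costs[ord[1]],
               runner_up = runner, margin = gap,
               ambiguous = !is.finite(costs[ord[1]]) | gap < margin,
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  allele_types <- sort(unique(calls$best[!calls$ambiguous]))
  list(calls = calls, allele_types = allele_types,
       unresolved = all(calls$ambiguous))
}
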