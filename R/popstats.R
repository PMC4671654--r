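# Population copy-number distributions and the two comparison tests
# (Kruskal-Wallis across populations, Welch t between species), implemented
# from their defining formulas.

#' Per-population frequency table of diploid 45 kb LCR copy number
#'
#' @param samples `data.frame` as from [sample_population()] (columns
#'   `population`, `count45`).
#' @return `data.frame` with one row per population (plus an `all` aggregate
#'   row) and one column per observed copy-number class; frequencies sum to
#'   1 within each row.
#' @export
cn_distribution <- function(samples) {
  stopifnot(nrow(samples) >= 1,
            all(c("population", "count45") %in% names(samples)))
  cls <- sort(unique(samples$count45))
  pops <- c(split(samples$count45, samples$population),
            list(all = samples$count45))
  freq <- t(vapply(pops, function(v)
    as.numeric(table(factor(v, levels = cls))) / length(v),
    numeric(length(cls))))
  out <- data.frame(population = names(pops), freq,
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[-1] <- paste0("CN", cls)
  out
}

#' Kruskal-Wallis rank-sum test
#'
#' H statistic with tie correction and a chi-square approximation for the
#' p-value; for total sample sizes up to `exact_n_max` an exact p-value by
#' complete enumeration of group assignments is also computed.
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @param exact_n_max Enumerate exactly when total n is at most this
#'   (default 10).
#' @return A `StatResult` list: `statistic`, `df`, `p_value`, `method`, and
#'   `p_exact` (NA when not enumerated).
#' @export
kruskal_wallis <- function(groups, exact_n_max = 10L) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  if (any(lengths(groups) == 0L)) stop("each group must be non-empty")
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  H_of <- function(gidx) {
    r <- rank(x)
    Rbar <- tapply(r, gidx, mean)
    ni <- tabulate(gidx, nbins = length(groups))
    H <- 12 / (N * (N + 1)) * sum(ni * (Rbar - (N + 1) / 2)^2)
    ties <- table(x)
    C <- 1 - sum(ties^3 - ties) / (N^3 - N)
    if (C > 0) H / C else 0
  }
  H <- H_of(g)
  df <- length(groups) - 1L
  p_chisq <- stats::pchisq(H, df, lower.tail = FALSE)
  p_exact <- NA_real_
  if (N <= exact_n_max) {
    perms <- .group_assignments(lengths(groups))
    Hs <- vapply(perms, H_of, numeric(1))
    p_exact <- mean(Hs >= H - 1e-12)
  }
  structure(list(statistic = H, df = df, p_value = p_chisq,
                 p_exact = p_exact, method = "Kruskal-Wallis rank sum test"),
            class = "StatResult")
}

# all distinct assignments of N items into groups of the given sizes,
# returned as group-index vectors
.group_assignments <- function(sizes) {
  N <- sum(sizes)
  out <- list()
  recurse <- function(remaining, gidx) {
    k <- length(sizes) - length(remaining) + 1L
    if (length(remaining) == 1L) {
      gidx[is.na(gidx)] <- k
      out[[length(out) + 1L]] <<- gidx
      return(invisible())
    }
    free <- which(is.na(gidx))
    for (pick in utils::combn(free, remaining[1], simplify = FALSE)) {
      g2 <- gidx
      g2[pick] <- k
      recurse(remaining[-1], g2)
    }
  }
  recurse(sizes, rep(NA_integer_, N))
  out
}

#' Welch two-sample t-test
#'
#' `t = (mean(a) - mean(b)) / sqrt(var(a)/n_a + var(b)/n_b)` with the
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param a,b Numeric vectors, each with >= 2 values; at least one with
#'   nonzero variance.
#' @return A `StatResult` list: `statistic`, `df`, `p_value`, `method`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs >= 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("zero variance in both groups")
  na <- length(a); nb <- length(b)
  se2a <- va / na; se2b <- vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 / (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  structure(list(statistic = t, df = df, p_value = p,
                 method = "Welch Two Sample t-test"),
            class = "StatResult")
}

#' @export
print.StatResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g\n", x$method,
              x$statistic, paste(signif(x$df, 4), collapse = ","), x$p_value))
  if (!is.null(x$p_exact) && !is.na(x$p_exact))
    cat(sprintf("  exact (permutation) p = %.4g\n", x$p_exact))
  invisible(x)
}
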