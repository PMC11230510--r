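#' Exact piecewise-constant fitting by penalized least squares
#'
#' Segments an ordered numeric series into constant-mean pieces by exact
#' dynamic programming. The objective is
#' \deqn{\sum_{s} \sum_{i \in s} (y_i - \bar y_s)^2 + \gamma\,(K - 1)}
#' where the sum runs over segments \eqn{s}, \eqn{\bar y_s} is the segment
#' mean, \eqn{K} the number of segments and \eqn{\gamma \ge 0} the penalty
#' per additional segment. The returned segmentation is the global minimizer
#' among all segmentations whose every segment has length at least `kmin`.
#' Ties are broken toward fewer segments, then toward the earliest
#' breakpoints.
#'
#' This is the exact O(n^2) counterpart of the fast heuristic PCF used by
#' copy-number segmentation tools; per-chromosome inter-mutation series are
#' short enough that exactness is affordable and makes the caller testable
#' against exhaustive enumeration.
#'
#' @param x Numeric vector, finite values, `length(x) >= kmin`.
#' @param gamma Non-negative penalty per additional segment.
#' @param kmin Minimum segment length (default 1).
#' @return A list of class `"pcf_segmentation"` with elements
#'   `starts` (first index of each segment), `lengths`, `means`,
#'   `cost` (the penalized objective) and `gamma`.
#' @examples
#' exact_pcf(c(0, 0, 0, 10, 10, 10), gamma = 1, kmin = 2)
#' @export
exact_pcf <- function(x, gamma, kmin = 1L) {
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x)))
    stop("`x` must be a non-empty numeric vector of finite values")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0)
    stop("`gamma` must be a single non-negative number")
  kmin <- as.integer(kmin)
  if (kmin < 1L) stop("`kmin` must be >= 1")
  n <- length(x)
  if (n < kmin) stop("series shorter than `kmin` (", n, " < ", kmin, ")")

  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  # F[e+1]: optimal cost of x[1..e]; prev[e+1]: end index of previous segment
  F <- rep(Inf, n + 1L)
  nseg <- rep(NA_integer_, n + 1L)
  prev <- rep(NA_integer_, n + 1L)
  F[1L] <- 0
  nseg[1L] <- 0L
  eps <- 1e-9
  for (j in seq_len(n)) {
    # previous segment ends e: e = 0 or e in [kmin, j - kmin]
    ends <- c(0L, seq_len(max(0L, j - kmin)))
    ends <- ends[ends == 0L | ends >= kmin]
    ends <- ends[j - ends >= kmin]
    if (j < kmin || length(ends) == 0L) next
    len <- j - ends
    sse <- (cs2[j + 1L] - cs2[ends + 1L]) - (cs[j + 1L] - cs[ends + 1L])^2 / len
    cost <- F[ends + 1L] + sse + gamma * (ends > 0L)
    # tie-break: min cost, then fewer segments, then earliest final breakpoint
    tol <- eps * max(1, abs(min(cost)))
    cand <- which(cost <= min(cost) + tol)
    if (length(cand) > 1L) {
      ns <- nseg[ends[cand] + 1L]
      cand <- cand[ns == min(ns)]
      cand <- cand[which.min(ends[cand])]
    }
    k <- cand[1L]
    F[j + 1L] <- cost[k]
    prev[j + 1L] <- ends[k]
    nseg[j + 1L] <- nseg[ends[k] + 1L] + 1L
  }
  if (!is.finite(F[n + 1L]))
    stop("no feasible segmentation: length ", n, " with kmin ", kmin)

  # backtrack
  starts <- integer(0)
  e <- n
  while (e > 0L) {
    s <- prev[e + 1L] + 1L
    starts <- c(s, starts)
    e <- prev[e + 1L]
  }
  lengths <- diff(c(starts, n + 1L))
  means <- vapply(seq_along(starts), function(i) {
    mean(x[starts[i]:(starts[i] + lengths[i] - 1L)])
  }, numeric(1))
  structure(
    list(starts = starts, lengths = lengths, means = means,
         cost = F[n + 1L], gamma = gamma),
    class = "pcf_segmentation"
  )
}

#' @export
print.pcf_segmentation <- function(x, ...) {
  cat("PCF segmentation:", length(x$starts), "segment(s), gamma =", x$gamma,
      ", cost =", format(x$cost), "\n")
  print(data.frame(start = x$starts, length = x$lengths, mean = x$means))
  invisible(x)
}

#' PCF-adjusted inter-mutation distances
#'
#' Computes the base-pair gaps between consecutive positions on one
#' chromosome, segments the log10 gaps with [exact_pcf()], and returns for
#' each gap the back-transformed segment mean `10^mean`. Smoothing the raw
#' inter-mutation distances this way suppresses single spuriously small or
#' large gaps so that the kataegis distance threshold is applied to the
#' local mutation density rather than to individual gaps.
#'
#' When there are fewer gaps than `kmin` the whole series forms one segment
#' (a single gap is returned unchanged).
#'
#' @param positions Strictly increasing 1-based positions on one chromosome
#'   (at least 2).
#' @param gamma Segmentation penalty on the log10 scale (default 25).
#' @param kmin Minimum segment length in gaps (default 2).
#' @return Numeric vector of length `length(positions) - 1`: the adjusted
#'   distance for each inter-mutation gap.
#' @examples
#' pcf_adjusted_imd(c(100, 200, 300))
#' @export
pcf_adjusted_imd <- function(positions, gamma = 25, kmin = 2L) {
  if (length(positions) < 2L) stop("need at least 2 positions")
  d <- diff(as.numeric(positions))
  if (any(d == 0)) stop("duplicate positions: de-duplicate upstream")
  if (any(d < 0)) stop("positions must be strictly increasing")
  y <- log10(d)
  seg <- exact_pcf(y, gamma = gamma, kmin = min(as.integer(kmin), length(y)))
  10^rep(seg$means, seg$lengths)
}
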