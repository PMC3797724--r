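# Circular binary segmentation.
#
# Recursive maximal-statistic splitting on circularized partial sums: within
# a segment, every contiguous arc (i, j] is scored by the standardized
# difference between its mean and the mean of its complement; the best arc is
# kept when its permutation p-value is <= alpha, and recursion continues on
# the resulting pieces.  No "undo" step; ties in the maximal statistic are
# broken by the shortest, leftmost arc.  Permutations stop early once the
# exceedance count shows p > alpha (sequential stopping).

# Maximal arc statistic for each column of a matrix of series.
# Returns list(best = per-column max |Z|, i, j = arc bounds of column 1).
max_arc_stat <- function(X, min_width = 2L) {
  n <- nrow(X); B <- ncol(X)
  S0 <- rbind(0, apply(X, 2, cumsum))
  tot <- S0[n + 1L, ]
  best <- rep(-Inf, B)
  bi <- 0L; bj <- 0L
  ls <- seq.int(min_width, n - min_width)
  if (length(ls) == 0 || n < 2L * min_width) {
    return(list(best = rep(0, B), i = 0L, j = 0L))
  }
  for (l in ls) {
    M <- S0[(1L + l):(n + 1L), , drop = FALSE] -
      S0[1L:(n + 1L - l), , drop = FALSE]
    Z <- (M / l - sweep(-M, 2L, tot, "+") / (n - l)) /
      sqrt(1 / l + 1 / (n - l))
    A <- abs(Z)
    tA <- t(A)
    jj <- max.col(tA, ties.method = "first")
    vals <- tA[cbind(seq_len(B), jj)]
    upd <- vals > best
    if (upd[1L]) { bi <- jj[1L] - 1L; bj <- jj[1L] - 1L + l }
    best[upd] <- vals[upd]
  }
  list(best = best, i = bi, j = bj)
}

# Sequential permutation p-value for the observed maximal arc statistic.
# Returns TRUE when p <= alpha (split accepted).
arc_split_significant <- function(x, obs, alpha, n_perm, min_width = 2L,
                                  batch = 100L) {
  exceed <- 0L
  done <- 0L
  limit <- floor(alpha * n_perm)
  while (done < n_perm) {
    b <- min(batch, n_perm - done)
    P <- vapply(seq_len(b), function(k) sample(x), numeric(length(x)))
    st <- max_arc_stat(P, min_width)$best
    exceed <- exceed + sum(st >= obs)
    done <- done + b
    if (exceed > limit) return(FALSE)
  }
  # p = (1 + exceed) / (1 + n_perm) <= alpha
  (1 + exceed) / (1 + n_perm) <= alpha
}

#' Circular binary segmentation of an ordered numeric series
#'
#' @param x numeric series (e.g. windowed coverage log-ratios along one
#'   chromosome).  Non-finite values are masked before segmentation; reported
#'   breakpoints refer to positions in the original series.
#' @param alpha significance level for accepting a split (default 0.01).
#' @param n_perm permutations per tested split (default 1000).
#' @param min_width minimum arc width (default 2).
#' @return sorted integer vector of breakpoints; a breakpoint `b` means the
#'   series changes level between `x[b]` and `x[b+1]`.
#' @export
cbs_segment <- function(x, alpha = 0.01, n_perm = 1000, min_width = 2L) {
  keep <- which(is.finite(x))
  xf <- x[keep]
  n <- length(xf)
  if (n < 2) return(integer(0))
  bps <- integer(0)
  recurse <- function(lo, hi) {
    m <- hi - lo + 1L
    if (m < 2L * min_width) return()
    seg <- xf[lo:hi]
    if (sd(seg) == 0) return()
    st <- max_arc_stat(matrix(seg, ncol = 1), min_width)
    if (!is.finite(st$best[1]) || st$best[1] <= 0) return()
    if (!arc_split_significant(seg, st$best[1], alpha, n_perm, min_width)) {
      return()
    }
    local_bps <- setdiff(c(st$i, st$j), c(0L, m))
    if (length(local_bps) == 0) return()
    bps <<- c(bps, lo - 1L + local_bps)
    cuts <- c(0L, sort(local_bps), m)
    for (k in seq_len(length(cuts) - 1L)) {
      recurse(lo + cuts[k], lo - 1L + cuts[k + 1L])
    }
  }
  recurse(1L, n)
  sort(keep[bps])
}

# Single change-point refinement: position b in 1..(m-1) maximizing the
# standardized two-sample mean difference; returns the index after which the
# series changes (leftmost tie).  Used for base-resolution breakpoint
# sharpening where full CBS would be quadratic in the region size.
max_t_split <- function(x) {
  m <- length(x)
  if (m < 2) return(NA_integer_)
  S <- cumsum(x)
  b <- seq_len(m - 1)
  z <- abs((S[b] / b - (S[m] - S[b]) / (m - b)) / sqrt(1 / b + 1 / (m - b)))
  which.max(z)
}
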