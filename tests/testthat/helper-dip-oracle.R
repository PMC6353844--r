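# Independent linear-programming oracle for the dip statistic on tiny
# samples. The dip is min over unimodal CDFs G of sup |F_n - G|. For a
# fixed mode position, the feasible G (convex increasing left of the mode,
# concave right, a single atom allowed at the mode) within a band of
# half-width t around the ECDF form a linear feasibility system, so
# minimizing t is an LP (solved with boot::simplex). The overall dip is
# the minimum over all mode placements; the optimal fit is piecewise
# linear with its mode at a data point, so knot modes suffice.
#
# Variables: g_1..g_n (G at the data points), gL (left limit at a knot
# mode), t. All data values assumed distinct.

dip_lp_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  stopifnot(n >= 3, !anyDuplicated(x))
  nv <- n + 2L  # g_1..g_n, gL, t
  iG <- seq_len(n)
  iL <- n + 1L
  iT <- n + 2L
  Fhi <- seq_len(n) / n        # F at x_i
  Flo <- (seq_len(n) - 1) / n  # F just below x_i

  best <- Inf
  solve_one <- function(A1, b1, A2, b2) {
    obj <- numeric(nv); obj[iT] <- 1
    fit <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                         maxi = FALSE)
    if (fit$solved == 1) fit$value else Inf
  }
  row <- function(...) {
    r <- numeric(nv)
    ids <- list(...)
    for (p in ids) r[p[[1]]] <- r[p[[1]]] + p[[2]]
    r
  }

  # slope comparison rows: slope(a,b) <= slope(b,c) as a <=-inequality
  convex_row <- function(ia, ib, ic, va = ia, vb = ib, vc = ic) {
    da <- x[ib] - x[ia]; db <- x[ic] - x[ib]
    # (g_b - g_a)/da <= (g_c - g_b)/db  ->  (g_b - g_a) db - (g_c - g_b) da <= 0
    row(list(va, -db), list(vb, db + da), list(vc, -da))
  }

  for (mode_type in "knot") {
    ks <- seq_len(n)
    for (k in ks) {
      A1 <- NULL; b1 <- NULL  # A1 z <= b1
      A2 <- NULL; b2 <- NULL  # A2 z >= b2
      add1 <- function(r, b) { A1 <<- rbind(A1, r); b1 <<- c(b1, b) }
      add2 <- function(r, b) { A2 <<- rbind(A2, r); b2 <<- c(b2, b) }

      # left-limit index map: at a knot mode the atom sits at x_k
      leftval <- function(i) if (mode_type == "knot" && i == k) iL else i

      for (i in seq_len(n)) {
        add1(row(list(leftval(i), 1), list(iT, -1)), Flo[i])  # G(x_i-) <= Flo + t
        add2(row(list(i, 1), list(iT, 1)), Fhi[i])            # g_i >= Fhi - t
        add1(row(list(i, 1)), 1)                              # g_i <= 1
      }
      # monotonicity (atoms only at the mode)
      for (i in seq_len(n - 1)) {
        add1(row(list(i, 1), list(leftval(i + 1), -1)), 0)
      }
      if (mode_type == "knot") {
        if (k > 1) add1(row(list(k - 1, 1), list(iL, -1)), 0)
        add1(row(list(iL, 1), list(k, -1)), 0)  # gL <= g_k
      } else {
        add1(row(list(iL, 1)), 0)  # unused atom variable pinned at 0
      }

      if (mode_type == "knot") {
        # convex through (x_1..x_{k-1}, g) and (x_k, gL)
        if (k >= 3) {
          for (i in 2:(k - 1)) {
            vc <- if (i + 1 == k) iL else i + 1L
            add1(convex_row(i - 1, i, i + 1, i - 1, i, vc), 0)
          }
        }
        # concave over (x_k, g_k), (x_{k+1}..x_n)
        if (k <= n - 2) {
          for (i in (k + 1):(n - 1)) {
            add1(-convex_row(i - 1, i, i + 1), 0)
          }
        }
      } else {
        if (k >= 3) for (i in 2:(k - 1)) add1(convex_row(i - 1, i, i + 1), 0)
        if (k + 1 <= n - 2) for (i in (k + 2):(n - 1)) {
          add1(-convex_row(i - 1, i, i + 1), 0)
        }
      }
      best <- min(best, solve_one(A1, b1, A2, b2))
    }
  }
  best
}
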