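# Independent oracles, deliberately implemented without the package's
# C++ kernels.

# Brute-force 3D connected-component labelling by repeated neighbour
# dilation in plain R. Labels are renumbered by each component's minimum
# linear index so they are comparable with label_components().
oracle_label <- function(arr, connectivity = 26) {
  d <- dim(arr)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  lab <- array(0L, dim = d)
  nextlab <- 0L
  for (seed in which(arr)) {
    if (lab[seed] != 0L) next
    nextlab <- nextlab + 1L
    frontier <- seed
    lab[seed] <- nextlab
    while (length(frontier)) {
      co <- arrayInd(frontier, d)
      nbr <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
        cbind(co[, 1] + offs$dx[i], co[, 2] + offs$dy[i], co[, 3] + offs$dz[i])))
      ok <- nbr[, 1] >= 1 & nbr[, 1] <= d[1] & nbr[, 2] >= 1 & nbr[, 2] <= d[2] &
        nbr[, 3] >= 1 & nbr[, 3] <= d[3]
      nbr <- nbr[ok, , drop = FALSE]
      idx <- unique(nbr[, 1] + (nbr[, 2] - 1) * d[1] +
                      (nbr[, 3] - 1) * d[1] * d[2])
      idx <- idx[arr[idx] & lab[idx] == 0L]
      lab[idx] <- nextlab
      frontier <- idx
    }
  }
  lab
}

# Clopper-Pearson bounds by bisection on explicit binomial tail sums.
oracle_cp_ci <- function(k, n, conf = 0.95, tol = 1e-9) {
  alpha <- 1 - conf
  upper_tail <- function(p) sum(dbinom(k:n, n, p))   # P(X >= k)
  lower_tail <- function(p) sum(dbinom(0:k, n, p))   # P(X <= k)
  bisect <- function(f, target, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) < target) hi <- mid else lo <- mid
      if (abs(hi - lo) < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (k == 0) 0 else bisect(function(p) upper_tail(p), alpha / 2, 1, 0)
  upper <- if (k == n) 1 else bisect(function(p) lower_tail(p), alpha / 2, 0, 1)
  c(lower = lower, upper = upper)
}
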