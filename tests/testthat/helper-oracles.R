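# Brute-force oracles, independent of the package implementations.

# pairwise Cliff's delta
bf_delta <- function(ref, comp) {
  (sum(outer(comp, ref, ">")) - sum(outer(comp, ref, "<"))) /
    (length(ref) * length(comp))
}

# Mann-Whitney U counting reference wins, ties 1/2
bf_u <- function(ref, comp) {
  sum(outer(ref, comp, ">")) + 0.5 * sum(outer(ref, comp, "=="))
}

# AUC as the pair statistic P(pos > neg) + P(pos == neg)/2
bf_auc <- function(pos, neg) {
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# exact one-sided MW p by enumeration of all rank assignments
bf_mw_p_enum <- function(ref, comp) {
  n1 <- length(ref)
  vals <- c(ref, comp)
  stopifnot(!anyDuplicated(vals))
  u_obs <- bf_u(ref, comp)
  picks <- utils::combn(length(vals), n1)
  u_all <- apply(picks, 2L, function(ix) bf_u(vals[ix], vals[-ix]))
  mean(u_all <= u_obs)
}

# connected components of the detection-link graph via BFS
bf_group_components <- function(det, tol, max_gap) {
  n <- nrow(det)
  if (n == 0L) return(integer(0))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- sqrt((det$x[i] - det$x[j])^2 + (det$y[i] - det$y[j])^2)
      adj[i, j] <- d <= tol && abs(det$z[i] - det$z[j]) <= max_gap + 1L
    }
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# direct (double-loop) 3x3 valid correlation, for the focus-metric oracle
bf_conv3x3 <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr - 2L, nc - 2L)
  for (i in 2:(nr - 1L)) {
    for (j in 2:(nc - 1L)) {
      acc <- 0
      for (di in -1:1) for (dj in -1:1) {
        acc <- acc + k[di + 2L, dj + 2L] * m[i + di, j + dj]
      }
      out[i - 1L, j - 1L] <- acc
    }
  }
  out
}

# exact delta / AUC between two discrete count distributions given their pmfs
bf_planted_stats <- function(pmf_x, pmf_y) {
  # pmf vectors over support 0..(length-1); x = comparator, y = reference
  px <- outer(pmf_x, pmf_y)
  gt <- sum(px[lower.tri(px)])          # x > y (row index > col index)
  lt <- sum(px[upper.tri(px)])
  eq <- sum(diag(px))
  list(delta = gt - lt, auc = gt + eq / 2)
}

# small fast cohort configurations used across tests
small_sim <- function(n_slides = 3, seed = 11, ...) {
  sim_config(n_slides = n_slides, seed = seed,
             cellularity = list(meanlog = log(250), sdlog = 0.4), ...)
}
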