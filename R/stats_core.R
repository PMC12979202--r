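#' One-sided Mann-Whitney test (alternative: comparator > reference)
#'
#' The U statistic counts reference wins over all cross pairs, with ties
#' counted 1/2 (computed from midranks). The one-sided p-value for the
#' pre-specified alternative "comparator stochastically greater" is the
#' lower tail of U. The exact null distribution is used when
#' `n_ref * n_comp <= 400` and there are no ties; otherwise a tie-corrected
#' normal approximation with continuity correction.
#'
#' @param ref Reference sample (numeric, non-empty).
#' @param comp Comparator sample (numeric, non-empty).
#' @return List of class `"group_comparison"`: `U` (reference wins),
#'   `n_ref`, `n_comp`, `p`, `delta` (Cliff's delta, positive when the
#'   comparator tends larger), `method`.
#' @export
#' @examples
#' mann_whitney_one_sided(c(1, 2, 3), c(4, 5, 6))$p  # exactly 1/20
mann_whitney_one_sided <- function(ref, comp) {
  if (!length(ref) || !length(comp)) stop("input error: empty sample")
  n1 <- length(ref); n2 <- length(comp)
  all_v <- c(ref, comp)
  r <- rank(all_v)
  u_ref <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # reference wins, ties 1/2
  ties <- table(all_v)
  has_ties <- any(ties > 1)
  if (n1 * n2 <= 400 && !has_ties) {
    p <- stats::pwilcox(u_ref, n1, n2)
    method <- "exact"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
    z <- (u_ref - mu + 0.5) / sigma  # continuity-corrected lower tail
    p <- stats::pnorm(z)
    method <- "normal_tie_corrected"
  }
  structure(list(
    U = u_ref, n_ref = n1, n_comp = n2,
    p = min(max(p, 0), 1),
    delta = 1 - 2 * u_ref / (n1 * n2),
    method = method
  ), class = "group_comparison")
}

#' Cliff's delta effect size
#'
#' delta = (#\{comp > ref\} - #\{comp < ref\}) / (n_ref * n_comp) over all
#' cross pairs: +1 for complete comparator dominance, 0 for stochastic
#' equality. Linearly related to the Mann-Whitney statistic
#' (delta = 1 - 2 U_ref / (n1 n2)) and to the ROC AUC (AUC = (delta+1)/2).
#'
#' @inheritParams mann_whitney_one_sided
#' @return Scalar in \[-1, 1\].
#' @export
#' @examples
#' cliffs_delta(c(1, 3, 5), c(2, 4, 6))  # 1/3
cliffs_delta <- function(ref, comp) {
  if (!length(ref) || !length(comp)) stop("input error: empty sample")
  n1 <- length(ref); n2 <- length(comp)
  r <- rank(c(ref, comp))
  u_ref <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  1 - 2 * u_ref / (n1 * n2)
}

#' Benjamini-Hochberg q-values within analysis families
#'
#' Step-up adjustment applied separately within each family (e.g. across
#' comparator categories for one metric in one figure).
#'
#' @param p Numeric p-values in \[0,1\].
#' @param family Optional grouping vector of the same length; adjustment is
#'   applied within each level.
#' @return Numeric q-values, `q >= p` elementwise, order-preserving.
#' @export
#' @examples
#' bh_adjust(c(0.005, 0.01, 0.03, 0.04))
bh_adjust <- function(p, family = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("input error: p-values must lie in [0, 1]")
  if (is.null(family)) return(stats::p.adjust(p, method = "BH"))
  stopifnot(length(family) == length(p))
  q <- p
  for (f in unique(family)) {
    sel <- which(family == f)
    q[sel] <- stats::p.adjust(p[sel], method = "BH")
  }
  q
}

#' Empirical ROC curve and AUC
#'
#' Threshold convention: a slide is predicted positive when
#' `score >= t`. The AUC equals the pair statistic
#' P(score_pos > score_neg) + 1/2 P(equal), i.e. ties count one half.
#'
#' @param scores Numeric slide scores.
#' @param labels `"positive"`/`"negative"` per slide (logical accepted,
#'   `TRUE` = positive).
#' @return List of class `"roc_result"`: `fpr`, `tpr` (step-curve vertices,
#'   beginning at (0,0)), `thresholds`, `auc`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' empirical_roc(c(3, 1, 2, 0), c("positive", "positive", "negative", "negative"))$auc
empirical_roc <- function(scores, labels) {
  pos <- as_positive(labels)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("undefined AUC: need at least one positive and one negative")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  last <- !duplicated(s, fromLast = TRUE)  # one vertex per distinct score
  tp <- cumsum(p)[last]; fp <- cumsum(!p)[last]
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(
    fpr = fpr, tpr = tpr, thresholds = c(Inf, s[last]),
    auc = auc, n_pos = n_pos, n_neg = n_neg
  ), class = "roc_result")
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  lv <- unique(as.character(labels))
  bad <- setdiff(lv, c("positive", "negative"))
  if (length(bad)) stop("labels must be 'positive'/'negative'; got '", bad[1], "'")
  as.character(labels) == "positive"
}

#' Interpolate a ROC curve onto an FPR grid
#'
#' Linear interpolation of TPR at the requested false-positive rates; at a
#' vertical segment of the step curve the upper envelope is taken.
#'
#' @param roc A `"roc_result"`.
#' @param grid Uniform FPR grid in \[0,1\].
#' @return Numeric TPR values at `grid`.
#' @export
roc_interp <- function(roc, grid = seq(0, 1, length.out = 1001)) {
  stats::approx(roc$fpr, roc$tpr, xout = grid, ties = max, rule = 2)$y
}

#' Stratified-bootstrap ROC confidence band
#'
#' Positives and negatives are resampled separately with replacement
#' (stratified, so every resample keeps both classes); each resample's
#' curve is linearly interpolated onto a uniform FPR grid and the band is
#' the pointwise percentile interval. An AUC percentile interval over the
#' same resamples is reported alongside.
#'
#' @inheritParams empirical_roc
#' @param n_resamples Number of bootstrap resamples (study default 2,000).
#' @param grid Uniform FPR grid (default 1,001 nodes on \[0,1\]).
#' @param seed RNG seed; the band is a pure function of
#'   (data, parameters, seed).
#' @param conf Confidence level (default 0.95, percentile interval).
#' @return List of class `"roc_band"`: `grid`, `tpr` (observed curve on the
#'   grid), `lower`, `upper`, `auc`, `auc_ci`, `n_resamples`, `conf`.
#' @export
bootstrap_roc_band <- function(scores, labels, n_resamples = 2000L,
                               grid = seq(0, 1, length.out = 1001),
                               seed = 1L, conf = 0.95) {
  if (n_resamples < 2) stop("n_resamples must be >= 2")
  pos <- as_positive(labels)
  sp <- scores[pos]; sn <- scores[!pos]
  roc <- empirical_roc(scores, labels)
  set.seed(seed)
  tpr_b <- matrix(NA_real_, n_resamples, length(grid))
  auc_b <- numeric(n_resamples)
  for (b in seq_len(n_resamples)) {
    bp <- sample(sp, replace = TRUE)
    bn <- sample(sn, replace = TRUE)
    rb <- empirical_roc(c(bp, bn), c(rep(TRUE, length(bp)), rep(FALSE, length(bn))))
    tpr_b[b, ] <- roc_interp(rb, grid)
    auc_b[b] <- rb$auc
  }
  a <- (1 - conf) / 2
  structure(list(
    grid = grid, tpr = roc_interp(roc, grid),
    lower = apply(tpr_b, 2L, stats::quantile, probs = a, names = FALSE),
    upper = apply(tpr_b, 2L, stats::quantile, probs = 1 - a, names = FALSE),
    auc = roc$auc,
    auc_ci = stats::quantile(auc_b, c(a, 1 - a), names = FALSE),
    n_resamples = n_resamples, conf = conf
  ), class = "roc_band")
}

#' Wilson score interval for a binomial proportion
#'
#' @param k Number of successes.
#' @param n Number of trials (> 0).
#' @param level Confidence level.
#' @return Numeric `c(lower, upper)`, contained in \[0,1\]; the lower bound
#'   is exactly 0 when `k = 0` and the upper exactly 1 when `k = n`.
#' @export
#' @examples
#' wilson_interval(8, 10)
wilson_interval <- function(k, n, level = 0.95) {
  if (n <= 0) stop("input error: n must be > 0")
  if (k < 0 || k > n) stop("input error: k must lie in [0, n]")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Human triage operating point with Wilson intervals
#'
#' Sensitivity and specificity of a binary triage call (e.g. "refer all
#' ASC-US or worse") against the reference labels, each with a 95% Wilson
#' interval.
#'
#' @param call Logical or `"positive"`/`"negative"` triage calls per slide.
#' @param labels Reference labels (`"positive"`/`"negative"` or logical).
#' @param level Confidence level for the Wilson intervals.
#' @return List of class `"operating_point"`: `sensitivity`, `specificity`,
#'   `sens_ci`, `spec_ci`, `n_pos`, `n_neg`.
#' @export
triage_operating_point <- function(call, labels, level = 0.95) {
  call <- as_positive(call)
  pos <- as_positive(labels)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("need both classes to define an operating point")
  tp <- sum(call & pos); tn <- sum(!call & !pos)
  structure(list(
    sensitivity = tp / n_pos, specificity = tn / n_neg,
    sens_ci = wilson_interval(tp, n_pos, level),
    spec_ci = wilson_interval(tn, n_neg, level),
    n_pos = n_pos, n_neg = n_neg
  ), class = "operating_point")
}

# FPR of the interpolated AI curve at a target TPR (inverse interpolation:
# smallest FPR reaching the target). Returns 1 with attribute
# "extrapolated" when the curve never reaches the target.
roc_inverse_fpr <- function(fpr_grid, tpr, target) {
  if (target > max(tpr)) {
    out <- 1
    attr(out, "extrapolated") <- TRUE
    return(out)
  }
  i <- which(tpr >= target)[1L]
  if (i == 1L || tpr[i] == target) return(fpr_grid[i])
  # linear inverse between grid nodes i-1 and i
  t0 <- tpr[i - 1L]; t1 <- tpr[i]
  f0 <- fpr_grid[i - 1L]; f1 <- fpr_grid[i]
  if (t1 == t0) return(f0)
  f0 + (target - t0) / (t1 - t0) * (f1 - f0)
}

#' Compare the AI score with a human triage rule at a matched operating point
#'
#' At matched specificity, reads the AI TPR off the grid-interpolated ROC
#' curve at the human FPR and tests Delta-TPR = TPR_AI - TPR_human; at
#' matched sensitivity, finds the AI FPR reaching the human sensitivity by
#' inverse interpolation and tests Delta-FPR = FPR_AI - FPR_human. Slides
#' are jointly resampled (stratified by reference label); by default both
#' the AI curve and the human point are re-estimated in every resample
#' (`refit_human = FALSE` keeps the human point fixed). The two-sided
#' p-value is 2 x the smaller tail probability of the bootstrap
#' Delta distribution around 0, capped at 1.
#'
#' @param scores AI slide scores.
#' @param labels Reference labels (`"positive"`/`"negative"` or logical).
#' @param human_call Human triage calls per slide (same length).
#' @param matching `"specificity"` or `"sensitivity"`.
#' @param n_resamples Bootstrap resamples (study default 2,000).
#' @param grid FPR grid for curve interpolation.
#' @param seed RNG seed.
#' @param refit_human Re-estimate the human point per resample (default).
#' @return List of class `"op_comparison"`: `delta` (point estimate), `p`,
#'   `matching`, `human` (an `"operating_point"`), `ai_tpr`/`ai_fpr` at the
#'   match, `extrapolated` flag, `deltas` (bootstrap draws).
#' @export
compare_at_matched_operating_point <- function(scores, labels, human_call,
                                               matching = c("specificity", "sensitivity"),
                                               n_resamples = 2000L,
                                               grid = seq(0, 1, length.out = 1001),
                                               seed = 1L, refit_human = TRUE) {
  matching <- match.arg(matching)
  pos <- as_positive(labels)
  call <- as_positive(human_call)
  human <- triage_operating_point(call, pos)
  if (human$sensitivity <= 0 || human$sensitivity >= 1 ||
      human$specificity <= 0 || human$specificity >= 1) {
    warning("human operating point lies on the boundary of (0,1)")
  }

  point_delta <- function(sc, lb, cl) {
    h <- triage_operating_point(cl, lb)
    tpr <- roc_interp(empirical_roc(sc, lb), grid)
    if (matching == "specificity") {
      ai_tpr <- stats::approx(grid, tpr, xout = 1 - h$specificity, rule = 2)$y
      list(delta = ai_tpr - h$sensitivity, at = ai_tpr, extrapolated = FALSE)
    } else {
      ai_fpr <- roc_inverse_fpr(grid, tpr, h$sensitivity)
      list(delta = as.numeric(ai_fpr) - (1 - h$specificity), at = as.numeric(ai_fpr),
           extrapolated = isTRUE(attr(ai_fpr, "extrapolated")))
    }
  }
  obs <- point_delta(scores, pos, call)
  if (obs$extrapolated) {
    warning("human sensitivity exceeds the AI curve's maximum; FPR taken as 1 (extrapolated)")
  }

  ip <- which(pos); ineg <- which(!pos)
  set.seed(seed)
  deltas <- numeric(n_resamples)
  for (b in seq_len(n_resamples)) {
    idx <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
    cl_b <- if (refit_human) call[idx] else call
    lb_b <- if (refit_human) pos[idx] else pos
    d <- if (refit_human) {
      point_delta(scores[idx], pos[idx], cl_b)$delta
    } else {
      # fixed human point: only the AI curve is resampled
      tpr <- roc_interp(empirical_roc(scores[idx], pos[idx]), grid)
      if (matching == "specificity") {
        stats::approx(grid, tpr, xout = 1 - human$specificity, rule = 2)$y -
          human$sensitivity
      } else {
        as.numeric(roc_inverse_fpr(grid, tpr, human$sensitivity)) -
          (1 - human$specificity)
      }
    }
    deltas[b] <- d
  }
  p <- min(1, 2 * min(mean(deltas <= 0), mean(deltas >= 0)))
  structure(list(
    delta = obs$delta, p = p, matching = matching, human = human,
    ai_at_match = obs$at, extrapolated = obs$extrapolated, deltas = deltas
  ), class = "op_comparison")
}

#' LOWESS trend with a bootstrap confidence band
#'
#' Locally weighted regression of `y` (optionally log-transformed) on `x`,
#' with a pointwise percentile band from bootstrap resampling of the
#' observations; the fit and band are back-transformed when `log_y = TRUE`.
#' Used for age trends of per-slide cell counts and composition fractions
#' (zero-count slides must be excluded upstream when `log_y = TRUE`).
#'
#' @param x Predictor (e.g. donor age); at least 10 points.
#' @param y Response (counts or fractions).
#' @param log_y Fit on `log(y)` (requires all `y > 0`).
#' @param frac LOWESS smoother span.
#' @param n_boot Bootstrap resamples (study default 100).
#' @param seed RNG seed.
#' @param conf Confidence level.
#' @return Tibble with `x` (sorted unique values), `fit`, `lower`, `upper`.
#' @export
lowess_trend <- function(x, y, log_y = FALSE, frac = 2 / 3,
                         n_boot = 100L, seed = 1L, conf = 0.95) {
  if (length(x) < 10) stop("input error: need at least 10 points")
  if (length(x) != length(y)) stop("input error: x and y lengths differ")
  if (log_y && any(y <= 0)) {
    stop("input error: log_y requires all y > 0 (exclude zero-count slides upstream)")
  }
  yy <- if (log_y) log(y) else y
  grid <- sort(unique(x))
  fit0 <- stats::lowess(x, yy, f = frac)
  fit <- stats::approx(fit0$x, fit0$y, xout = grid, rule = 2, ties = mean)$y
  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, length(grid))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(length(x), replace = TRUE)
    fb <- stats::lowess(x[idx], yy[idx], f = frac)
    boots[b, ] <- stats::approx(fb$x, fb$y, xout = grid, rule = 2, ties = mean)$y
  }
  a <- (1 - conf) / 2
  lower <- apply(boots, 2L, stats::quantile, probs = a, names = FALSE, na.rm = TRUE)
  upper <- apply(boots, 2L, stats::quantile, probs = 1 - a, names = FALSE, na.rm = TRUE)
  if (log_y) {
    fit <- exp(fit); lower <- exp(lower); upper <- exp(upper)
  }
  tibble::tibble(x = grid, fit = fit, lower = lower, upper = upper)
}

#' Tidy group-comparison table (one-sided MW + Cliff's delta + BH q)
#'
#' Runs [mann_whitney_one_sided()] (alternative: comparator > reference)
#' and [cliffs_delta()] for each stratum of `data`, then adjusts p-values
#' with [bh_adjust()] within each `family`.
#'
#' @param data Data frame.
#' @param value Name of the numeric response column.
#' @param group Name of the two-level grouping column.
#' @param ref_level,comp_level Reference and comparator levels of `group`.
#' @param strata Optional name of a stratifying column (one test per level).
#' @param family Optional name of the family column for BH adjustment
#'   (defaults to one family spanning all rows).
#' @return Tibble: `stratum`, `n_ref`, `n_comp`, `U`, `delta`, `p`, `q`.
#' @export
group_comparison_table <- function(data, value, group, ref_level, comp_level,
                                   strata = NULL, family = NULL) {
  strat <- if (is.null(strata)) rep("all", nrow(data)) else data[[strata]]
  rows <- list()
  for (s in unique(strat)) {
    d <- data[strat == s, , drop = FALSE]
    ref <- d[[value]][d[[group]] == ref_level]
    comp <- d[[value]][d[[group]] == comp_level]
    if (!length(ref) || !length(comp)) next
    mw <- mann_whitney_one_sided(ref, comp)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      stratum = as.character(s), n_ref = mw$n_ref, n_comp = mw$n_comp,
      U = mw$U, delta = mw$delta, p = mw$p,
      family = if (is.null(family)) "all" else as.character(d[[family]][1])
    )
  }
  if (!length(rows)) {
    return(tibble::tibble(stratum = character(), n_ref = integer(),
                          n_comp = integer(), U = numeric(), delta = numeric(),
                          p = numeric(), q = numeric()))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p, out$family)
  out$family <- NULL
  out
}
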