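#' Slide-level diagnostic endpoint specification
#'
#' An endpoint maps every Bethesda diagnosis (or the HPV result) to
#' positive, negative or excluded, and names the count-based score used as
#' the predictor:
#'
#' * `"LSIL+"` — low-grade or worse. Default: ASC-US excluded; negatives
#'   NILM; positives LSIL, ASC-H, HSIL, SCC. Default score is the LSIL+HSIL
#'   count sum; `score_rule = "lsil_only"` uses the LSIL count alone. With
#'   `all_samples = TRUE` nothing is excluded (ASC-US counts as negative).
#' * `"HSIL+"` — high-grade. Default: ASC-H excluded; negatives NILM,
#'   ASC-US, LSIL; positives HSIL, SCC; score is the HSIL count.
#' * `"HPV+"` — HPV positivity as the reference label (slides with missing
#'   HPV are excluded); score defaults to the LSIL+HSIL sum.
#'
#' @param name One of `"LSIL+"`, `"HSIL+"`, `"HPV+"`.
#' @param score_rule `"lsil_hsil_sum"`, `"lsil_only"` or `"hsil_only"`
#'   (default depends on `name`).
#' @param all_samples If `TRUE`, drop the default category exclusion and
#'   fold the excluded category into the negatives.
#' @return List of class `"endpoint_spec"` with `excluded`, `negative`,
#'   `positive` category sets and `score_rule`.
#' @export
#' @examples
#' endpoint_spec("LSIL+")
#' endpoint_spec("HSIL+")$positive
endpoint_spec <- function(name = c("LSIL+", "HSIL+", "HPV+"),
                          score_rule = NULL, all_samples = FALSE) {
  name <- match.arg(name)
  sets <- switch(name,
    "LSIL+" = list(
      excluded = "ASC-US", negative = "NILM",
      positive = c("LSIL", "ASC-H", "HSIL", "SCC"),
      score_rule = "lsil_hsil_sum"
    ),
    "HSIL+" = list(
      excluded = "ASC-H", negative = c("NILM", "ASC-US", "LSIL"),
      positive = c("HSIL", "SCC"),
      score_rule = "hsil_only"
    ),
    "HPV+" = list(
      excluded = character(0), negative = character(0),
      positive = character(0), score_rule = "lsil_hsil_sum"
    )
  )
  if (all_samples) {
    sets$negative <- c(sets$negative, sets$excluded)
    sets$excluded <- character(0)
  }
  if (!is.null(score_rule)) {
    score_rule <- match.arg(score_rule, c("lsil_hsil_sum", "lsil_only", "hsil_only"))
    sets$score_rule <- score_rule
  }
  structure(c(list(name = name), sets), class = "endpoint_spec")
}

#' Map a diagnosis to the endpoint label
#'
#' @param diagnosis Bethesda category (vectorised).
#' @param spec An [endpoint_spec()] (for `"HPV+"` pass the HPV result as
#'   `diagnosis`: `"positive"`/`"negative"`/`"missing"`).
#' @return Character vector over `{"positive", "negative", "excluded"}`.
#' @export
endpoint_label <- function(diagnosis, spec) {
  if (spec$name == "HPV+") {
    out <- ifelse(diagnosis == "positive", "positive",
           ifelse(diagnosis == "negative", "negative",
           ifelse(diagnosis == "missing", "excluded", NA)))
    if (anyNA(out)) {
      stop("specification error: unknown HPV value '",
           diagnosis[which(is.na(out))[1]], "'")
    }
    return(out)
  }
  out <- ifelse(diagnosis %in% spec$positive, "positive",
         ifelse(diagnosis %in% spec$negative, "negative",
         ifelse(diagnosis %in% spec$excluded, "excluded", NA)))
  if (anyNA(out)) {
    stop("specification error: category '", diagnosis[which(is.na(out))[1]],
         "' is in none of the endpoint's sets")
  }
  out
}

#' Slide score for an endpoint
#'
#' @param counts Named per-class count vector, or a slides table with
#'   `count_*` columns (then a vector of scores is returned).
#' @param spec An [endpoint_spec()], or a score-rule string.
#' @return Non-negative numeric score(s).
#' @export
#' @examples
#' slide_score(c(lsil = 7, hsil = 3), endpoint_spec("LSIL+"))
slide_score <- function(counts, spec = endpoint_spec("LSIL+")) {
  rule <- if (is.character(spec)) spec else spec$score_rule
  if (is.data.frame(counts)) {
    lsil <- counts$count_lsil
    hsil <- counts$count_hsil
  } else {
    lsil <- counts[["lsil"]]
    hsil <- counts[["hsil"]]
  }
  switch(rule,
    lsil_hsil_sum = lsil + hsil,
    lsil_only = lsil,
    hsil_only = hsil,
    stop("specification error: unknown score rule '", rule, "'")
  )
}

#' Positivity curves: fraction of slides above a count cutoff, by category
#'
#' For each Bethesda category and cutoff `c`, the fraction of that
#' category's slides whose count for `class` strictly exceeds `c`. Each
#' curve is non-increasing in the cutoff.
#'
#' @param slides Slides table with `diagnosis` and `count_*` columns.
#' @param class Lesion class name (e.g. `"lsil"`).
#' @param cutoffs Numeric vector of cutoffs.
#' @return Tibble with `diagnosis`, `cutoff`, `n`, `fraction_positive`
#'   (`NA` for empty categories).
#' @export
positivity_curve <- function(slides, class = "lsil",
                             cutoffs = c(0, 1, 2, 5, 10, 20, 50, 100, 200, 500)) {
  if (!length(cutoffs)) stop("`cutoffs` must be non-empty")
  col <- paste0("count_", class)
  cats <- bethesda_categories()
  out <- expand.grid(diagnosis = cats, cutoff = sort(cutoffs),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n <- NA_integer_
  out$fraction_positive <- NA_real_
  for (i in seq_len(nrow(out))) {
    sel <- slides$diagnosis == out$diagnosis[i]
    out$n[i] <- sum(sel)
    if (out$n[i] > 0) {
      out$fraction_positive[i] <- mean(slides[[col]][sel] > out$cutoff[i])
    }
  }
  tibble::as_tibble(out)
}

#' Sweep the per-cell probability threshold and track endpoint AUC
#'
#' Re-gates the cohort's cells with all lesion thresholds set to each grid
#' value, recomputes slide scores, and reports the endpoint AUC with a
#' stratified-bootstrap percentile confidence interval at every threshold.
#' The reported stability range (max - min AUC) quantifies robustness to the
#' threshold choice.
#'
#' @param cohort A `"cyto_cohort"` with cells.
#' @param spec An [endpoint_spec()].
#' @param grid Threshold grid, strictly increasing within (0,1). Default
#'   0.60 to 0.99 in steps of 0.01.
#' @param gate Base [gate_config()] supplying the non-lesion thresholds.
#' @param n_resamples Bootstrap resamples per threshold.
#' @param seed RNG seed for the bootstrap.
#' @return Tibble (`threshold`, `auc`, `ci_lo`, `ci_hi`, `n_pos`, `n_neg`)
#'   with attribute `auc_range = max - min` of the AUC column.
#' @export
threshold_sweep <- function(cohort, spec = endpoint_spec("LSIL+"),
                            grid = seq(0.60, 0.99, by = 0.01),
                            gate = gate_config(taxonomy = cohort$taxonomy),
                            n_resamples = 500L, seed = 1L) {
  if (any(grid <= 0) || any(grid >= 1)) stop("grid must lie within (0, 1)")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  lab <- endpoint_label(
    if (spec$name == "HPV+") cohort$slides$hpv else cohort$slides$diagnosis, spec)
  keep <- lab != "excluded"
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    t <- grid[i]
    g <- gate_config(
      taxonomy = gate$taxonomy, irrelevant = gate$irrelevant,
      leukocyte = gate$leukocyte,
      lesion = stats::setNames(rep(t, length(gate$lesion)), names(gate$lesion))
    )
    gated <- gate_cohort(cohort, g)
    score <- slide_score(gated$slides, spec)
    band <- bootstrap_roc_band(score[keep], lab[keep],
                               n_resamples = n_resamples,
                               seed = seed + i)
    rows[[i]] <- tibble::tibble(
      threshold = t, auc = band$auc,
      ci_lo = band$auc_ci[1], ci_hi = band$auc_ci[2],
      n_pos = sum(lab[keep] == "positive"), n_neg = sum(lab[keep] == "negative")
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "auc_range") <- max(out$auc) - min(out$auc)
  out
}
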