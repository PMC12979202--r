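#' Gate configuration for hierarchical cell labelling
#'
#' The labelling hierarchy mimics flow-cytometry gating: cells are first
#' removed as irrelevant objects (debris, defocused material), then as
#' leukocytes; remaining cells crossing a lesion gate (LSIL, HSIL,
#' adenocarcinoma) are labelled with that lesion class; everything else is
#' assigned by argmax over the normal epithelial classes.
#'
#' The lesion gates default to 0.80 (the per-cell probability threshold used
#' for positive classes); the irrelevant and leukocyte gates default to 0.5
#' and are configurable since they are reported only graphically.
#'
#' @param taxonomy Class taxonomy; both the 10- and 11-class variants are
#'   supported (navicular is a fallback/normal class).
#' @param irrelevant,leukocyte Gate thresholds in \[0,1\].
#' @param lesion Named thresholds for `lsil`, `hsil`, `adenocarcinoma`
#'   (classes absent from the taxonomy are ignored).
#' @return List of class `"gate_config"`.
#' @export
#' @examples
#' gate_config(lesion = c(lsil = 0.9, hsil = 0.9, adenocarcinoma = 0.9))
gate_config <- function(taxonomy = cyto_classes(11),
                        irrelevant = 0.5, leukocyte = 0.5,
                        lesion = c(lsil = 0.80, hsil = 0.80,
                                   adenocarcinoma = 0.80)) {
  lesion <- lesion[intersect(lesion_classes(), names(lesion))]
  lesion <- lesion[names(lesion) %in% taxonomy]
  thr <- c(irrelevant = irrelevant, leukocyte = leukocyte, lesion)
  if (any(thr < 0 | thr > 1)) stop("gate thresholds must lie in [0, 1]")
  structure(list(
    taxonomy = taxonomy,
    irrelevant = irrelevant, leukocyte = leukocyte, lesion = lesion,
    fallback = fallback_classes(taxonomy),
    # severity order used on exact CMD ties between crossed lesion gates
    lesion_precedence = c("adenocarcinoma", "hsil", "lsil")
  ), class = "gate_config")
}

#' Label one cell from its CMD vector
#'
#' Strict evaluation order: irrelevant gate, then leukocyte gate, then the
#' lesion gates, then argmax over the fallback classes. A cell crossing
#' several lesion gates receives the crossed class with the highest CMD
#' value; exact ties resolve by severity (adenocarcinoma > HSIL > LSIL).
#' All gates use the `>=` convention.
#'
#' @param cmd Named numeric CMD vector whose names equal the taxonomy.
#' @param config A [gate_config()].
#' @return A single class name.
#' @export
#' @examples
#' cfg <- gate_config()
#' v <- setNames(rep(0.1, 11), cyto_classes(11))
#' v["lsil"] <- 0.85
#' gate_cell(v, cfg)
gate_cell <- function(cmd, config = gate_config()) {
  m <- matrix(cmd, nrow = 1, dimnames = list(NULL, names(cmd)))
  gate_cells(m, config)[1L]
}

#' Label many cells at once
#'
#' Vectorised form of [gate_cell()] over a matrix (or data frame) of CMD
#' values with one row per cell; columns may be named either by class or as
#' `cmd_<class>`.
#'
#' @param cmd Numeric matrix/data frame, rows = cells.
#' @param config A [gate_config()].
#' @return Character vector of labels, one per row.
#' @export
gate_cells <- function(cmd, config = gate_config()) {
  tax <- config$taxonomy
  cmd <- as.matrix(cmd)
  colnames(cmd) <- sub("^cmd_", "", colnames(cmd))
  check_cmd_schema(cmd, tax)
  cmd <- cmd[, tax, drop = FALSE]
  n <- nrow(cmd)
  label <- rep(NA_character_, n)

  open <- rep(TRUE, n)
  hit <- open & cmd[, "irrelevant"] >= config$irrelevant
  label[hit] <- "irrelevant"; open <- open & !hit
  hit <- open & cmd[, "leukocyte"] >= config$leukocyte
  label[hit] <- "leukocyte"; open <- open & !hit

  les <- names(config$lesion)
  if (length(les)) {
    crossed <- sweep(cmd[, les, drop = FALSE], 2L, config$lesion, ">=")
    any_cross <- open & rowSums(crossed) > 0
    if (any(any_cross)) {
      vals <- cmd[, les, drop = FALSE]
      vals[!crossed] <- -Inf
      # order columns by severity so max.col's first-max tie rule applies it
      sev <- intersect(config$lesion_precedence, les)
      vals <- vals[, sev, drop = FALSE]
      pick <- sev[max.col(vals[any_cross, , drop = FALSE], ties.method = "first")]
      label[any_cross] <- pick
      open <- open & !any_cross
    }
  }
  if (any(open)) {
    fb <- config$fallback
    label[open] <- fb[max.col(cmd[open, fb, drop = FALSE], ties.method = "first")]
  }
  label
}

#' Gate all cells of one slide and aggregate class counts
#'
#' @param cells Tibble of cell records for a single slide (columns
#'   `slide_id` and the `cmd_*` columns).
#' @param config A [gate_config()].
#' @return List with `cells` (input with a `label` column written back) and
#'   `counts` (named integer vector over the taxonomy; sums to the number
#'   of cells).
#' @export
gate_slide <- function(cells, config = gate_config()) {
  if (length(unique(cells$slide_id)) > 1L) {
    stop("input error: `cells` mixes multiple slide ids")
  }
  tax <- config$taxonomy
  counts <- stats::setNames(integer(length(tax)), tax)
  if (nrow(cells)) {
    lab <- gate_cells(cells[, cmd_cols(tax), drop = FALSE], config)
    cells$label <- lab
    tab <- table(factor(lab, levels = tax))
    counts[names(tab)] <- as.integer(tab)
  } else {
    cells$label <- character(0)
  }
  list(cells = cells, counts = counts)
}

#' Gate a whole cohort and attach per-slide counts
#'
#' Applies [gate_cells()] to every cell, writes the `label` column back onto
#' the cells table and adds `count_*` columns to the slides table.
#'
#' @param cohort A `"cyto_cohort"` (see [simulate_cohort()]) or a list with
#'   `slides` and `cells` tibbles.
#' @param config A [gate_config()].
#' @return The cohort with labelled cells and per-slide counts.
#' @export
gate_cohort <- function(cohort, config = gate_config()) {
  tax <- config$taxonomy
  cells <- cohort$cells
  if (is.null(cells)) stop("cohort has no cells; was it simulated with include_cells = FALSE?")
  if (nrow(cells)) {
    cells$label <- gate_cells(cells[, cmd_cols(tax), drop = FALSE], config)
  } else {
    cells$label <- character(0)
  }
  sid <- factor(cells$slide_id, levels = cohort$slides$slide_id)
  tab <- table(sid, factor(cells$label, levels = tax))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), colnames(tab)))
  slides <- cohort$slides
  for (cl in tax) {
    slides[[paste0("count_", cl)]] <-
      as.integer(counts[match(slides$slide_id, rownames(counts)), cl])
  }
  cohort$cells <- cells
  cohort$slides <- slides
  cohort$gate <- config
  cohort
}

#' Superficial/intermediate fraction of the epithelial population
#'
#' Ratio of superficial/intermediate squamous cells to all non-irrelevant,
#' non-leukocyte cells — the quantity whose age trend tracks epithelial
#' remodelling around menopause.
#'
#' @param counts Named count vector over the taxonomy (or a one-row slides
#'   table with `count_*` columns).
#' @return Value in \[0,1\], or `NA` when the denominator is zero.
#' @export
#' @examples
#' epithelial_fraction(c(superficial_intermediate = 50, parabasal = 50,
#'                       leukocyte = 1000))
epithelial_fraction <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- unlist(counts[1, grep("^count_", names(counts))])
    names(counts) <- sub("^count_", "", names(counts))
  }
  keep <- setdiff(names(counts), c("irrelevant", "leukocyte"))
  denom <- sum(counts[keep])
  if (denom == 0) return(NA_real_)
  unname(sum(counts[intersect("superficial_intermediate", keep)]) / denom)
}
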