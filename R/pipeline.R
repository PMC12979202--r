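#' Write a cohort to delimited text (slides + cells CSV)
#'
#' Schemas: `slides.csv` has `slide_id, centre, prep, diagnosis, age, hpv`
#' plus any `count_*` columns; `cells.csv` has `slide_id, cell_id, x, y, z`,
#' optional `true_class`/`label`, and one `cmd_<class>` column per class.
#' The master seed is recorded in a `#`-prefixed header comment.
#'
#' @param cohort A `"cyto_cohort"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(slides = file.path(dir, "slides.csv"),
             cells = file.path(dir, "cells.csv"))
  hdr <- paste0("# cytogate cohort; seed: ",
                if (is.null(cohort$seed)) "NA" else cohort$seed)
  for (what in names(paths)) {
    tbl <- cohort[[what]]
    if (is.null(tbl)) next
    con <- file(paths[[what]], "w")
    writeLines(hdr, con)
    utils::write.csv(as.data.frame(tbl), con, row.names = FALSE)
    close(con)
  }
  invisible(paths)
}

read_csv_commented <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  check.names = FALSE)
}

apply_col_map <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  for (std in names(col_map)) {
    if (col_map[[std]] %in% names(df)) {
      names(df)[names(df) == col_map[[std]]] <- std
    }
  }
  df
}

#' Load and validate a slides table
#'
#' @param path CSV path (comment lines starting with `#` are skipped).
#' @param col_map Optional named character vector mapping standard column
#'   names to the file's column names (adapts external dialects without
#'   code changes), e.g. `c(diagnosis = "cytology")`.
#' @return Tibble with validated types; unknown Bethesda categories are
#'   rejected with their row numbers, malformed ages raise a parse error
#'   naming the row, and missing/blank HPV values map to `"missing"`.
#' @export
load_slides <- function(path, col_map = NULL) {
  df <- apply_col_map(read_csv_commented(path), col_map)
  need <- c("slide_id", "centre", "prep", "diagnosis", "age")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("slides file missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!df$diagnosis %in% bethesda_categories())
  if (length(bad)) {
    stop("unknown Bethesda category in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), ": '",
         df$diagnosis[bad[1]], "'")
  }
  age_num <- suppressWarnings(as.numeric(df$age))
  bad <- which(is.na(age_num))
  if (length(bad)) {
    stop("parse error: malformed age in row ", bad[1], " ('", df$age[bad[1]], "')")
  }
  df$age <- age_num
  if ("hpv" %in% names(df)) {
    df$hpv[is.na(df$hpv) | df$hpv == ""] <- "missing"
    bad <- which(!df$hpv %in% c("positive", "negative", "missing"))
    if (length(bad)) {
      stop("invalid hpv value in row ", bad[1], ": '", df$hpv[bad[1]], "'")
    }
  }
  for (cc in grep("^count_", names(df), value = TRUE)) {
    df[[cc]] <- as.integer(df[[cc]])
  }
  tibble::as_tibble(df)
}

#' Load and validate a cells table
#'
#' @inheritParams load_slides
#' @param taxonomy Expected class taxonomy; the `cmd_*` columns must cover
#'   it exactly.
#' @return Tibble of cell records.
#' @export
load_cells <- function(path, taxonomy = NULL, col_map = NULL) {
  df <- apply_col_map(read_csv_commented(path), col_map)
  need <- c("slide_id", "cell_id", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cells file missing column(s): ", paste(miss, collapse = ", "))
  cmd <- grep("^cmd_", names(df), value = TRUE)
  if (!length(cmd)) stop("cells file has no cmd_* columns")
  if (is.null(taxonomy)) taxonomy <- sub("^cmd_", "", cmd)
  check_cmd_schema(df[, cmd, drop = FALSE], taxonomy)
  for (cc in cmd) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) | v < 0 | v > 1)
    if (length(bad)) {
      stop("parse error: invalid value in ", cc, ", row ", bad[1])
    }
    df[[cc]] <- v
  }
  if (anyDuplicated(paste(df$slide_id, df$cell_id))) {
    stop("duplicate (slide_id, cell_id) pairs in cells file")
  }
  tibble::as_tibble(df)
}

#' Figure-style report tables from gated slides
#'
#' * `composition` — long table of per-slide class counts, slides grouped
#'   by diagnosis and ordered within each group by total cell count (the
#'   stacked-bar layout).
#' * `abnormal` — per-slide lesion-class counts by diagnosis and HPV
#'   status (the violin layout; zero rows when no lesion class counts
#'   exist).
#'
#' @param slides Gated slides table (with `count_*` columns).
#' @param taxonomy Class taxonomy.
#' @return List of tibbles.
#' @export
report_tables <- function(slides, taxonomy = cyto_classes(11)) {
  ccols <- intersect(count_cols(taxonomy), names(slides))
  total <- rowSums(slides[, ccols, drop = FALSE])
  ord <- order(factor(slides$diagnosis, levels = bethesda_categories()), -total)
  comp <- slides[ord, c("slide_id", "diagnosis"), drop = FALSE]
  comp$total <- total[ord]
  comp$rank_in_group <- stats::ave(
    seq_len(nrow(comp)), comp$diagnosis, FUN = seq_along)
  long <- do.call(rbind, lapply(ccols, function(cc) {
    tibble::tibble(
      slide_id = comp$slide_id, diagnosis = comp$diagnosis,
      total = comp$total, rank_in_group = comp$rank_in_group,
      class = sub("^count_", "", cc),
      count = slides[[cc]][ord]
    )
  }))
  lesion_cols <- intersect(count_cols(lesion_classes()), names(slides))
  abnormal <- if (length(lesion_cols) && nrow(slides)) {
    do.call(rbind, lapply(lesion_cols, function(cc) {
      tibble::tibble(
        slide_id = slides$slide_id, centre = slides$centre,
        diagnosis = slides$diagnosis,
        hpv = if ("hpv" %in% names(slides)) slides$hpv else NA_character_,
        class = sub("^count_", "", cc), count = slides[[cc]]
      )
    }))
  } else {
    tibble::tibble(slide_id = character(), centre = character(),
                   diagnosis = character(), hpv = character(),
                   class = character(), count = integer())
  }
  list(composition = tibble::as_tibble(long), abnormal = abnormal)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or load) a cohort, gate every cell, score slides for
#' the configured endpoints, run the HPV-stratified and diagnosis-stratified
#' comparisons, compute positivity curves and ROC/AUC summaries (overall
#' and per centre), optionally sweep the per-cell threshold, and write all
#' result CSVs plus a JSON manifest (config hash, seed, per-stage row
#' counts). Re-running with an identical config reproduces byte-identical
#' CSVs.
#'
#' @param config Either a YAML file path or a list with elements:
#'   `simulation` (arguments to [sim_config()], or a ready `"sim_config"`)
#'   OR `cells_csv` + `slides_csv`; optional `gate` (arguments to
#'   [gate_config()]), `endpoints` (character vector of endpoint names),
#'   `n_resamples`, `seed`, `sweep` (logical), `sweep_grid`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the manifest and in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  has_sim <- !is.null(config$simulation)
  has_files <- !is.null(config$cells_csv) || !is.null(config$slides_csv)
  if (has_sim == has_files) {
    stop("config must contain exactly one of `simulation` or `cells_csv`/`slides_csv`")
  }
  seed <- config$seed %||% 1L
  n_resamples <- config$n_resamples %||% 500L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (has_sim) {
    sim <- config$simulation
    if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
    cohort <- simulate_cohort(sim)
    taxonomy <- sim$taxonomy
  } else {
    slides <- load_slides(config$slides_csv, col_map = config$col_map)
    cells <- load_cells(config$cells_csv, col_map = config$col_map)
    taxonomy <- sub("^cmd_", "", grep("^cmd_", names(cells), value = TRUE))
    cohort <- structure(list(slides = slides, cells = cells,
                             taxonomy = taxonomy, seed = seed),
                        class = "cyto_cohort")
  }
  n_cells_in <- nrow(cohort$cells)

  gate_args <- config$gate %||% list()
  gate_args$taxonomy <- taxonomy
  gate <- do.call(gate_config, gate_args)
  cohort <- gate_cohort(cohort, gate)
  slides <- cohort$slides
  stopifnot(sum(slides[, count_cols(taxonomy)]) == n_cells_in)

  endpoints <- config$endpoints %||% c("LSIL+", "HSIL+")
  has_hpv <- "hpv" %in% names(slides) && any(slides$hpv %in% c("positive", "negative"))
  results <- list()

  # group comparisons (HPV+ vs HPV- within centre and within diagnosis)
  if (has_hpv) {
    hp <- slides[slides$hpv %in% c("positive", "negative"), , drop = FALSE]
    cmp <- list()
    for (cl in intersect(c("lsil", "hsil"), taxonomy)) {
      for (strat in c("centre", "diagnosis")) {
        t <- group_comparison_table(
          hp, paste0("count_", cl), "hpv", "negative", "positive",
          strata = strat)
        if (nrow(t)) {
          t$metric <- cl; t$stratified_by <- strat
          cmp[[length(cmp) + 1L]] <- t
        }
      }
    }
    results$comparisons <- if (length(cmp)) do.call(rbind, cmp) else NULL
  } else {
    warning("no usable HPV results; HPV-stratified analyses skipped")
  }

  # positivity curves
  results$positivity <- do.call(rbind, lapply(
    intersect(c("lsil", "hsil"), taxonomy), function(cl) {
      pc <- positivity_curve(slides, cl)
      pc$class <- cl
      pc
    }))

  # ROC per endpoint, overall and per centre
  auc_rows <- list(); curve_rows <- list()
  for (ep in endpoints) {
    spec <- endpoint_spec(ep)
    labsrc <- if (spec$name == "HPV+") {
      if (!has_hpv) next
      slides$hpv
    } else slides$diagnosis
    lab <- endpoint_label(labsrc, spec)
    keep <- lab != "excluded"
    score <- slide_score(slides, spec)
    centres <- unique(slides$centre)
    sel_list <- c(list(all = keep),
                  stats::setNames(lapply(centres, function(ct) keep & slides$centre == ct),
                                  centres))
    for (nm in names(sel_list)) {
      sel <- sel_list[[nm]]
      if (sum(lab[sel] == "positive") == 0 || sum(lab[sel] == "negative") == 0) next
      band <- bootstrap_roc_band(score[sel], lab[sel],
                                 n_resamples = n_resamples, seed = seed)
      auc_rows[[length(auc_rows) + 1L]] <- tibble::tibble(
        endpoint = ep, centre = nm, auc = band$auc,
        ci_lo = band$auc_ci[1], ci_hi = band$auc_ci[2],
        n_pos = sum(lab[sel] == "positive"), n_neg = sum(lab[sel] == "negative")
      )
      if (nm == "all") {
        curve_rows[[length(curve_rows) + 1L]] <- tibble::tibble(
          endpoint = ep, fpr = band$grid, tpr = band$tpr,
          lower = band$lower, upper = band$upper
        )
      }
    }
  }
  results$roc_auc <- if (length(auc_rows)) do.call(rbind, auc_rows) else NULL
  results$roc_curves <- if (length(curve_rows)) do.call(rbind, curve_rows) else NULL

  if (isTRUE(config$sweep)) {
    results$sweep <- threshold_sweep(
      cohort, endpoint_spec(endpoints[1]),
      grid = config$sweep_grid %||% seq(0.60, 0.99, by = 0.01),
      gate = gate, n_resamples = n_resamples, seed = seed)
  }

  rep_tabs <- report_tables(slides, taxonomy)
  results$composition <- rep_tabs$composition
  results$abnormal <- rep_tabs$abnormal

  # write outputs
  write_cohort(cohort, out_dir)
  written <- c("slides.csv", "cells.csv")
  for (nm in names(results)) {
    if (is.null(results[[nm]])) next
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(results[[nm]]), f, row.names = FALSE)
    written <- c(written, basename(f))
  }
  manifest <- list(
    package = "cytogate",
    config_hash = rlang::hash(config),
    seed = seed,
    n_slides = nrow(slides),
    n_cells = n_cells_in,
    n_cells_labelled = sum(!is.na(cohort$cells$label)),
    files = written
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, cohort = cohort, results = results))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
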