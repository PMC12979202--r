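#' Configuration for the synthetic multi-centre cohort generator
#'
#' Builds the full parameter set for [simulate_cohort()]. Defaults emulate a
#' multi-centre cervical-cytology screening study: per-slide total cellularity
#' is log-normal and spans roughly three orders of magnitude (thousands to
#' hundreds of thousands of detected objects); epithelial composition shifts
#' with donor age (the superficial/intermediate fraction declines after ~50,
#' navicular cells peak in the early 20s); abnormal-cell burden is negative
#' binomial conditional on the Bethesda diagnosis and HPV status; and each
#' cell's CMD vector consists of independent Beta draws (sigmoid semantics:
#' entries in \[0,1\], not summing to 1) with a high-mean draw for the true
#' class, low-mean draws elsewhere, and optional confusion mass between
#' morphologically adjacent phenotypes (navicular vs LSIL, LSIL vs HSIL).
#'
#' @param n_slides Slides per centre: a single integer or a vector named by
#'   centre.
#' @param centres Centre identifiers.
#' @param taxonomy Class taxonomy, see [cyto_classes()].
#' @param diagnosis_mixture Named list (by centre) of probability vectors over
#'   [bethesda_categories()], or a single vector recycled to all centres.
#' @param hpv_model List with `p_positive` (named by diagnosis: P(HPV+ | dx))
#'   and `p_missing` (probability the HPV result is unavailable).
#' @param age_model Named list (by centre) of `list(mean, sd, min, max)` for a
#'   truncated-normal age draw. Defaults match the study centres' printed
#'   medians/IQRs (C 49 (41-59), T 42 (35-53), K 40 (30-48), J 42 (34-55)).
#' @param cellularity List `(meanlog, sdlog)` of the log-normal total count.
#' @param composition Parameters of the age-conditional composition model; see
#'   [composition_weights()].
#' @param abnormal_burden List with per-diagnosis negative-binomial means
#'   `lsil_mu`, `hsil_mu`, `adeno_mu` (named by diagnosis), a common
#'   dispersion `size` (Inf = deterministic `round(mu)`), and
#'   `hpv_multiplier` applied to the mean on HPV-positive slides.
#' @param cmd_noise List with Beta shape pairs `true` and `off`, a
#'   `confusion` block (`pairs`, `prob`, `shape`), and a `concentration`
#'   multiplier applied to every shape pair (variance shrinks as it grows;
#'   `Inf` means noiseless: true class exactly 1, all others 0).
#' @param prep_mix Probability a slide is ThinPrep (vs SurePath).
#' @param seed Master seed. Per-slide substreams are derived by counter from
#'   it, so any subset of slides is reproducible independently of cohort size.
#' @return A validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_slides = 4, seed = 1)
#' coh <- simulate_cohort(cfg)
#' nrow(coh$slides)
sim_config <- function(n_slides = 25,
                       centres = c("C", "T", "K", "J"),
                       taxonomy = cyto_classes(11),
                       diagnosis_mixture = NULL,
                       hpv_model = NULL,
                       age_model = NULL,
                       cellularity = list(meanlog = log(15000), sdlog = 1.15),
                       composition = NULL,
                       abnormal_burden = NULL,
                       cmd_noise = NULL,
                       prep_mix = 0.5,
                       seed = 1L) {
  dx <- bethesda_categories()
  if (is.null(diagnosis_mixture)) {
    diagnosis_mixture <- list(
      C = c(0.70, 0.08, 0.10, 0.03, 0.07, 0.02),
      T = c(0.75, 0.07, 0.09, 0.03, 0.05, 0.01),
      K = c(0.88, 0.05, 0.04, 0.01, 0.015, 0.005),
      J = c(0.75, 0.07, 0.09, 0.03, 0.05, 0.01)
    )
    diagnosis_mixture <- lapply(diagnosis_mixture, stats::setNames, dx)
    diagnosis_mixture <- diagnosis_mixture[
      ifelse(centres %in% names(diagnosis_mixture), centres, "T")]
    names(diagnosis_mixture) <- centres
  }
  if (is.numeric(diagnosis_mixture)) {
    diagnosis_mixture <- stats::setNames(
      rep(list(stats::setNames(diagnosis_mixture, dx)), length(centres)), centres)
  }
  if (is.null(hpv_model)) {
    hpv_model <- list(
      p_positive = stats::setNames(c(0.15, 0.45, 0.85, 0.85, 0.90, 0.95), dx),
      p_missing = 0.28
    )
  }
  if (is.null(age_model)) {
    defaults <- list(
      C = list(mean = 49, sd = 13.3, min = 18, max = 90),
      T = list(mean = 42, sd = 13.3, min = 18, max = 90),
      K = list(mean = 40, sd = 13.3, min = 18, max = 90),
      J = list(mean = 42, sd = 15.6, min = 18, max = 90)
    )
    age_model <- lapply(centres, function(ct) {
      if (ct %in% names(defaults)) defaults[[ct]] else defaults[["T"]]
    })
    names(age_model) <- centres
  }
  if (is.null(composition)) {
    composition <- list(
      irrelevant_w = 0.30, leukocyte_w = 0.25,
      si_young = 0.75, si_old = 0.35, age_mid = 50, age_scale = 6,
      nav_peak = 0.12, nav_age = 22, nav_width = 6,
      glandular_w = 0.06, miscellaneous_w = 0.10
    )
  }
  if (is.null(abnormal_burden)) {
    abnormal_burden <- list(
      lsil_mu  = stats::setNames(c(0.6, 4, 40, 15, 20, 20), dx),
      hsil_mu  = stats::setNames(c(0.25, 1.5, 4, 30, 120, 250), dx),
      adeno_mu = stats::setNames(rep(0.1, 6), dx),
      size = 0.8,
      hpv_multiplier = 4
    )
  }
  if (is.null(cmd_noise)) {
    cmd_noise <- list(
      true = c(16, 2), off = c(0.5, 10),
      confusion = list(
        pairs = list(c("navicular", "lsil"), c("lsil", "hsil")),
        prob = 0.08, shape = c(2.5, 4.5)
      ),
      concentration = 1
    )
  }
  if (length(n_slides) == 1L) {
    n_slides <- stats::setNames(rep(as.integer(n_slides), length(centres)), centres)
  }
  cfg <- structure(list(
    n_slides = n_slides, centres = centres, taxonomy = taxonomy,
    diagnosis_mixture = diagnosis_mixture, hpv_model = hpv_model,
    age_model = age_model, cellularity = cellularity,
    composition = composition, abnormal_burden = abnormal_burden,
    cmd_noise = cmd_noise, prep_mix = prep_mix, seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' A separable cohort configuration
#'
#' Noiseless CMD vectors (`concentration = Inf`) and deterministic abnormal
#' burdens: NILM and ASC-US slides carry zero lesion cells, every LSIL+ slide
#' carries LSIL cells and every HSIL+ slide carries HSIL cells. Slide-level
#' endpoint scores then separate positives from negatives perfectly, which
#' pins the expected ROC behaviour (AUC = 1 at every per-cell threshold).
#'
#' @inheritParams sim_config
#' @param ... Passed to [sim_config()].
#' @return A `"sim_config"`.
#' @export
sim_config_separable <- function(n_slides = 25, seed = 1L, ...) {
  dx <- bethesda_categories()
  sim_config(
    n_slides = n_slides, seed = seed,
    abnormal_burden = list(
      lsil_mu  = stats::setNames(c(0, 0, 30, 10, 8, 8), dx),
      hsil_mu  = stats::setNames(c(0, 0, 0, 40, 60, 100), dx),
      adeno_mu = stats::setNames(rep(0, 6), dx),
      size = Inf, hpv_multiplier = 1
    ),
    cmd_noise = list(
      true = c(16, 2), off = c(0.5, 10),
      confusion = list(pairs = list(), prob = 0, shape = c(2.5, 4.5)),
      concentration = Inf
    ),
    ...
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk_num <- function(x, field, nonneg = TRUE) {
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x) & !is.infinite(x))) {
      stop("configuration error in `", field, "`: non-finite value")
    }
    if (any(is.nan(x))) stop("configuration error in `", field, "`: NaN")
    if (nonneg && any(x < 0)) {
      stop("configuration error in `", field, "`: negative value")
    }
    invisible(TRUE)
  }
  if (any(cfg$n_slides < 0)) stop("configuration error in `n_slides`: negative value")
  tax <- cfg$taxonomy
  if (!all(c("irrelevant", "leukocyte") %in% tax)) {
    stop("configuration error in `taxonomy`: must contain 'irrelevant' and 'leukocyte'")
  }
  if (!any(lesion_classes() %in% tax)) {
    stop("configuration error in `taxonomy`: needs at least one lesion class")
  }
  for (ct in cfg$centres) {
    w <- cfg$diagnosis_mixture[[ct]]
    chk_num(w, paste0("diagnosis_mixture$", ct))
    if (abs(sum(w) - 1) > 1e-9) {
      stop("configuration error in `diagnosis_mixture$", ct,
           "`: weights must sum to 1 (got ", format(sum(w)), ")")
    }
    am <- cfg$age_model[[ct]]
    chk_num(unlist(am), paste0("age_model$", ct), nonneg = FALSE)
    if (am$sd <= 0) stop("configuration error in `age_model$", ct, "$sd`: must be > 0")
  }
  chk_num(cfg$hpv_model$p_positive, "hpv_model$p_positive")
  chk_num(cfg$hpv_model$p_missing, "hpv_model$p_missing")
  chk_num(unlist(cfg$cellularity), "cellularity", nonneg = FALSE)
  if (cfg$cellularity$sdlog < 0) stop("configuration error in `cellularity$sdlog`: negative value")
  chk_num(unlist(cfg$composition), "composition")
  for (f in c("lsil_mu", "hsil_mu", "adeno_mu")) {
    chk_num(cfg$abnormal_burden[[f]], paste0("abnormal_burden$", f))
  }
  chk_num(cfg$abnormal_burden$size, "abnormal_burden$size")
  chk_num(cfg$abnormal_burden$hpv_multiplier, "abnormal_burden$hpv_multiplier")
  chk_num(cfg$cmd_noise$true, "cmd_noise$true")
  chk_num(cfg$cmd_noise$off, "cmd_noise$off")
  chk_num(cfg$cmd_noise$concentration, "cmd_noise$concentration")
  chk_num(cfg$cmd_noise$confusion$prob, "cmd_noise$confusion$prob")
  if (cfg$prep_mix < 0 || cfg$prep_mix > 1) {
    stop("configuration error in `prep_mix`: must lie in [0, 1]")
  }
  invisible(cfg)
}

# Deterministic per-slide substream seed derived by counter from the master
# seed; independent of cohort size so slide subsets reproduce exactly.
slide_seed <- function(master, i) {
  as.integer((as.numeric(master) %% 2147483629 * 48271 + i * 104729) %% 2147483629)
}

#' Age-conditional expected composition over non-lesion classes
#'
#' Mixture weights (summing to 1) over the non-lesion classes of the
#' taxonomy, as a function of donor age: the superficial/intermediate share
#' declines sigmoidally around `age_mid`, navicular cells (11-class taxonomy)
#' carry a Gaussian bump peaking at `nav_age`, parabasal and metaplastic
#' cells absorb the remainder, and fixed shares go to irrelevant objects and
#' leukocytes.
#'
#' @param age Donor age in years (scalar).
#' @param taxonomy Class taxonomy.
#' @param params Composition parameter block from [sim_config()].
#' @return Named numeric vector of weights over the non-lesion classes.
#' @export
composition_weights <- function(age, taxonomy = cyto_classes(11),
                                params = sim_config()$composition) {
  p <- params
  si <- p$si_old + (p$si_young - p$si_old) / (1 + exp((age - p$age_mid) / p$age_scale))
  nav <- if ("navicular" %in% taxonomy) {
    p$nav_peak * exp(-((age - p$nav_age) / p$nav_width)^2)
  } else 0
  rest <- max(1 - si - nav - p$glandular_w - p$miscellaneous_w, 0.02)
  epi <- c(
    superficial_intermediate = si,
    parabasal = rest / 2, metaplasia = rest / 2,
    glandular = p$glandular_w, miscellaneous = p$miscellaneous_w
  )
  if ("navicular" %in% taxonomy) epi <- c(epi, navicular = nav)
  epi <- epi / sum(epi) * (1 - p$irrelevant_w - p$leukocyte_w)
  w <- c(irrelevant = p$irrelevant_w, leukocyte = p$leukocyte_w, epi)
  w[intersect(setdiff(taxonomy, lesion_classes()), names(w))]
}

# draw a negative-binomial burden count (size = Inf means deterministic)
draw_burden <- function(mu, size) {
  if (mu <= 0) return(0L)
  if (is.infinite(size)) return(as.integer(round(mu)))
  stats::rnbinom(1L, size = size, mu = mu)
}

#' Simulate one CMD vector for a cell of known class
#'
#' Independent Beta draws per class: the true class from the high-mean
#' `true` shape pair, all others from the low-mean `off` pair, with the
#' `concentration` multiplier scaling both shapes (mean preserved, variance
#' shrinks). `concentration = Inf` is the noiseless limit: the true-class
#' entry is exactly 1 and all others 0. Draws use R's current RNG stream.
#'
#' @param true_class Class name, must belong to `taxonomy`.
#' @param noise `cmd_noise` block of a [sim_config()].
#' @param taxonomy Class taxonomy.
#' @return Named numeric vector over `taxonomy`, values in \[0,1\].
#' @export
#' @examples
#' set.seed(1)
#' simulate_cmd_vector("lsil", sim_config(n_slides = 1)$cmd_noise)
simulate_cmd_vector <- function(true_class, noise, taxonomy = cyto_classes(11)) {
  if (!true_class %in% taxonomy) {
    stop("taxonomy error: unknown class '", true_class, "'")
  }
  m <- simulate_cmd_matrix(true_class, noise, taxonomy)
  stats::setNames(as.numeric(m[1L, ]), taxonomy)
}

# vectorised CMD generation for a vector of true classes
simulate_cmd_matrix <- function(true_classes, noise, taxonomy) {
  n <- length(true_classes)
  K <- length(taxonomy)
  idx <- match(true_classes, taxonomy)
  if (anyNA(idx)) {
    stop("taxonomy error: unknown class '",
         true_classes[which(is.na(idx))[1L]], "'")
  }
  conc <- noise$concentration
  if (is.infinite(conc)) {
    m <- matrix(0, n, K, dimnames = list(NULL, taxonomy))
    m[cbind(seq_len(n), idx)] <- 1
    return(m)
  }
  m <- matrix(
    stats::rbeta(n * K, conc * noise$off[1], conc * noise$off[2]),
    n, K, dimnames = list(NULL, taxonomy)
  )
  m[cbind(seq_len(n), idx)] <- stats::rbeta(n, conc * noise$true[1], conc * noise$true[2])
  cf <- noise$confusion
  if (length(cf$pairs) && cf$prob > 0) {
    for (pair in cf$pairs) {
      if (!all(pair %in% taxonomy)) next
      for (k in 1:2) {
        a <- pair[k]; b <- pair[3 - k]
        sel <- which(true_classes == a)
        if (!length(sel)) next
        flip <- sel[stats::runif(length(sel)) < cf$prob]
        if (length(flip)) {
          m[cbind(flip, match(b, taxonomy))] <-
            stats::rbeta(length(flip), conc * cf$shape[1], conc * cf$shape[2])
        }
      }
    }
  }
  m
}

#' Simulate a multi-centre cohort of slides and per-cell CMD vectors
#'
#' For every slide: diagnosis from the centre's Bethesda mixture, HPV status
#' conditional on diagnosis, age from the centre's truncated normal, total
#' cellularity from the log-normal model, lesion-cell counts from the
#' negative-binomial burden model (mean scaled up on HPV-positive slides),
#' remaining cells multinomially split over the age-conditional composition,
#' and one CMD vector per cell. Fully reproducible: slide `i` uses a
#' substream seed derived by counter from the master seed.
#'
#' @param config A [sim_config()].
#' @param include_cells If `FALSE`, skip per-cell simulation and instead
#'   attach the true per-class counts to the slides table (`count_*`
#'   columns) — the fast path for slide-level studies.
#' @return List of class `"cyto_cohort"` with `slides` (tibble: slide_id,
#'   centre, prep, diagnosis, age, hpv) and `cells` (tibble: slide_id,
#'   cell_id, x, y, z, true_class, one `cmd_*` column per class), or
#'   `cells = NULL` when `include_cells = FALSE`.
#' @export
simulate_cohort <- function(config, include_cells = TRUE) {
  validate_sim_config(config)
  tax <- config$taxonomy
  slide_rows <- list()
  cell_rows <- list()
  i <- 0L
  for (ct in config$centres) {
    n_ct <- config$n_slides[[ct]]
    if (is.na(n_ct)) n_ct <- 0L
    for (j in seq_len(n_ct)) {
      i <- i + 1L
      sl <- simulate_slide(config, ct, i, include_cells)
      slide_rows[[i]] <- sl$slide
      if (include_cells) cell_rows[[i]] <- sl$cells
    }
  }
  slides <- if (length(slide_rows)) {
    do.call(rbind, slide_rows)
  } else {
    empty_slides_tbl(tax, include_counts = !include_cells)
  }
  cells <- if (!include_cells) {
    NULL
  } else if (length(cell_rows)) {
    do.call(rbind, cell_rows)
  } else {
    empty_cells_tbl(tax)
  }
  structure(
    list(slides = tibble::as_tibble(slides),
         cells = if (is.null(cells)) NULL else tibble::as_tibble(cells),
         taxonomy = tax, seed = config$seed),
    class = "cyto_cohort"
  )
}

empty_slides_tbl <- function(tax, include_counts = FALSE) {
  out <- tibble::tibble(
    slide_id = character(), centre = character(), prep = character(),
    diagnosis = character(), age = numeric(), hpv = character()
  )
  if (include_counts) {
    for (cc in count_cols(tax)) out[[cc]] <- integer()
  }
  out
}

empty_cells_tbl <- function(tax) {
  out <- tibble::tibble(
    slide_id = character(), cell_id = character(),
    x = numeric(), y = numeric(), z = integer(), true_class = character()
  )
  for (cc in cmd_cols(tax)) out[[cc]] <- numeric()
  out
}

simulate_slide <- function(config, centre, i, include_cells) {
  set.seed(slide_seed(config$seed, i))
  tax <- config$taxonomy
  dx <- bethesda_categories()
  diagnosis <- sample(dx, 1L, prob = config$diagnosis_mixture[[centre]])
  hpv_true <- stats::runif(1) < config$hpv_model$p_positive[[diagnosis]]
  hpv <- if (stats::runif(1) < config$hpv_model$p_missing) {
    "missing"
  } else if (hpv_true) "positive" else "negative"
  am <- config$age_model[[centre]]
  age <- Inf
  while (age < am$min || age > am$max) age <- stats::rnorm(1, am$mean, am$sd)
  age <- round(age)
  prep <- if (stats::runif(1) < config$prep_mix) "ThinPrep" else "SurePath"
  n_total <- max(1L, as.integer(round(stats::rlnorm(
    1, config$cellularity$meanlog, config$cellularity$sdlog))))

  ab <- config$abnormal_burden
  mult <- if (hpv_true) ab$hpv_multiplier else 1
  lesion_counts <- c(
    lsil = draw_burden(ab$lsil_mu[[diagnosis]] * mult, ab$size),
    hsil = draw_burden(ab$hsil_mu[[diagnosis]] * mult, ab$size),
    adenocarcinoma = draw_burden(ab$adeno_mu[[diagnosis]] * mult, ab$size)
  )
  lesion_counts <- lesion_counts[intersect(names(lesion_counts), tax)]
  n_rest <- max(n_total - sum(lesion_counts), 0L)
  w <- composition_weights(age, tax, config$composition)
  rest_counts <- stats::setNames(
    as.integer(stats::rmultinom(1L, n_rest, w)), names(w))
  counts <- stats::setNames(integer(length(tax)), tax)
  counts[names(rest_counts)] <- rest_counts
  counts[names(lesion_counts)] <- counts[names(lesion_counts)] + as.integer(lesion_counts)

  slide <- tibble::tibble(
    slide_id = sprintf("S%04d", i), centre = centre, prep = prep,
    diagnosis = diagnosis, age = age, hpv = hpv
  )
  if (!include_cells) {
    for (k in seq_along(tax)) slide[[paste0("count_", tax[k])]] <- counts[[k]]
    return(list(slide = slide, cells = NULL))
  }
  n_cells <- sum(counts)
  true_class <- rep(tax, counts)
  cmd <- simulate_cmd_matrix(true_class, config$cmd_noise, tax)
  cells <- tibble::tibble(
    slide_id = slide$slide_id,
    cell_id = sprintf("%s_c%06d", slide$slide_id, seq_len(n_cells)),
    x = stats::runif(n_cells, 0, 4480),
    y = stats::runif(n_cells, 0, 4504),
    z = sample.int(13L, n_cells, replace = TRUE) - 1L,
    true_class = true_class
  )
  colnames(cmd) <- cmd_cols(tax)
  cells <- tibble::as_tibble(cbind(cells, tibble::as_tibble(cmd)))
  list(slide = slide, cells = cells)
}
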