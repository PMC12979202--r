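#' Group per-layer nucleus detections into 3D nucleus instances
#'
#' Optical sections are acquired as a z-stack, so one nucleus is typically
#' detected on several neighbouring layers. Detections are merged by
#' single-linkage connectivity: two detections are linked when their lateral
#' centre distance is at most `tol` pixels and their layer indices differ by
#' at most `max_gap + 1`; connected components become nucleus instances.
#'
#' @param detections Data frame with columns `x`, `y`, `z`, `w`, `h`,
#'   `score` (one row per detection box; `z` is the layer index).
#' @param tol Lateral tolerance in pixels. Default: half the mean box
#'   diagonal of the input.
#' @param max_gap Maximum number of skipped layers between linked
#'   detections (0 links only adjacent or same layers).
#' @return List of nucleus instances. Each is a list with `members` (row
#'   indices into `detections`), `centre` (score-weighted mean of member
#'   centres), `z_min`, `z_max`, and unset `best_layer`/`focus_scores`.
#' @export
#' @examples
#' d <- data.frame(x = c(10, 10), y = c(10, 10), z = c(3, 4),
#'                 w = 8, h = 8, score = 0.9)
#' length(group_detections(d, tol = 2, max_gap = 0))
group_detections <- function(detections, tol = NULL, max_gap = 0L) {
  if (max_gap < 0) stop("parameter error: `max_gap` must be >= 0")
  n <- nrow(detections)
  if (is.null(n) || n == 0L) return(list())
  if (is.null(tol)) {
    tol <- mean(sqrt(detections$w^2 + detections$h^2)) / 2
  }
  if (!is.finite(tol) || tol <= 0) stop("parameter error: `tol` must be > 0")

  # union-find over pairwise links
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  x <- detections$x; y <- detections$y; z <- detections$z
  ord <- order(z, x, y)
  for (ii in seq_len(n - 1L)) {
    a <- ord[ii]
    for (jj in (ii + 1L):n) {
      b <- ord[jj]
      if (z[b] - z[a] > max_gap + 1L) break
      if (abs(x[a] - x[b]) > tol) next
      if (sqrt((x[a] - x[b])^2 + (y[a] - y[b])^2) <= tol) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(split(seq_len(n), roots), function(members) {
    sc <- detections$score[members]
    if (sum(sc) <= 0) sc <- rep(1, length(members))
    list(
      members = members,
      centre = c(
        x = sum(x[members] * sc) / sum(sc),
        y = sum(y[members] * sc) / sum(sc)
      ),
      z_min = min(z[members]), z_max = max(z[members]),
      best_layer = NA_integer_, focus_scores = NULL
    )
  }) |> unname()
}

#' Focus score of an image tile
#'
#' Sharpness metric for best-focal-plane selection. The default
#' `"laplacian"` metric is the variance of the 3x3 Laplacian response;
#' `"tenengrad"` is the mean squared Sobel gradient magnitude. Both are
#' invariant to an additive intensity offset and return 0 for a constant
#' tile; both strictly decrease under Gaussian blurring of textured tiles.
#'
#' @param tile Numeric matrix of intensities.
#' @param method `"laplacian"` (default) or `"tenengrad"`.
#' @return Non-negative scalar.
#' @export
focus_score <- function(tile, method = c("laplacian", "tenengrad")) {
  method <- match.arg(method)
  if (is.null(dim(tile)) || any(dim(tile) < 1L)) stop("tile must be non-empty")
  if (nrow(tile) < 3L || ncol(tile) < 3L) return(0)
  if (method == "laplacian") {
    r <- conv3x3(tile, matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3))
    v <- stats::var(as.vector(r))
    if (is.na(v)) 0 else v
  } else {
    gx <- conv3x3(tile, matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE))
    gy <- conv3x3(tile, t(matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)))
    mean(gx^2 + gy^2)
  }
}

# valid (interior-only) 3x3 convolution, correlation orientation
conv3x3 <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr - 2L, nc - 2L)
  for (di in 0:2) {
    for (dj in 0:2) {
      out <- out + k[di + 1L, dj + 1L] *
        m[(1L + di):(nr - 2L + di), (1L + dj):(nc - 2L + dj)]
    }
  }
  out
}

#' Select the best-focus layer for a nucleus instance
#'
#' Evaluates [focus_score()] on a window around the instance's
#' representative centre on every layer of its z range and returns the
#' argmax layer. Exact ties go to the layer nearest the z-range midpoint,
#' then to the lower index.
#'
#' @param stack 3D array (layers x rows x cols) of intensities; layer 1 is
#'   z index 1.
#' @param instance A nucleus instance from [group_detections()] (or any
#'   list with `centre`, `z_min`, `z_max`).
#' @param window Window half-size in pixels (the evaluated tile is the
#'   clipped `2*window+1` square around the centre).
#' @param method Passed to [focus_score()].
#' @return Integer layer index in `[z_min, z_max]`.
#' @export
select_focus_layer <- function(stack, instance, window = 16L,
                               method = "laplacian") {
  zr <- instance$z_min:instance$z_max
  if (min(zr) < 1L || max(zr) > dim(stack)[1]) {
    stop("instance z range lies outside the stack depth")
  }
  cx <- instance$centre[["x"]]; cy <- instance$centre[["y"]]
  nr <- dim(stack)[2]; nc <- dim(stack)[3]
  # (x = column, y = row), 0-based pixel convention
  rows <- (floor(cy) - window):(floor(cy) + window) + 1L
  cols <- (floor(cx) - window):(floor(cx) + window) + 1L
  rows <- rows[rows >= 1L & rows <= nr]
  cols <- cols[cols >= 1L & cols <= nc]
  if (!length(rows) || !length(cols)) {
    stop("geometry error: focus window lies fully outside the image bounds")
  }
  scores <- vapply(zr, function(z) {
    focus_score(stack[z, rows, cols, drop = TRUE], method = method)
  }, numeric(1))
  best <- which(scores == max(scores))
  if (length(best) > 1L) {
    mid <- (instance$z_min + instance$z_max) / 2
    d <- abs(zr[best] - mid)
    best <- best[d == min(d)]
    best <- best[1L]  # lower index on remaining ties
  }
  zr[best]
}

#' Crop a nucleus-centred patch from one stack layer
#'
#' Extracts a `size x size` patch centred on `centre` (0-based, x = column,
#' y = row, half-open pixel convention: the centre pixel lands at output
#' index `floor(size/2)`). Regions beyond the image border are filled by
#' mirror reflection.
#'
#' @param stack 3D array (layers x rows x cols).
#' @param centre Numeric `c(x, y)` in pixels.
#' @param layer Layer index.
#' @param size Patch side length in pixels (classifier input is 224).
#' @return `size x size` numeric matrix.
#' @export
crop_patch <- function(stack, centre, layer, size = 224L) {
  if (size <= 0) stop("parameter error: `size` must be > 0")
  if (layer < 1L || layer > dim(stack)[1]) stop("layer outside stack depth")
  img <- stack[layer, , , drop = TRUE]
  if (is.null(dim(img))) img <- matrix(img, dim(stack)[2], dim(stack)[3])
  half <- size %/% 2L
  rows0 <- (floor(centre[["y"]]) - half):(floor(centre[["y"]]) - half + size - 1L)
  cols0 <- (floor(centre[["x"]]) - half):(floor(centre[["x"]]) - half + size - 1L)
  img[reflect_index(rows0, nrow(img)), reflect_index(cols0, ncol(img)), drop = FALSE]
}

# map 0-based indices onto [1, n] by mirror reflection (abcb|abcd|cbab style)
reflect_index <- function(idx0, n) {
  if (n == 1L) return(rep(1L, length(idx0)))
  period <- 2L * (n - 1L)
  m <- ((idx0 %% period) + period) %% period
  as.integer(ifelse(m < n, m, period - m)) + 1L
}

#' Synthesise an image stack with a known best-focus layer
#'
#' Fixture generator for focus-selection tests: a random smooth-ish texture
#' is blurred per layer with Gaussian sigma growing linearly in the distance
#' from `focus_layer`, so the planted layer is the sharpest.
#'
#' @param n_layers Number of layers.
#' @param focus_layer Planted sharp layer, in `[1, n_layers]`.
#' @param seed Texture seed.
#' @param nr,nc Image size in pixels.
#' @param sigma_step Blur increment per layer of defocus.
#' @return 3D array (layers x rows x cols), deterministic given `seed`.
#' @export
make_blurred_stack <- function(n_layers, focus_layer, seed = 1L,
                               nr = 48L, nc = 48L, sigma_step = 0.8) {
  if (focus_layer < 1L || focus_layer > n_layers) {
    stop("`focus_layer` must lie in [1, n_layers]")
  }
  set.seed(seed)
  base <- matrix(stats::runif(nr * nc), nr, nc)
  stack <- array(0, dim = c(n_layers, nr, nc))
  for (z in seq_len(n_layers)) {
    sigma <- sigma_step * abs(z - focus_layer)
    stack[z, , ] <- if (sigma == 0) base else gaussian_blur(base, sigma)
  }
  stack
}

# separable Gaussian blur with reflected borders (fixture-scale images)
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_r <- reflect_index((-r):(nrow(img) - 1L + r), nrow(img))
  pad_c <- reflect_index((-r):(ncol(img) - 1L + r), ncol(img))
  p <- img[pad_r, , drop = FALSE]
  v <- apply(p, 2L, function(col) as.numeric(stats::filter(col, k, sides = 2L)))
  v <- v[(r + 1L):(r + nrow(img)), , drop = FALSE]
  p2 <- v[, pad_c, drop = FALSE]
  h <- t(apply(p2, 1L, function(row) as.numeric(stats::filter(row, k, sides = 2L))))
  h[, (r + 1L):(r + ncol(img)), drop = FALSE]
}
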