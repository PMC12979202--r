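test_that("detection grouping follows the connectivity rule on hand traces", {
  one <- data.frame(x = 5, y = 5, z = 4L, w = 8, h = 8, score = 0.7)
  g <- group_detections(one, tol = 3, max_gap = 0L)
  expect_length(g, 1)
  expect_equal(g[[1]]$z_min, 4L)
  expect_equal(g[[1]]$z_max, 4L)

  two <- data.frame(x = c(10, 10), y = c(10, 10), z = c(3L, 4L),
                    w = 8, h = 8, score = 0.9)
  g <- group_detections(two, tol = 2, max_gap = 0L)
  expect_length(g, 1)
  expect_equal(c(g[[1]]$z_min, g[[1]]$z_max), c(3L, 4L))

  far <- data.frame(x = c(10, 10), y = c(10, 10), z = c(3L, 7L),
                    w = 8, h = 8, score = 0.9)
  expect_length(group_detections(far, tol = 2, max_gap = 0L), 2)

  expect_equal(group_detections(data.frame()), list())
  expect_error(group_detections(one, tol = -1), "parameter error")
  expect_error(group_detections(one, tol = 3, max_gap = -1), "parameter error")
})

test_that("no detections merge when all are farther apart than the tolerance", {
  d <- data.frame(x = seq(0, 990, by = 10), y = 0, z = 1L, w = 4, h = 4, score = 1)
  expect_length(group_detections(d, tol = 5, max_gap = 0L), nrow(d))
})

test_that("representative centre is the score-weighted mean of members", {
  d <- data.frame(x = c(0, 2), y = c(0, 0), z = c(1L, 1L), w = 4, h = 4,
                  score = c(1, 3))
  g <- group_detections(d, tol = 5, max_gap = 0L)
  expect_length(g, 1)
  expect_equal(unname(g[[1]]$centre["x"]), 1.5)
})

test_that("grouping memberships partition the input and match a BFS oracle", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(1:25, 1)
    det <- data.frame(
      x = runif(n, 0, 60), y = runif(n, 0, 60),
      z = sample(1:6, n, replace = TRUE),
      w = runif(n, 4, 10), h = runif(n, 4, 10), score = runif(n)
    )
    tol <- runif(1, 3, 15)
    gap <- sample(0:2, 1)
    g <- group_detections(det, tol = tol, max_gap = gap)
    members <- sort(unlist(lapply(g, `[[`, "members")))
    expect_equal(members, seq_len(n))   # partition: each detection exactly once
    oracle <- bf_group_components(det, tol, gap)
    mine <- integer(n)
    for (k in seq_along(g)) mine[g[[k]]$members] <- k
    # same partition up to relabelling
    expect_equal(length(unique(oracle)), length(g))
    expect_true(all(tapply(oracle, mine, function(v) length(unique(v))) == 1))
  }
})

test_that("focus score: flat tiles give zero, offsets do not matter", {
  expect_equal(focus_score(matrix(7, 20, 20)), 0)
  expect_equal(focus_score(matrix(7, 20, 20), method = "tenengrad"), 0)
  set.seed(3)
  t1 <- matrix(runif(400), 20, 20)
  for (m in c("laplacian", "tenengrad")) {
    expect_equal(focus_score(t1 + 100, method = m), focus_score(t1, method = m),
                 tolerance = 1e-9)
  }
})

test_that("focus score decreases under Gaussian blur of a textured tile", {
  set.seed(4)
  t1 <- matrix(runif(32 * 32), 32, 32)
  blurred <- cytogate:::gaussian_blur(t1, 2)
  for (m in c("laplacian", "tenengrad")) {
    expect_gt(focus_score(t1, method = m), focus_score(blurred, method = m))
  }
})

test_that("variance-of-Laplacian matches a direct convolution oracle", {
  cb <- outer(1:12, 1:12, function(i, j) (i + j) %% 2)  # checkerboard
  k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  expect_equal(focus_score(cb), var(as.vector(bf_conv3x3(cb, k))),
               tolerance = 1e-12)
  set.seed(5)
  tx <- matrix(rnorm(15 * 11), 15, 11)
  expect_equal(focus_score(tx), var(as.vector(bf_conv3x3(tx, k))),
               tolerance = 1e-12)
})

test_that("focus layer selection recovers a planted optimum and breaks ties", {
  st <- make_blurred_stack(9, 5, seed = 21)
  inst <- list(centre = c(x = 24, y = 24), z_min = 1L, z_max = 9L)
  expect_equal(select_focus_layer(st, inst, window = 12), 5L)

  single <- list(centre = c(x = 24, y = 24), z_min = 3L, z_max = 3L)
  expect_equal(select_focus_layer(st, single, window = 12), 3L)

  # two identical layers: tie resolves to the lower index
  dup <- array(0, dim = c(2, 16, 16))
  set.seed(6)
  layer <- matrix(runif(256), 16, 16)
  dup[1, , ] <- layer; dup[2, , ] <- layer
  expect_equal(
    select_focus_layer(dup, list(centre = c(x = 8, y = 8), z_min = 1L, z_max = 2L),
                       window = 6), 1L)

  expect_error(
    select_focus_layer(st, list(centre = c(x = 2000, y = 2000),
                                z_min = 1L, z_max = 2L), window = 4),
    "geometry error")
  expect_error(
    select_focus_layer(st, list(centre = c(x = 24, y = 24),
                                z_min = 1L, z_max = 40L)),
    "z range")
})

test_that("planted focus layer is recovered across random blurred stacks", {
  hits <- 0L
  for (i in 1:100) {
    fl <- ((i * 7) %% 7L) + 1L
    st <- make_blurred_stack(7, fl, seed = 1000 + i, nr = 32, nc = 32)
    got <- select_focus_layer(
      st, list(centre = c(x = 16, y = 16), z_min = 1L, z_max = 7L), window = 10)
    hits <- hits + (got == fl)
  }
  expect_gte(hits, 99L)
})

test_that("blurred-stack fixtures are deterministic in the seed", {
  expect_identical(make_blurred_stack(5, 3, seed = 9),
                   make_blurred_stack(5, 3, seed = 9))
})

test_that("crop geometry: interior crops, reflection padding and round trip", {
  set.seed(8)
  img <- matrix(runif(512 * 512), 512, 512)
  st <- array(img, dim = c(1, 512, 512))
  p <- crop_patch(st, centre = c(x = 256, y = 256), layer = 1, size = 224)
  expect_equal(dim(p), c(224, 224))
  expect_equal(p, img[(256 - 112 + 1):(256 + 112), (256 - 112 + 1):(256 + 112)])

  # centre at the (0,0) corner: explicit reflection index arithmetic
  small <- matrix(1:25, 5, 5)
  sst <- array(small, dim = c(1, 5, 5))
  p <- crop_patch(sst, centre = c(x = 0, y = 0), layer = 1, size = 5)
  # output rows come from 0-based indices -2:-2+4 = (-2,-1,0,1,2) -> rows 3,2,1,2,3
  expect_equal(p, small[c(3, 2, 1, 2, 3), c(3, 2, 1, 2, 3)])

  expect_equal(crop_patch(sst, c(x = 2, y = 3), 1, size = 1),
               small[4, 3, drop = FALSE])
  expect_error(crop_patch(sst, c(x = 1, y = 1), 1, size = 0), "parameter error")

  # round trip: embed a patch, crop at its centre, recover it exactly
  patch <- matrix(runif(49), 7, 7)
  big <- matrix(0, 64, 64)
  big[21:27, 31:37] <- patch
  bst <- array(big, dim = c(1, 64, 64))
  # patch centre pixel (0-based): row 21+3-1 = 23 -> y = 23; col 33 -> x = 33
  expect_equal(crop_patch(bst, c(x = 33, y = 23), 1, size = 7), patch)
})
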