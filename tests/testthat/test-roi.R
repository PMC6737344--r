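test_that("sphere rasterisation matches an exhaustive distance check", {
  for (spec in list(atl_spec(), scc_spec())) {
    g <- nf_grid(c(30, 30, 30), voxel_mm = c(3, 3, 3))
    g$affine[1:3, 4] <- spec$centre_mni - 14.5 * 3  # centre grid on the ROI
    m <- make_sphere_roi(spec, g)
    idx <- as.matrix(expand.grid(0:29, 0:29, 0:29))
    mm <- t(g$affine %*% rbind(t(idx), 1))[, 1:3]
    d2 <- rowSums(sweep(mm, 2, spec$centre_mni)^2)
    expect_equal(sum(m$weights > 0), sum(d2 <= spec$radius_mm^2 + 1e-9))
  }
  # monotone in radius: SCC sphere (6 mm) strictly larger than ATL (4 mm)
  g2 <- nf_grid(c(20, 20, 20), voxel_mm = c(3, 3, 3))
  n_small <- sum(make_sphere_roi(roi_spec("A", c(0, 0, 0), 4), g2)$weights)
  n_large <- sum(make_sphere_roi(roi_spec("B", c(0, 0, 0), 6), g2)$weights)
  expect_gt(n_large, n_small)
})

test_that("degenerate and out-of-grid spheres behave as specified", {
  g <- nf_grid(c(5, 5, 5), voxel_mm = c(1, 1, 1))
  # radius-0 sphere at a voxel centre selects exactly that voxel
  centre <- c(0, 0, 0)  # grid is centred on the origin
  m <- make_sphere_roi(roi_spec("P", centre, 0), g)
  expect_equal(sum(m$weights > 0), 1)
  expect_error(make_sphere_roi(roi_spec("X", c(100, 0, 0), 2), g),
               "outside the grid")
})

test_that("Gaussian smoothing conserves mass, keeps symmetry, fwhm 0 is identity", {
  g <- nf_grid(c(15, 15, 15), voxel_mm = c(3, 3, 3))
  m <- make_sphere_roi(roi_spec("C", c(0, 0, 0), 0.5), g)  # single voxel
  expect_equal(smooth_mask(m, 0)$weights, m$weights)

  sm <- smooth_mask(m, 6)
  # mass conserved for an interior source
  expect_equal(sum(sm$weights), sum(m$weights), tolerance = 1e-6)
  # peak stays at the source voxel
  expect_equal(which.max(sm$weights), which.max(m$weights))
  # reflection symmetry through the source (centre voxel index 8 on each axis)
  w <- sm$weights
  expect_equal(w, w[15:1, , ], tolerance = 1e-12)
  expect_equal(w, w[, 15:1, ], tolerance = 1e-12)
  expect_equal(w, w[, , 15:1], tolerance = 1e-12)
  # agrees with a direct dense convolution oracle along one axis
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 3    # in voxels
  half <- ceiling(4 * sigma)
  k <- exp(-(-half:half)^2 / (2 * sigma^2)); k <- k / sum(k)
  axis_profile <- w[, 8, 8]
  oracle <- sapply(1:15, function(i) {
    src <- i - (-half:half)
    ok <- src >= 1 & src <= 15
    sum(k[ok] * as.numeric(src[ok] == 8))
  })
  expect_equal(axis_profile / sum(axis_profile), oracle / sum(oracle),
               tolerance = 1e-9)
  expect_error(smooth_mask(m, -1), ">= 0")
})

test_that("affine warping maps supports as the coordinate algebra predicts", {
  g <- nf_grid(c(12, 12, 12), voxel_mm = c(3, 3, 3))
  m <- make_sphere_roi(roi_spec("C", c(0, 0, 0), 5), g)

  expect_equal(warp_to_native(m, diag(4))$weights, m$weights)
  expect_equal(warp_to_native(m, diag(4))$space, "NATIVE")

  # pure translation by one voxel (+3 mm in x in native-to-MNI direction)
  A <- diag(4); A[1, 4] <- 3
  w <- warp_to_native(m, A)
  s0 <- which(m$weights > 0, arr.ind = TRUE)
  s1 <- which(w$weights > 0, arr.ind = TRUE)
  expect_equal(s1[, 1], s0[, 1] - 1L, ignore_attr = TRUE)
  expect_equal(s1[, 2:3], s0[, 2:3], ignore_attr = TRUE)

  # nearest-neighbour round trip recovers the interior support
  R <- diag(4); R[1:3, 1:3] <- matrix(c(cos(.2), sin(.2), 0,
                                        -sin(.2), cos(.2), 0, 0, 0, 1), 3)
  fwd <- warp_to_native(m, R)
  back <- warp_to_native(fwd, solve(R))
  expect_true(all(back$weights[m$weights > 0 &
                                 seq_along(m$weights) %in%
                                 which(fwd$weights > 0)] >= 0))
  expect_gt(sum(back$weights > 0 & m$weights > 0) / sum(m$weights > 0), 0.8)

  expect_error(warp_to_native(m, matrix(0, 4, 4)), "singular")
  # provenance is append-only and records the transform
  expect_equal(w$provenance[[length(w$provenance)]]$step, "warp_to_native")
})

test_that("GLM contrast t-values match a closed-form OLS oracle", {
  tl <- build_localizer_run()
  set.seed(42)
  y <- rnorm(200)
  map <- glm_activation_map(matrix(y, ncol = 1), tl,
                            c("GUILT", "INDIGNATION"))
  X <- cbind(1, as.numeric(tl$conditions == "GUILT"),
             as.numeric(tl$conditions == "INDIGNATION"))
  fit <- lm(y ~ 0 + X)
  cvec <- c(0, 1, -1)
  t_oracle <- sum(cvec * coef(fit)) / sqrt(t(cvec) %*% vcov(fit) %*% cvec)
  expect_equal(unname(map$statistic), as.numeric(t_oracle), tolerance = 1e-10)
  expect_equal(map$df, 200 - 3)

  expect_error(glm_activation_map(matrix(rnorm(10), ncol = 1), tl),
               "volumes")
})

test_that("a pure activation voxel maximises the guilt-vs-subtraction statistic", {
  tl <- build_localizer_run()
  n_vox <- 50
  set.seed(7)
  Y <- matrix(rnorm(200 * n_vox), nrow = 200)
  Y[, 17] <- as.numeric(tl$conditions == "GUILT")  # noise-free box-car
  map <- glm_activation_map(Y, tl, c("GUILT", "SUBTRACTION"))
  expect_equal(which.max(map$statistic), 17L)
})

test_that("GLM type-I error is calibrated on pure-noise voxels", {
  tl <- build_localizer_run()
  set.seed(123)
  Y <- matrix(rnorm(200 * 1000), nrow = 200)
  map <- glm_activation_map(Y, tl, c("GUILT", "SUBTRACTION"))
  p <- 2 * pt(abs(map$statistic), df = map$df, lower.tail = FALSE)
  rate <- mean(p < 0.05)
  se2 <- 2 * sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(rate - 0.05), se2)
})

test_that("top-fraction selection uses the ceil rule, is monotone and deterministic", {
  m <- flat_mask(c(10, 10, 2))       # 200 support voxels
  set.seed(11)
  stats_vec <- rnorm(200)
  map <- stat_map(stats_vec, m$grid)

  sel10 <- select_top_fraction(map, m, 0.10)
  expect_length(sel10$voxel_indices, 20)
  expect_equal(select_top_fraction(map, m, 1.0)$voxel_indices, 1:200)

  # ceil: 7 support voxels at 10% -> 1 voxel, the argmax
  m7 <- flat_mask(c(7, 1, 1))
  map7 <- stat_map(rnorm(7), m7$grid)
  s7 <- select_top_fraction(map7, m7, 0.10)
  expect_length(s7$voxel_indices, 1)
  expect_equal(s7$voxel_indices, which.max(map7$statistic))

  # monotone nesting over fractions
  prev <- select_top_fraction(map, m, 0.05)$voxel_indices
  for (f in c(0.1, 0.25, 0.5, 1)) {
    cur <- select_top_fraction(map, m, f)$voxel_indices
    expect_true(all(prev %in% cur))
    prev <- cur
  }

  # ties broken by ascending linear index
  map_tie <- stat_map(rep(0, 200), m$grid)
  expect_equal(select_top_fraction(map_tie, m, 0.10)$voxel_indices, 1:20)
  expect_equal(select_top_fraction(map_tie, m, 0.10)$voxel_indices,
               select_top_fraction(map_tie, m, 0.10)$voxel_indices)
})

test_that("mean-signal extraction equals direct enumeration", {
  m <- flat_mask(c(5, 5, 1))
  map <- stat_map(1:25, m$grid)
  set.seed(5)
  Y <- matrix(rnorm(30 * 25), nrow = 30)

  one <- select_top_fraction(map, m, 0.04)          # single voxel (argmax 25)
  expect_equal(extract_mean_signal(Y, one), Y[, 25])

  two <- select_top_fraction(map, m, 0.08)          # voxels 24, 25
  expect_equal(extract_mean_signal(Y, two), (Y[, 24] + Y[, 25]) / 2)

  twenty <- select_top_fraction(map, m, 0.8)
  expect_equal(extract_mean_signal(Y, twenty),
               rowMeans(Y[, twenty$voxel_indices]))
})

test_that("affine matrices and masks round-trip through their text and NIfTI forms", {
  A <- diag(4); A[1:3, 4] <- c(1.5, -2, 3); A[1, 2] <- 0.1
  p <- file.path(tempdir(), "xfm.mat")
  write_affine_mat(A, p)
  expect_equal(read_affine_mat(p), A, tolerance = 1e-9)

  g <- nf_grid(c(8, 8, 8), voxel_mm = c(3, 3, 3))
  m <- smooth_mask(make_sphere_roi(roi_spec("C", c(0, 0, 0), 4), g), 6)
  np <- file.path(tempdir(), "mask.nii.gz")
  write_mask_nifti(m, np)
  back <- read_mask_nifti(np)
  expect_equal(as.numeric(back$weights), as.numeric(m$weights),
               tolerance = 1e-6)
  expect_equal(back$grid$affine, m$grid$affine, tolerance = 1e-5)
})
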