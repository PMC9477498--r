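test_that("nuisance regression matches per-voxel least squares", {
  set.seed(21)
  n <- 20; V <- 50
  vals <- matrix(rnorm(n * V), n, V)
  cov <- data.frame(age = rnorm(n, 70, 5),
                    gender = sample(c("M", "F"), n, TRUE),
                    edu = rnorm(n, 16, 2))
  res <- regress_nuisance(vals, cov)
  # brute-force per-voxel OLS residuals
  mm <- model.matrix(~ age + gender + edu, cov)
  for (v in seq(1, V, by = 7)) {
    ref <- residuals(lm.fit(mm, vals[, v]))
    expect_equal(res[, v], ref, tolerance = 1e-8, ignore_attr = TRUE)
  }
  # residuals orthogonal to every covariate column
  expect_lt(max(abs(crossprod(mm, res))), 1e-8)
})

test_that("degenerate nuisance designs behave as specified", {
  set.seed(22)
  vals <- matrix(rnorm(30), 10, 3)
  # covariate identical to a voxel column: residual column is zero
  cov <- data.frame(z = vals[, 2])
  res <- regress_nuisance(vals, cov)
  expect_lt(max(abs(res[, 2])), 1e-12)
  # covariates orthogonal to the data: only mean-centering happens
  x <- rnorm(10); x <- x - mean(x)
  y <- rnorm(10); y <- y - mean(y)
  y <- y - sum(x * y) / sum(x^2) * x # orthogonalise
  res2 <- regress_nuisance(matrix(y, 10, 1), data.frame(x = x))
  expect_equal(res2[, 1], y, tolerance = 1e-10)
  # collinear design named
  cov3 <- data.frame(a = 1:10, b = 2 * (1:10))
  expect_error(regress_nuisance(vals, cov3), "collinear")
})

test_that("TFCE equals brute-force per-threshold cluster enumeration", {
  set.seed(23)
  for (rep in 1:4) {
    m <- array(0, c(8, 8, 1))
    # sparse random heights with plateaus and multiple clusters
    hot <- sample(64, 20)
    m[hot] <- sample(c(1, 1.5, 2, 3), 20, TRUE)
    dh <- max(m) / 25
    got <- tfce(m, E = 0.5, H = 2, dh = dh)
    ref <- tfce_brute(m, E = 0.5, H = 2, dh = dh)
    expect_equal(got, as.numeric(ref), tolerance = 1e-8)
  }
})

test_that("TFCE limits and degenerate inputs", {
  z <- array(0, c(6, 6, 2))
  expect_equal(tfce(z), numeric(72))
  # isolated voxel: sum_h h^H dh -> h0^(H+1)/(H+1) as dh -> 0
  m <- array(0, c(8, 8, 1)); m[4, 4, 1] <- 1.7
  fine <- max(tfce(m, dh = 1.7 / 4000, H = 2, E = 0.5))
  expect_equal(fine, 1.7^3 / 3, tolerance = 1e-3)
  expect_error(tfce(m, dh = -1), "dh")
})

test_that("TFCE is monotone under pointwise scaling", {
  set.seed(24)
  m <- array(rexp(8 * 8 * 2), c(8, 8, 2))
  e1 <- tfce(m, n_steps = 50)
  e2 <- tfce(2 * m, n_steps = 50)
  expect_true(all(e2 >= e1 - 1e-12))
})

test_that("sphere masks equal brute-force distance enumeration", {
  grid <- brain_grid(c(10, 10, 10), voxel_mm = 2)
  xyz <- stagenet:::grid_coords(grid)
  set.seed(25)
  for (rep in 1:3) {
    ctr <- runif(3, -6, 6)
    got <- sphere_mask(grid, ctr, 4)
    ref <- sqrt(colSums((t(xyz) - ctr)^2)) <= 4
    expect_equal(got, ref)
  }
})

test_that("copied groups yield no significant voxels", {
  co <- small_cohort()
  idx <- which(co$phenotypes$diagnosis == "CN")
  im <- image_matrix(co$gmv$values[idx, ], co$grid, modality = "GMV")
  res <- permutation_contrast(im, im, n_perm = 99, seed = 1)
  expect_true(all(res$p_fwe > 0.05))
  expect_true(all(res$p_fwe >= 1 / 100))
  expect_equal(sum(res$threshold_mask), 0)
})

test_that("planted focal atrophy is detected and FWE is controlled", {
  set.seed(26)
  grid <- brain_grid(c(8, 8, 1), voxel_mm = 2)
  # 2-SD focal effect at a 2x2 patch, 30 per group
  n <- 30
  mk <- function(shift) {
    v <- matrix(rnorm(n * 64), n, 64)
    if (shift) v[, c(28, 29, 36, 37)] <- v[, c(28, 29, 36, 37)] + 2
    v
  }
  a <- image_matrix(mk(TRUE), grid, modality = "GMV")
  b <- image_matrix(mk(FALSE), grid, modality = "GMV")
  res <- permutation_contrast(a, b, n_perm = 299, seed = 2)
  expect_true(all(res$threshold_mask[c(28, 29, 36, 37)]))

  # family-wise error under a global null, 200 replicates
  hits <- vapply(1:200, function(r) {
    a0 <- image_matrix(matrix(rnorm(20 * 64), 20, 64), grid,
                       modality = "GMV")
    b0 <- image_matrix(matrix(rnorm(20 * 64), 20, 64), grid,
                       modality = "GMV")
    any(permutation_contrast(a0, b0, n_perm = 99,
                             seed = 1000 + r)$threshold_mask)
  }, logical(1))
  rate <- mean(hits)
  expect_lt(rate, 0.05 + 2.5 * sqrt(0.05 * 0.95 / 200))
  expect_gt(rate, 0.0) # the test has power to reject at all
})

test_that("peak extraction finds planted foci and reports absences", {
  grid <- brain_grid(c(24, 24, 24), voxel_mm = 4)
  loci <- default_loci()
  # synthetic thresholded t maps: one Gaussian blob per locus
  field <- rep(0, grid$n_voxels)
  for (i in seq_len(nrow(loci)))
    field <- field + 5 * stagenet:::gaussian_pattern(
      grid, as.numeric(loci[i, c("x", "y", "z")]), 6)
  seeds <- combine_and_peak(field, field, loci, grid,
                            search_radius_mm = 12)
  expect_equal(nrow(seeds), 12)
  # peaks at the planted centres (within one voxel)
  d <- sqrt((seeds$x - loci$x[match(seeds$name, loci$name)])^2 +
              (seeds$y - loci$y[match(seeds$name, loci$name)])^2 +
              (seeds$z - loci$z[match(seeds$name, loci$name)])^2)
  expect_true(all(d <= 4))
  # 4 mm sphere masks equal brute-force enumeration and are disjoint
  for (i in c(1, 11)) {
    ref <- sphere_mask(grid, c(seeds$x[i], seeds$y[i], seeds$z[i]), 4)
    expect_equal(seeds$mask[[i]], ref)
  }
  any_overlap <- FALSE
  for (i in seq_len(nrow(seeds) - 1))
    for (j in (i + 1):nrow(seeds))
      any_overlap <- any_overlap ||
        any(seeds$mask[[i]] & seeds$mask[[j]])
  expect_false(any_overlap)

  # a region whose neighbourhood holds no significant voxel is absent
  field2 <- field
  far <- sqrt(rowSums(sweep(stagenet:::grid_coords(grid), 2,
                            c(-24, -16, -16))^2)) < 14
  field2[far] <- 0
  expect_warning(
    seeds2 <- combine_and_peak(field2, field2, loci, grid,
                               search_radius_mm = 12),
    "HIP_L")
  expect_equal(nrow(seeds2), 11)
  expect_equal(attr(seeds2, "absent"), "HIP_L")
})
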