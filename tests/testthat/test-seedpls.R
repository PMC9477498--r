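test_that("seed values are masked means", {
  grid <- brain_grid(c(4, 4, 1), voxel_mm = 2)
  sph <- rep(FALSE, 16); sph[c(6, 7)] <- TRUE
  vals <- matrix(0, 3, 16)
  vals[1, ] <- 5                 # constant image -> constant seed value
  vals[2, c(6, 7)] <- c(1, 3)    # two-voxel seed -> mean 2
  vals[3, ] <- rnorm(16)
  im <- image_matrix(vals, grid, modality = "FDG")
  Y <- extract_seed_values(im, sph)
  expect_equal(Y[1], 5)
  expect_equal(Y[2], 2)
  expect_equal(Y[3], mean(vals[3, c(6, 7)])) # brute-force masked mean
  expect_error(extract_seed_values(im, rep(FALSE, 16)), "empty")
})

test_that("correlation vector is exact Pearson correlation", {
  set.seed(41)
  n <- 30
  Y <- rnorm(n)
  X <- matrix(rnorm(n * 10), n, 10)
  X[, 1] <- Y
  X[, 2] <- -Y
  R <- correlation_vector(Y, X)
  expect_equal(R[1], 1, tolerance = 1e-12)
  expect_equal(R[2], -1, tolerance = 1e-12)
  ref <- as.numeric(cor(Y, X)) # textbook oracle
  expect_equal(as.numeric(R), ref, tolerance = 1e-10)
  expect_true(all(R >= -1 & R <= 1))
  # constant voxel columns give 0 with a reported count
  X[, 3] <- 7
  expect_warning(R2 <- correlation_vector(Y, X), "constant")
  expect_equal(R2[3], 0)
  expect_equal(attr(R2, "n_constant"), 1L)
  expect_error(correlation_vector(Y[1:2], X[1:2, ]), "3 subjects")
})

test_that("single-seed SVD has the rank-1 closed form", {
  lv <- pls_svd(c(0.6, 0.8))[[1]]
  expect_equal(lv$s, 1.0, tolerance = 1e-12)
  expect_equal(lv$u, c(0.6, 0.8), tolerance = 1e-12)
  expect_equal(lv$v, 1, tolerance = 1e-12)
  set.seed(42)
  for (i in 1:10) {
    R <- rnorm(25)
    lv <- pls_svd(R)[[1]]
    expect_equal(lv$u * lv$v, R / sqrt(sum(R^2)), tolerance = 1e-12)
    expect_equal(lv$s, sqrt(sum(R^2)), tolerance = 1e-12)
    expect_equal(sum(lv$u^2), 1, tolerance = 1e-12)
  }
  # matrix case: orthonormal saliences, energy identity, decreasing s
  Rm <- matrix(rnorm(3 * 40), 3, 40)
  lvs <- pls_svd(Rm)
  U <- vapply(lvs, `[[`, numeric(40), "u")
  expect_equal(crossprod(U), diag(3), tolerance = 1e-10)
  s <- vapply(lvs, `[[`, numeric(1), "s")
  expect_true(all(diff(s) <= 0))
  expect_equal(sum(s^2), sum(Rm^2), tolerance = 1e-10)
  # degenerate input flagged
  expect_true(pls_svd(rep(0, 5))[[1]]$degenerate)
})

test_that("latent-variable permutation p has the correct lower bound", {
  set.seed(43)
  n <- 40
  u <- rnorm(30); u <- u / sqrt(sum(u^2))
  lat <- rnorm(n)
  X <- outer(lat, u) + matrix(rnorm(n * 30, sd = 0.1), n, 30)
  res <- permute_lv(lat, X, n_perm = 199, seed = 9)
  expect_equal(res$p, 1 / 200) # planted covariance saturates the test
  expect_gte(res$p, 1 / (199 + 1))
  expect_length(res$s_null, 199)
})

test_that("bootstrap ratios are sign-alignment invariant and calibrated", {
  set.seed(44)
  n <- 200
  u <- c(rep(0.4, 5), rep(0, 45)); u <- u / sqrt(sum(u^2))
  lat <- rnorm(n)
  X <- outer(lat, u) + matrix(rnorm(n * 50), n, 50)
  Y <- lat + rnorm(n, sd = 0.5)
  bsr <- bootstrap_bsr(Y, X, n_boot = 100, seed = 5)
  # planted support reliable, pure-noise voxels not
  expect_true(all(abs(bsr[1:5]) > 3))
  expect_lt(mean(abs(bsr[6:50])), 2)
  # global sign flip of the data leaves |bsr| unchanged
  bsr_flip <- bootstrap_bsr(Y, -X, n_boot = 100, seed = 5)
  expect_equal(abs(bsr_flip), abs(bsr), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("network scores are projections, bilaterally averaged, z-scored", {
  grid <- brain_grid(c(4, 4, 1), voxel_mm = 2)
  set.seed(45)
  u <- rnorm(16); u <- u / sqrt(sum(u^2))
  a <- c(1, 2, 4) # subject expression levels; map_i = a_i * u
  vals <- outer(a, u)
  im <- image_matrix(vals, grid, modality = "GMV",
                     subject_ids = c("s1", "s2", "s3"))
  lv <- structure(list(u = u, v = 1, s = 1, p_perm = 0.001),
                  class = "latent_variable")
  cohort <- list(gmv = im, fdg = im,
                 phenotypes = tibble::tibble(id = c("s1", "s2", "s3"),
                                             diagnosis = c("CN", "CN",
                                                           "AD")))
  pls_tbl <- tibble::tibble(seed = "HIP_L", modality = "GMV",
                            s = 1, p_perm = 0.001, lv = list(lv))
  sc <- compute_network_scores(cohort, pls_tbl)
  # raw projection X u = a (projection identity + linearity), then z
  expect_equal(sc$HIP_GMV, as.numeric(scale(a)), tolerance = 1e-10)

  # bilateral averaging: left/right homologues averaged before z-scoring
  lv_r <- structure(list(u = u, v = 1, s = 1, p_perm = 0.001),
                    class = "latent_variable")
  pls2 <- tibble::tibble(seed = c("HIP_L", "HIP_R"), modality = "GMV",
                         s = 1, p_perm = 0.001, lv = list(lv, lv_r))
  sc2 <- compute_network_scores(cohort, pls2)
  expect_equal(sc2$HIP_GMV, sc$HIP_GMV, tolerance = 1e-10)
  expect_named(sc2, c("id", "HIP_GMV"))

  # CN reference: z-scale anchored on the CN subjects only
  sc_cn <- compute_network_scores(cohort, pls_tbl, reference_group = "CN")
  ref <- (a - mean(a[1:2])) / sd(a[1:2])
  expect_equal(sc_cn$HIP_GMV, ref, tolerance = 1e-10)

  # non-significant latent variables are dropped with a warning
  pls_ns <- pls_tbl; pls_ns$p_perm <- 0.5
  expect_warning(sc_ns <- compute_network_scores(cohort, pls_ns),
                 "non-significant")
  expect_named(sc_ns, "id")
})

test_that("full seed-PLS recovers the planted covariance structure", {
  co <- default_cohort() # n = 405 at default SNR
  sph <- sphere_mask(co$grid, c(-24, -16, -16), 4)
  Y <- extract_seed_values(co$gmv, sph)
  u <- pls_svd(correlation_vector(Y, co$gmv$values))[[1]]$u

  # closed-form population correlation map (the planted pattern in
  # covariance space): loadings share the stage gradient across networks
  cfg <- co$config
  vmu <- mean((cfg$loading_mu - mean(cfg$loading_mu))^2)
  S <- diag(7) * cfg$loading_sd^2 + vmu
  P <- co$truth$patterns
  m <- sum(sph)
  w <- as.numeric(P[, sph[co$gmv$mask]] %*% rep(1 / m, m))
  cov_sv <- as.numeric(t(w) %*% S %*% P)
  var_s <- as.numeric(t(w) %*% S %*% w) + cfg$noise_sd^2 / m +
    cfg$site_sd^2 / 1e6 # site offsets independent between seed and voxel
  var_v <- colSums(P * (S %*% P)) + cfg$noise_sd^2 + cfg$site_sd^2
  r_implied <- cov_sv / sqrt(var_s * var_v)
  expect_gt(abs(cor(u, r_implied)), 0.9)

  # projection scores invariant to a consistent voxel permutation
  perm <- sample(ncol(co$gmv$values))
  expect_equal(co$gmv$values[, perm] %*% u[perm], co$gmv$values %*% u,
               tolerance = 1e-12)
})
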