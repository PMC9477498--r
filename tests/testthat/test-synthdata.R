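test_that("identical seeds give bit-identical cohorts", {
  cfg <- sim_config(n_per_cell = 4, rng_seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$gmv$values, b$gmv$values)
  expect_identical(a$fdg$values, b$fdg$values)
  expect_identical(a$truth$loadings, b$truth$loadings)
})

test_that("every stage-by-pathology cell is filled as configured", {
  co <- small_cohort()
  tab <- table(co$phenotypes$stage, co$phenotypes$pathology)
  expect_true(all(tab == co$config$n_per_cell))
  expect_equal(dim(tab), c(3, 3))
})

test_that("generated CSF values reproduce the intended strata exactly", {
  co <- default_cohort()
  got <- stratify_pathology(co$phenotypes$csf_abeta, co$phenotypes$csf_ptau)
  expect_equal(as.character(got), as.character(co$phenotypes$pathology))
})

test_that("generated clinical scores are consistent with the stage labels", {
  co <- default_cohort()
  ph <- co$phenotypes
  rules <- classify_diagnosis(ph$mmse, ph$cdr_global, ph$cdr_sob)
  expect_equal(as.character(rules), ph$diagnosis)
})

test_that("a grid that cannot contain the loci is refused", {
  expect_error(generate_cohort(sim_config(grid_dims = c(8, 8, 8))),
               "grid too small")
  expect_error(sim_config(grid_dims = c(2, 2, 2)), "grid too small")
})

test_that("noiseless limit: seed and in-pattern voxels correlate to 1", {
  cfg <- sim_config(n_per_cell = 10, loading_sd = 0, noise_sd = 1e-8,
                    site_sd = 0, rng_seed = 7)
  co <- generate_cohort(cfg)
  sph <- sphere_mask(co$grid, c(-24, -16, -16), 4) # HIP_L focus
  Y <- extract_seed_values(co$gmv, sph)
  pat <- co$truth$patterns["HIP", ]
  vox <- which(pat > 0.5 & !sph[co$gmv$mask])
  for (v in vox[1:5])
    expect_gt(cor(Y, co$gmv$values[, v]), 0.999)
})

test_that("seed-voxel correlation matches the closed-form attenuation", {
  # single-site cohort; loading variance = loading_sd^2 + between-cell
  # spread of the stage means; seed averages m voxels so its noise
  # variance is noise_sd^2/m; all networks share the stage gradient, which
  # couples their loadings
  cfg <- sim_config(n_per_cell = 45, n_sites = 1, site_sd = 0,
                    rng_seed = 31)
  co <- generate_cohort(cfg) # n = 405
  sph <- sphere_mask(co$grid, c(-24, -16, -16), 4)
  Y <- extract_seed_values(co$gmv, sph)
  mu <- cfg$loading_mu
  vmu <- mean((mu - mean(mu))^2)
  S <- diag(7) * cfg$loading_sd^2 + vmu      # loading covariance
  P <- co$truth$patterns                      # regions x voxels
  m <- sum(sph)
  w <- as.numeric(P[, sph[co$gmv$mask]] %*% rep(1 / m, m))
  var_seed <- as.numeric(t(w) %*% S %*% w) + cfg$noise_sd^2 / m
  pat <- P["HIP", ]
  vox <- which(pat > 0.6 & !sph[co$gmv$mask])
  for (v in vox[seq(1, length(vox), length.out = 6)]) {
    pv <- P[, v]
    r_theory <- as.numeric(t(w) %*% S %*% pv) /
      sqrt(var_seed * (as.numeric(t(pv) %*% S %*% pv) + cfg$noise_sd^2))
    expect_lt(abs(cor(Y, co$gmv$values[, v]) - r_theory), 0.1)
  }
})

test_that("null coefficient curves give memory unrelated to predictors", {
  cfg <- sim_config(n_per_cell = 45, rng_seed = 17)
  beta0 <- cfg$beta_truth * 0
  co <- generate_cohort(sim_config(n_per_cell = 45, rng_seed = 17,
                                   beta_truth = beta0,
                                   memory_noise_sd = 1), images = FALSE)
  x <- co$truth$x_std
  r <- abs(cor(co$phenotypes$memory, x))
  expect_true(all(r < 0.15)) # n = 405
})

test_that("noiseless memory is exactly the planted linear combination", {
  cfg <- sim_config(n_per_cell = 10, rng_seed = 13)
  co <- generate_cohort(sim_config(n_per_cell = 10, rng_seed = 13,
                                   memory_noise_sd = 1e-12),
                        images = FALSE)
  staged <- stage_cohort(co$phenotypes, bin_size = co$config$bin_size)
  staged <- staged[match(co$phenotypes$id, staged$id), ]
  bt <- co$truth$beta_truth
  pred <- rowSums(co$truth$x_std[, rownames(bt)] *
                    t(bt)[staged$bin, , drop = FALSE])
  expect_equal(co$phenotypes$memory, round(pred, 6), tolerance = 1e-5)
})

test_that("per-bin OLS slopes track a decreasing planted curve", {
  # one pathology group, beta declining 0.8 -> 0.2; regress memory on the
  # planted predictor inside coarse bin blocks and compare with truth
  co <- tabular_cohort()
  ph <- co$phenotypes
  sel <- ph$pathology == "A+"
  staged <- stage_cohort(ph[sel, ], bin_size = 10)
  x <- co$truth$x_std[match(staged$id, ph$id), "HIP_GMV"]
  y <- staged$memory
  bt <- co$truth$beta_truth["HIP_GMV", ]
  # blocks of 5 bins -> 50 subjects each, enough for a stable slope
  blocks <- split(seq_len(nrow(staged)), (staged$bin - 1) %/% 5)
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    slope <- coef(lm(y[idx] ~ x[idx]))[2]
    expect_lt(abs(slope - mean(bt[unique(staged$bin[idx])])), 0.25)
  }
})

test_that("cohort fixtures round-trip through NIfTI + TSV + JSON", {
  co <- generate_cohort(sim_config(n_per_cell = 1, rng_seed = 5,
                                   grid_dims = c(24, 24, 24)))
  dir <- withr::local_tempdir()
  write_cohort_fixture(co, dir)
  # 9 subjects x 2 modalities + phenotypes + truth
  expect_length(list.files(dir, pattern = "\\.nii$"), 18)
  expect_true(file.exists(file.path(dir, "phenotypes.tsv")))
  back <- read_cohort_fixture(dir)
  expect_equal(back$phenotypes$id, co$phenotypes$id)
  expect_equal(back$gmv$values, co$gmv$values, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$fdg$values, co$fdg$values, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$truth$loadings, co$truth$loadings, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$grid$affine, co$grid$affine, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("an empty or imageless cohort cannot be written", {
  co <- small_cohort()
  co_empty <- co
  co_empty$phenotypes <- co$phenotypes[0, ]
  expect_error(write_cohort_fixture(co_empty, tempfile()), "empty")
  co_tab <- generate_cohort(sim_config(n_per_cell = 2, rng_seed = 1),
                            images = FALSE)
  expect_error(write_cohort_fixture(co_tab, tempfile()), "images")
})
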