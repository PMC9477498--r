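test_that("spline basis: partition of unity, shape, polynomial span", {
  b <- build_basis(20, 6)
  expect_equal(dim(b$B), c(20, 6))
  expect_equal(rowSums(b$B), rep(1, 20), tolerance = 1e-12)
  expect_true(isSymmetric(b$Omega))
  expect_true(all(eigen(b$Omega, only.values = TRUE)$values > 0))
  # M = degree + 1 with no interior knots spans cubics exactly
  b4 <- build_basis(12, 4)
  t <- 1:12
  cubic <- 2 - 0.3 * t + 0.05 * t^2 - 0.002 * t^3
  fit <- lm.fit(b4$B, cubic)
  expect_lt(max(abs(fit$residuals)), 1e-10)
  expect_error(build_basis(4, 6), "K")
  expect_error(build_basis(10, 3, degree = 3), "degree")
})

test_that("standardisation is per group, refuses degenerate columns", {
  y <- c(1, 2, 3)
  X <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "a"))
  std <- standardize_inputs(y, X)
  expect_equal(as.numeric(std$X), c(-1, 0, 1))
  expect_equal(std$y, c(-1, 0, 1))
  # already standardised input is unchanged
  std2 <- standardize_inputs(std$y, std$X)
  expect_equal(std2$X, std$X, tolerance = 1e-12)
  # two groups centred independently
  g <- factor(c("p", "p", "p", "q", "q", "q"))
  X2 <- matrix(c(1, 2, 3, 10, 20, 30), 6, 1, dimnames = list(NULL, "a"))
  std3 <- standardize_inputs(rnorm(6), X2, g)
  expect_equal(mean(std3$X[1:3, 1]), 0, tolerance = 1e-12)
  expect_equal(mean(std3$X[4:6, 1]), 0, tolerance = 1e-12)
  expect_equal(sd(std3$X[4:6, 1]), 1, tolerance = 1e-12)
  X2[4:6, 1] <- 5
  expect_error(standardize_inputs(rnorm(6), X2, g), "constant")
})

# shared small regression problem with one stage-varying signal
svc_problem <- function(n = 200, K = 20, p = 6, noise = 0.5, seed = 61) {
  set.seed(seed)
  bins <- rep(seq_len(K), each = n / K)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  beta1 <- seq(1, 0.2, length.out = K)
  y <- X[, 1] * beta1[bins] + rnorm(n, sd = noise)
  std <- standardize_inputs(y, X)
  list(y = std$y, X = std$X, bins = bins, basis = build_basis(K, 6),
       beta1 = beta1)
}

test_that("ridge at lambda 0 equals the least-squares solution", {
  pb <- svc_problem()
  f <- fit_svc(pb$y, pb$X, pb$bins, pb$basis, lambda = 0,
               penalty = "ridge")
  Z <- stagenet:::svc_design(pb$X, pb$bins, pb$basis, reparam = FALSE)
  ols <- qr.solve(Z, pb$y) # normal-equations oracle
  expect_equal(as.numeric(t(f$gamma)), as.numeric(ols),
               tolerance = 1e-6)
})

test_that("group lasso satisfies its KKT conditions", {
  pb <- svc_problem()
  lmax <- svc_lambda_max(pb$y, pb$X, pb$bins, pb$basis)
  # at or above lambda_max every group is zero
  f0 <- fit_svc(pb$y, pb$X, pb$bins, pb$basis, lmax * 1.0001)
  expect_length(f0$selected, 0)
  expect_true(all(abs(f0$gamma) == 0))
  # just below, something activates
  f1 <- fit_svc(pb$y, pb$X, pb$bins, pb$basis, lmax * 0.95)
  expect_gt(length(f1$selected), 0)
  # KKT residuals within tolerance at several penalties
  for (frac in c(0.5, 0.2, 0.05)) {
    f <- fit_svc(pb$y, pb$X, pb$bins, pb$basis, lmax * frac)
    expect_true(f$converged)
    expect_lt(max(f$kkt), 1e-4)
    # objective never above the all-zero objective
    f_zero_obj <- sum(pb$y^2) / (2 * length(pb$y))
    expect_lte(f$objective, f_zero_obj)
  }
})

test_that("active sets are nested along a warm-started penalty path", {
  pb <- svc_problem()
  lmax <- svc_lambda_max(pb$y, pb$X, pb$bins, pb$basis)
  grid <- lambda_grid(lmax, n_lambda = 20, ratio = 0.01)
  fits <- stagenet:::fit_svc_path(pb$y, pb$X, pb$bins, pb$basis, grid)
  sizes <- lengths(lapply(fits, `[[`, "selected"))
  expect_true(all(diff(sizes) >= 0))
})

test_that("a single planted predictor is recovered with its curve", {
  pb <- svc_problem(n = 300, K = 30, noise = 0.5)
  lmax <- svc_lambda_max(pb$y, pb$X, pb$bins, pb$basis)
  f <- fit_svc(pb$y, pb$X, pb$bins, pb$basis, lmax * 0.2)
  expect_equal(f$selected, "x1")
  expect_gt(cor(f$beta_curves["x1", ], pb$beta1), 0.9)
})

test_that("ridge and group lasso agree on the dominant predictor", {
  pb <- svc_problem(n = 300, K = 30, noise = 0.5)
  lmax <- svc_lambda_max(pb$y, pb$X, pb$bins, pb$basis)
  gl <- fit_svc(pb$y, pb$X, pb$bins, pb$basis, lmax * 0.2)
  rg <- fit_svc(pb$y, pb$X, pb$bins, pb$basis, lmax * 0.2,
                penalty = "ridge")
  norms <- sqrt(rowSums((rg$gamma %*% pb$basis$Omega_half)^2))
  expect_equal(names(which.max(norms)), gl$selected)
})

test_that("cross-validation selects a workable penalty", {
  pb <- svc_problem()
  # singleton grid returns that lambda
  cv1 <- cv_lambda(pb$y, pb$X, pb$bins, pb$basis, grid = 0.05, seed = 1)
  expect_equal(cv1$lambda, 0.05)
  # argmin property under the "min" rule
  cv <- cv_lambda(pb$y, pb$X, pb$bins, pb$basis, n_lambda = 15,
                  rule = "min", seed = 2)
  expect_equal(min(cv$cv_error$mse),
               cv$cv_error$mse[cv$cv_error$lambda == cv$lambda])
  # 1-SE rule never chooses a smaller penalty than the minimiser
  cv1se <- cv_lambda(pb$y, pb$X, pb$bins, pb$basis, n_lambda = 15,
                     seed = 2)
  expect_gte(cv1se$lambda, cv$lambda)
  # the selected penalty retains the true predictor
  f <- fit_svc(pb$y, pb$X, pb$bins, pb$basis, cv1se$lambda)
  expect_true("x1" %in% f$selected)
  # fold assignment is stratified by bin
  expect_true(all(tapply(cv$folds, pb$bins,
                         function(f) length(unique(f))) >= 2))
})

test_that("noiseless truth is selected in every repetition", {
  pb <- svc_problem(n = 120, K = 12, p = 4, noise = 1e-8, seed = 62)
  sm <- repeat_and_summarize(pb$y, pb$X, pb$bins, pb$basis, n_rep = 8,
                             threshold = 7, n_lambda = 15, base_seed = 3)
  fr <- sm$frequency
  expect_equal(fr$n_selected[fr$predictor == "x1"], 8L)
  expect_true(all(fr$n_selected[fr$predictor != "x1"] == 0L))
  expect_true(all(fr$n_selected >= 0 & fr$n_selected <= 8))
  expect_true(fr$kept[fr$predictor == "x1"])
})

test_that("selection frequencies and curve bands summarise repetitions", {
  pb <- svc_problem(n = 200, K = 20, noise = 0.5, seed = 63)
  sm <- repeat_and_summarize(pb$y, pb$X, pb$bins, pb$basis, n_rep = 10,
                             threshold = 9, n_lambda = 15, base_seed = 4)
  tb <- tidy(sm)
  expect_true(all(c("predictor", "bin", "mean", "se", "n_selected",
                    "kept") %in% names(tb)))
  expect_true(all(sm$frequency$n_selected <= 10))
  x1 <- tb[tb$predictor == "x1", ]
  expect_gt(cor(x1$mean, pb$beta1), 0.85)
  expect_true(all(x1$se >= 0))
  g <- glance(sm)
  expect_equal(g$n_rep, 10)
})

test_that("the identity permutation reproduces the original summary", {
  pb <- svc_problem(n = 100, K = 10, p = 3, seed = 64)
  base <- 70L
  ref <- repeat_and_summarize(pb$y, pb$X, pb$bins, pb$basis, n_rep = 3,
                              threshold = 2, n_lambda = 10,
                              base_seed = base + 1000L)
  spec <- permutation_specificity(pb$y, pb$X, pb$bins, pb$basis,
                                  n_perm_datasets = 1, n_rep = 3,
                                  threshold = 2, n_lambda = 10,
                                  base_seed = base, identity = TRUE)
  expect_equal(spec$n_selected, ref$frequency$n_selected)
  expect_equal(spec$predictor, ref$frequency$predictor)
})

test_that("basis size barely moves the recovered coefficient curve", {
  pb <- svc_problem(n = 300, K = 30, noise = 0.5, seed = 65)
  for (M in c(4, 6, 8, 10)) {
    basis <- build_basis(30, M)
    lmax <- svc_lambda_max(pb$y, pb$X, pb$bins, basis)
    f <- fit_svc(pb$y, pb$X, pb$bins, basis, lmax * 0.2)
    expect_true("x1" %in% f$selected)
    expect_gt(cor(f$beta_curves["x1", ], pb$beta1), 0.85)
  }
})
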