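#' Mean image value within a seed
#'
#' The seed value of a participant is the average of their map over the
#' seed's voxels.
#'
#' @param images An [image_matrix()].
#' @param seed Logical full-grid mask, or one row of a seed tibble from
#'   [combine_and_peak()].
#' @return Numeric vector, one value per subject.
#' @export
extract_seed_values <- function(images, seed) {
  if (is.data.frame(seed)) seed <- seed$mask[[1]]
  seed_in_mask <- seed[images$mask]
  if (!any(seed_in_mask)) abort("empty seed")
  rowMeans(images$values[, seed_in_mask, drop = FALSE])
}

#' Seed-brain correlation vector
#'
#' Centres the seed vector and every voxel column and scales each to unit
#' Euclidean norm, so that `R = t(Y) %*% X` holds the exact Pearson
#' correlation between the seed and every voxel. Constant voxel columns
#' yield correlation 0; their count is attached as attribute
#' `n_constant` and reported.
#'
#' @param Y Numeric per-subject seed values (length n >= 3).
#' @param X Numeric n x V matrix of voxel values.
#' @return Numeric length-V correlation vector in `[-1, 1]`.
#' @export
correlation_vector <- function(Y, X) {
  n <- length(Y)
  if (n < 3) abort("need at least 3 subjects")
  if (nrow(X) != n) abort("Y and X must be row-aligned")
  y <- Y - mean(Y)
  ny <- sqrt(sum(y^2))
  if (ny == 0) abort("seed values are constant")
  y <- y / ny
  Xc <- sweep(X, 2, colMeans(X))
  nx <- sqrt(colSums(Xc^2))
  const <- nx == 0
  nx[const] <- 1
  R <- as.numeric(crossprod(y, sweep(Xc, 2, nx, "/")))
  R <- pmin(pmax(R, -1), 1) # guard against float spill past +/-1
  R[const] <- 0
  if (any(const))
    warn(paste(sum(const), "constant voxel column(s); correlation set to 0"))
  attr(R, "n_constant") <- sum(const)
  R
}

#' Singular value decomposition of a correlation vector/matrix
#'
#' Decomposes `R = v s u'` into latent variables ordered by decreasing
#' singular value; the number of latent variables equals the rank of `R`.
#' For the single-seed case (`R` a 1 x V vector) there is exactly one
#' latent variable with `u = R / ||R||`, `s = ||R||`, `v = 1`. An all-zero
#' `R` returns one degenerate latent variable flagged as such.
#'
#' @param R Correlation vector (length V) or matrix (seeds x V).
#' @return List of `latent_variable` objects: fields `u` (unit-norm voxel
#'   salience), `v` (seed salience), `s` (singular value), `degenerate`.
#' @export
pls_svd <- function(R) {
  if (is.null(dim(R))) R <- matrix(R, nrow = 1)
  if (any(!is.finite(R))) abort("R must be finite")
  if (all(R == 0)) {
    lv <- structure(list(u = rep(0, ncol(R)), v = rep(0, nrow(R)), s = 0,
                         degenerate = TRUE), class = "latent_variable")
    return(list(lv))
  }
  dec <- svd(t(R)) # t(R): V x seeds, so dec$u is voxel-space
  keep <- which(dec$d > max(dec$d) * 1e-12)
  lapply(keep, function(k) {
    u <- dec$u[, k]; v <- dec$v[, k]; s <- dec$d[k]
    # sign convention: seed salience non-negative for the leading entry
    if (v[which.max(abs(v))] < 0) { u <- -u; v <- -v }
    structure(list(u = u, v = v, s = s, degenerate = FALSE),
              class = "latent_variable")
  })
}

#' @export
print.latent_variable <- function(x, ...) {
  cat("<latent_variable> s = ", signif(x$s, 4),
      if (!is.null(x$p_perm)) paste0(", p = ", signif(x$p_perm, 3)),
      if (isTRUE(x$degenerate)) " (degenerate)", "\n", sep = "")
  invisible(x)
}

#' Permutation test of latent-variable significance
#'
#' Permutes the subject order of the seed vector relative to the image
#' matrix and uses the (first) singular value as the test statistic:
#' `p = (1 + #\{s_perm >= s_obs\}) / (n_perm + 1)`, so p is never below
#' `1/(n_perm + 1)`.
#'
#' @param Y Seed values (length n).
#' @param X n x V image matrix.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional RNG seed.
#' @return Named list: `p`, `s_obs`, `s_null` (the permuted singular
#'   values).
#' @export
permute_lv <- function(Y, X, n_perm = 1000, seed = NULL) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  n <- length(Y)
  y <- Y - mean(Y); y <- y / sqrt(sum(y^2))
  Xc <- sweep(X, 2, colMeans(X))
  nx <- sqrt(colSums(Xc^2)); const <- nx == 0; nx[const] <- 1
  Xs <- sweep(Xc, 2, nx, "/"); Xs[, const] <- 0
  s_obs <- sqrt(sum(as.numeric(crossprod(y, Xs))^2))
  run <- function() {
    P <- vapply(seq_len(n_perm), function(b) y[sample.int(n)], numeric(n))
    sqrt(rowSums(crossprod(P, Xs)^2))
  }
  s_null <- if (is.null(seed)) run() else with_seed(seed, run())
  list(p = (1 + sum(s_null >= s_obs)) / (n_perm + 1),
       s_obs = s_obs, s_null = s_null)
}

#' Bootstrap ratios for voxel salience stability
#'
#' Resamples subjects with replacement, recomputes the salience each time
#' (sign-aligned to the original: a bootstrap salience is flipped when its
#' inner product with the original salience is negative), and divides the
#' original salience by the voxelwise bootstrap standard error. Resamples
#' with a constant seed vector are redrawn; their count is attached as
#' attribute `n_redrawn`.
#'
#' @param Y Seed values.
#' @param X n x V image matrix.
#' @param n_boot Number of bootstrap resamples (default 500).
#' @param seed Optional RNG seed.
#' @return Numeric length-V bootstrap-ratio map (salience / bootstrap SE);
#'   voxels with zero bootstrap SE get 0.
#' @export
bootstrap_bsr <- function(Y, X, n_boot = 500, seed = NULL) {
  if (n_boot < 2) abort("n_boot must be >= 2")
  n <- length(Y)
  R0 <- suppressWarnings(correlation_vector(Y, X))
  u0 <- R0 / sqrt(sum(R0^2))
  run <- function() {
    U <- matrix(NA_real_, n_boot, length(u0))
    redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        if (sd(Y[idx]) > 0) break
        redrawn <- redrawn + 1L
      }
      Rb <- suppressWarnings(correlation_vector(Y[idx], X[idx, , drop = FALSE]))
      nb <- sqrt(sum(Rb^2))
      ub <- if (nb > 0) Rb / nb else Rb
      if (sum(ub * u0) < 0) ub <- -ub
      U[b, ] <- ub
    }
    list(U = U, redrawn = redrawn)
  }
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  se <- apply(res$U, 2, sd)
  bsr <- ifelse(se > 0, u0 / se, 0)
  if (res$redrawn > 0)
    warn(paste(res$redrawn, "degenerate bootstrap resample(s) redrawn"))
  attr(bsr, "n_redrawn") <- res$redrawn
  bsr
}

#' Seed PLS for one seed and one modality
#'
#' The full single-seed path: seed extraction, correlation vector, SVD,
#' permutation test of the latent variable, and bootstrap ratios.
#'
#' @param images An [image_matrix()].
#' @param seed One-row seed tibble (or full-grid logical mask).
#' @param n_perm,n_boot Resampling counts (defaults 1000 and 500).
#' @param seed_rng Optional RNG seed.
#' @return A `latent_variable` with `p_perm` and `bsr` fields filled, plus
#'   `seed_name` and `modality`.
#' @export
seed_pls <- function(images, seed, n_perm = 1000, n_boot = 500,
                     seed_rng = NULL) {
  Y <- extract_seed_values(images, seed)
  X <- images$values
  R <- suppressWarnings(correlation_vector(Y, X))
  lv <- pls_svd(R)[[1]]
  lv$p_perm <- permute_lv(Y, X, n_perm = n_perm, seed = seed_rng)$p
  lv$bsr <- bootstrap_bsr(Y, X, n_boot = n_boot,
                          seed = if (is.null(seed_rng)) NULL
                                 else seed_rng + 1L)
  lv$seed_name <- if (is.data.frame(seed)) seed$name[[1]] else NA_character_
  lv$modality <- images$modality
  lv
}

#' Run seed PLS for every seed in both modalities
#'
#' @param cohort A cohort list with `gmv` and `fdg` [image_matrix()]s.
#' @param seeds Seed tibble from [combine_and_peak()] / [define_seeds()].
#' @param n_perm,n_boot Resampling counts per analysis.
#' @param seed Optional master RNG seed (per-analysis seeds derived).
#' @return Tibble: `seed`, `modality`, `s`, `p_perm`, and an `lv`
#'   list-column of `latent_variable` objects.
#' @export
run_seed_pls <- function(cohort, seeds, n_perm = 1000, n_boot = 500,
                         seed = NULL) {
  combos <- expand.grid(i = seq_len(nrow(seeds)),
                        modality = c("GMV", "FDG"),
                        stringsAsFactors = FALSE)
  rows <- purrr::pmap(combos, function(i, modality) {
    im <- if (modality == "GMV") cohort$gmv else cohort$fdg
    rng <- if (is.null(seed)) NULL else seed + 2L * i +
      (modality == "FDG") * 1000L
    lv <- seed_pls(im, seeds[i, ], n_perm = n_perm, n_boot = n_boot,
                   seed_rng = rng)
    tibble(seed = seeds$name[i], modality = modality,
           s = lv$s, p_perm = lv$p_perm, lv = list(lv))
  })
  purrr::list_rbind(rows)
}

#' Individual network scores from salience projection
#'
#' Projects each participant's voxel map onto the voxel salience of the
#' (significant) latent variable of every seed-by-modality analysis
#' (`L_X = X u`), averages the left/right scores of bilateral regions on
#' the raw projection scale, and z-scores each resulting column using the
#' mean and SD of the reference group (all participants, or CN only). With
#' the canonical 7 regions and 2 modalities this yields 14 columns named
#' `<REGION>_<MODALITY>`.
#'
#' @param cohort Cohort list with `gmv`, `fdg` and `phenotypes`.
#' @param pls_results Tibble from [run_seed_pls()].
#' @param reference_group `"all"` (default) or `"CN"`: subjects whose mean
#'   and SD define the z-scale.
#' @param p_threshold Latent variables with permutation p above this are
#'   dropped (their column is reported absent); default 0.05.
#' @return Tibble: `id` plus one z-scored column per region-modality.
#' @export
compute_network_scores <- function(cohort, pls_results,
                                   reference_group = c("all", "CN"),
                                   p_threshold = 0.05) {
  reference_group <- match.arg(reference_group)
  ph <- cohort$phenotypes
  keep <- is.na(pls_results$p_perm) | pls_results$p_perm <= p_threshold
  if (any(!keep))
    warn(paste("dropping non-significant latent variable(s):",
               paste(pls_results$seed[!keep], pls_results$modality[!keep],
                     collapse = ", ")))
  res <- pls_results[keep, , drop = FALSE]
  res$region <- sub("_[LR]$", "", res$seed)

  raw <- purrr::pmap(res, function(seed, modality, lv, region, ...) {
    im <- if (modality == "GMV") cohort$gmv else cohort$fdg
    as.numeric(im$values %*% lv$u)
  })
  res$raw <- raw

  ref_idx <- if (reference_group == "CN")
    which(ph$diagnosis == "CN") else seq_len(nrow(ph))

  out <- tibble(id = ph$id)
  combos <- dplyr::distinct(res, .data$region, .data$modality)
  for (r in seq_len(nrow(combos))) {
    sel <- res$region == combos$region[r] & res$modality == combos$modality[r]
    avg <- rowMeans(do.call(cbind, res$raw[sel])) # bilateral average, raw
    z <- (avg - mean(avg[ref_idx])) / sd(avg[ref_idx])
    out[[paste(combos$region[r], combos$modality[r], sep = "_")]] <- z
  }
  out
}

#' Write a network score table as TSV keyed by participant id
#'
#' @param scores Score tibble from [compute_network_scores()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
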