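#' Regress nuisance covariates out of voxel data
#'
#' Per-voxel ordinary least squares on the covariate design (plus
#' intercept); returns the residuals. Residuals are exactly orthogonal to
#' every covariate column. Rank-deficient designs are refused with the
#' offending columns named, rather than silently dropped.
#'
#' @param values Numeric matrix (subjects x voxels) or an [image_matrix()].
#' @param covariates Data frame or matrix of per-subject covariates,
#'   row-aligned with `values`. Character/factor columns are expanded to
#'   treatment-coded dummies.
#' @return Residualised object of the same type as `values`.
#' @export
regress_nuisance <- function(values, covariates) {
  imat <- NULL
  if (inherits(values, "image_matrix")) {
    imat <- values; values <- imat$values
  }
  X <- covariate_design(covariates)
  if (nrow(X) != nrow(values))
    abort("covariates must be row-aligned with subjects")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste("collinear covariate columns:", paste(bad, collapse = ", ")))
  }
  res <- values - qr.fitted(qrX, values)
  if (!is.null(imat)) { imat$values <- res; return(imat) }
  res
}

# intercept + numeric/dummy expansion of a covariate table
covariate_design <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  df <- as.data.frame(covariates)
  mm <- stats::model.matrix(~ ., data = df)
  mm
}

#' Threshold-free cluster enhancement
#'
#' Integrates cluster extent over all cluster-forming thresholds: voxel v
#' receives `sum_h extent(cluster_h(v))^E * h^H * dh` over heights
#' `h = dh, 2dh, ...` up to the map maximum, with face (6-)connected
#' clusters. Only the positive part of the map is enhanced (the contrasts
#' here are one-sided); an all-zero or non-positive map returns zeros.
#'
#' @param stat_map Numeric statistic map: a vector over the full grid, or a
#'   3D array.
#' @param dims Grid dims (length 3); taken from the array when omitted.
#' @param E,H TFCE extent and height exponents (defaults 0.5 and 2).
#' @param dh Integration step; default `max(stat_map)/n_steps`.
#' @param n_steps Number of integration steps used when `dh` is `NULL`
#'   (default 100).
#' @return Numeric vector of enhanced values, same length as the input.
#' @export
tfce <- function(stat_map, dims = NULL, E = 0.5, H = 2, dh = NULL,
                 n_steps = 100) {
  if (is.array(stat_map) && is.null(dims)) dims <- dim(stat_map)
  if (is.null(dims)) abort("dims required for vector input")
  v <- as.numeric(stat_map)
  if (any(!is.finite(v))) abort("stat_map must be finite")
  mx <- max(v)
  if (mx <= 0) return(numeric(length(v)))
  if (is.null(dh)) dh <- mx / n_steps
  if (dh <= 0) abort("dh must be positive")
  .tfce_cpp(v, as.integer(dims), E, H, dh)
}

# pooled-variance two-sample t statistics per voxel, one-sided A - B
t_stat_two_sample <- function(values, is_a) {
  n1 <- sum(is_a); n2 <- sum(!is_a)
  m1 <- colMeans(values[is_a, , drop = FALSE])
  m2 <- colMeans(values[!is_a, , drop = FALSE])
  ss1 <- colSums(values[is_a, , drop = FALSE]^2) - n1 * m1^2
  ss2 <- colSums(values[!is_a, , drop = FALSE]^2) - n2 * m2^2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  se <- sqrt(pmax(sp2, .Machine$double.eps) * (1 / n1 + 1 / n2))
  (m1 - m2) / se
}

#' Permutation group contrast with TFCE and FWE control
#'
#' Voxelwise two-sample contrast (group A minus group B, one-sided, pooled
#' variance) with significance assessed by a label-permutation test:
#' nuisance covariates are first regressed out of the pooled data
#' (Freedman-Lane style residualisation), group labels are then permuted,
#' each permuted t map is TFCE-enhanced, and the maximum enhanced statistic
#' per permutation forms the null used for family-wise error corrected
#' voxel p-values. The observed labelling is included in the null, so
#' p >= 1/(n_perm + 1).
#'
#' @param images_a,images_b [image_matrix()] objects (same grid/mask) for
#'   the two groups.
#' @param covariates Optional per-subject covariate table for the pooled
#'   sample (rows of A then rows of B).
#' @param n_perm Number of permutations (default 5000).
#' @param alpha FWE threshold for the significance mask (default 0.05).
#' @param E,H,n_steps TFCE parameters, see [tfce()].
#' @param seed Optional RNG seed for the permutation stream.
#' @return A `group_difference_map`: list with `t`, `tfce`, `p_fwe`,
#'   `threshold_mask` (all vectors over in-mask voxels), `t_thresh`
#'   (t zeroed where not significant), the grid/mask, and `max_null`.
#' @export
permutation_contrast <- function(images_a, images_b, covariates = NULL,
                                 n_perm = 5000, alpha = 0.05,
                                 E = 0.5, H = 2, n_steps = 100,
                                 seed = NULL) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  if (nrow(images_a$values) < 2 || nrow(images_b$values) < 2)
    abort("need at least 2 subjects per group")
  stopifnot(identical(images_a$grid$dims, images_b$grid$dims))
  vals <- rbind(images_a$values, images_b$values)
  is_a <- c(rep(TRUE, nrow(images_a$values)),
            rep(FALSE, nrow(images_b$values)))
  if (!is.null(covariates)) vals <- regress_nuisance(vals, covariates)
  grid <- images_a$grid; mask <- images_a$mask
  dims <- grid$dims

  enhance <- function(tv) {
    full <- embed_map(grid, tv, mask)
    tfce(full, dims, E = E, H = H, n_steps = n_steps)[mask]
  }
  t_obs <- t_stat_two_sample(vals, is_a)
  tfce_obs <- enhance(t_obs)

  run <- function() {
    n <- length(is_a)
    max_null <- numeric(n_perm)
    max_null[1] <- max(tfce_obs) # observed labelling belongs to the null
    if (n_perm > 1) {
      for (b in 2:n_perm) {
        perm <- sample.int(n)
        tv <- t_stat_two_sample(vals[perm, , drop = FALSE], is_a)
        max_null[b] <- max(enhance(tv), 0)
      }
    }
    max_null
  }
  max_null <- if (is.null(seed)) run() else with_seed(seed, run())

  # upper tail count with the observed map included once
  p_fwe <- (1 + vapply(tfce_obs,
                       function(x) sum(max_null[-1] >= x),
                       numeric(1))) / (n_perm + 1)
  thr <- p_fwe <= alpha & t_obs > 0
  structure(list(
    t = t_obs, tfce = tfce_obs, p_fwe = p_fwe, threshold_mask = thr,
    t_thresh = ifelse(thr, t_obs, 0),
    grid = grid, mask = mask, n_perm = n_perm, alpha = alpha,
    max_null = max_null
  ), class = "group_difference_map")
}

#' @export
print.group_difference_map <- function(x, ...) {
  cat("<group_difference_map> ", sum(x$threshold_mask), " of ",
      length(x$t), " voxels significant at FWE ", x$alpha,
      " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' Combine thresholded maps and extract spherical seed regions
#'
#' Superimposes the two modality-specific thresholded t maps by voxelwise
#' summation, then locates, within each expected region's search
#' neighbourhood, the peak of the summed map among significant voxels.
#' A spherical seed (default radius 4 mm, membership by voxel-centre
#' distance) is built at every peak found; regions whose neighbourhood
#' contains no significant voxel are reported absent, never fabricated.
#'
#' @param t_gmv_thresh,t_fdg_thresh Thresholded t vectors over in-mask
#'   voxels (zero where not significant), e.g. the `t_thresh` field of
#'   [permutation_contrast()].
#' @param expected_regions Tibble with `name`, `x`, `y`, `z` (mm): the
#'   anatomical neighbourhoods to search (e.g. [default_loci()]).
#' @param grid A [brain_grid()].
#' @param mask In-brain mask (default all voxels).
#' @param radius_mm Seed sphere radius (default 4).
#' @param search_radius_mm Neighbourhood radius around each expected locus
#'   (default 12).
#' @return A tibble of seeds: `name`, `x`, `y`, `z` (peak, mm),
#'   `radius_mm`, `peak_sum`, `n_voxels`, and a `mask` list-column of
#'   full-grid logical sphere masks. Absent regions are dropped; their
#'   names are kept in the `absent` attribute.
#' @export
combine_and_peak <- function(t_gmv_thresh, t_fdg_thresh, expected_regions,
                             grid, mask = NULL, radius_mm = 4,
                             search_radius_mm = 12) {
  if (is.null(mask)) mask <- rep(TRUE, grid$n_voxels)
  stopifnot(length(t_gmv_thresh) == length(t_fdg_thresh))
  summed <- rep(0, grid$n_voxels)
  summed[mask] <- t_gmv_thresh + t_fdg_thresh
  xyz <- grid_coords(grid)
  rows <- purrr::pmap(expected_regions[, c("name", "x", "y", "z")],
    function(name, x, y, z) {
      d2 <- (xyz[, 1] - x)^2 + (xyz[, 2] - y)^2 + (xyz[, 3] - z)^2
      cand <- which(d2 <= search_radius_mm^2 & summed > 0 & mask)
      if (!length(cand)) return(NULL)
      peak <- cand[which.max(summed[cand])]
      centre <- xyz[peak, ]
      sph <- sphere_mask(grid, centre, radius_mm) & mask
      tibble(name = name, x = centre[1], y = centre[2], z = centre[3],
             radius_mm = radius_mm, peak_sum = summed[peak],
             n_voxels = sum(sph), mask = list(sph))
    })
  found <- purrr::list_rbind(purrr::compact(rows))
  absent <- setdiff(expected_regions$name,
                    if (nrow(found)) found$name else character())
  if (length(absent))
    warn(paste("no significant voxel near:", paste(absent, collapse = ", ")))
  attr(found, "absent") <- absent
  found
}

#' Define seed regions from a cohort's CN vs dementia contrast
#'
#' End-to-end seed definition: nuisance-adjusted permutation contrast
#' (CN greater than AD) per modality, TFCE/FWE thresholding, voxelwise
#' summation of the two thresholded t maps, and 4 mm spherical seeds at the
#' regional peaks.
#'
#' @param cohort A `synthetic_cohort` (or any list with `phenotypes`,
#'   `gmv`, `fdg`).
#' @param expected_regions Search loci tibble; defaults to the cohort's
#'   planted loci when present, else [default_loci()].
#' @param covariate_cols Phenotype columns regressed out before the
#'   contrast.
#' @param n_perm,alpha,search_radius_mm,radius_mm See
#'   [permutation_contrast()] and [combine_and_peak()].
#' @param seed RNG seed for the permutation streams.
#' @return Tibble of seeds as from [combine_and_peak()], with the two
#'   `group_difference_map`s attached as attribute `contrasts`.
#' @export
define_seeds <- function(cohort, expected_regions = NULL,
                         covariate_cols = c("age", "gender", "education",
                                            "apoe4"),
                         n_perm = 5000, alpha = 0.05,
                         search_radius_mm = 12, radius_mm = 4,
                         seed = NULL) {
  ph <- cohort$phenotypes
  if (is.null(expected_regions))
    expected_regions <- if (!is.null(cohort$truth$loci))
      cohort$truth$loci else default_loci()
  idx_cn <- which(ph$diagnosis == "CN")
  idx_ad <- which(ph$diagnosis == "AD")
  sub <- function(im, idx) image_matrix(im$values[idx, , drop = FALSE],
                                        im$grid, im$mask, im$modality)
  cov_tab <- ph[c(idx_cn, idx_ad), covariate_cols, drop = FALSE]
  maps <- lapply(list(gmv = cohort$gmv, fdg = cohort$fdg), function(im) {
    permutation_contrast(sub(im, idx_cn), sub(im, idx_ad),
                         covariates = cov_tab, n_perm = n_perm,
                         alpha = alpha, seed = seed)
  })
  seeds <- combine_and_peak(maps$gmv$t_thresh, maps$fdg$t_thresh,
                            expected_regions, cohort$gmv$grid,
                            cohort$gmv$mask, radius_mm = radius_mm,
                            search_radius_mm = search_radius_mm)
  attr(seeds, "contrasts") <- maps
  seeds
}

#' Write a seed table as TSV (name, centre mm, radius)
#'
#' @param seeds Seed tibble from [combine_and_peak()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_seeds_tsv <- function(seeds, path) {
  write.table(seeds[, c("name", "x", "y", "z", "radius_mm")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
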