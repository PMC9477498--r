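#' Default network loci for synthetic cohorts
#'
#' Twelve seed-anchoring foci: bilateral hippocampus (HIP), angular gyrus
#' (ANG), insula (INS), dorsolateral prefrontal cortex (DLPFC) and posterior
#' parietal cortex (PPC), plus midline posterior cingulate (PCC) and medial
#' prefrontal cortex (mPFC). Coordinates are synthetic: they echo the
#' relative anatomical layout of the default-mode, salience, executive
#' control and memory networks but are scaled to fit the default synthetic
#' grid, not any stereotaxic atlas.
#'
#' @return Tibble with columns `name`, `region`, `hemi`, `x`, `y`, `z` (mm).
#' @export
default_loci <- function() {
  tibble(
    name  = c("HIP_L", "HIP_R", "ANG_L", "ANG_R", "INS_L", "INS_R",
              "DLPFC_L", "DLPFC_R", "PPC_L", "PPC_R", "PCC", "mPFC"),
    region = c("HIP", "HIP", "ANG", "ANG", "INS", "INS",
               "DLPFC", "DLPFC", "PPC", "PPC", "PCC", "mPFC"),
    hemi  = c("L", "R", "L", "R", "L", "R", "L", "R", "L", "R", "M", "M"),
    x = c(-24, 24, -36, 36, -28, 28, -32, 32, -20, 20, 0, 0),
    y = c(-16, -16, -40, -40, 12, 12, 32, 32, -44, -44, -36, 40),
    z = c(-16, -16, 28, 28, 0, 0, 24, 24, 36, 36, 24, 8)
  )
}

# 7 regions x 2 modalities, the 14 predictors of the downstream model
predictor_names <- function(regions = unique(default_loci()$region),
                            modalities = c("GMV", "FDG")) {
  as.vector(outer(regions, modalities, paste, sep = "_"))
}

#' Configuration for a synthetic cohort
#'
#' Fixes every knob of the simulated study: cell sizes of the stage-by-
#' pathology design, grid geometry, the planted covariance networks (smooth
#' Gaussian blobs around bilateral/midline loci), subject-loading
#' distribution across stages, voxel noise, site effects, the true
#' stage-varying coefficient curves that generate memory, and the seed of
#' the generator. Defaults describe a cohort in which every network shows
#' declining expression from CN through MCI to dementia, and only the
#' hippocampal structural network drives memory, with a coupling that fades
#' across the disease continuum.
#'
#' @param n_per_cell Participants per (stage x pathology) cell; the three
#'   stages and three pathology strata give `9 * n_per_cell` in total.
#' @param grid_dims Voxel grid size (length 3).
#' @param voxel_mm Voxel edge in mm.
#' @param loci Tibble of planted foci as from [default_loci()].
#' @param pattern_sd_mm Gaussian kernel SD of the planted blobs, mm.
#' @param loading_mu Named stage means (CN, MCI, AD) of the network
#'   loadings; decreasing values plant the disease gradient.
#' @param loading_sd Between-subject SD of network loadings.
#' @param noise_sd Voxel-level iid noise SD.
#' @param n_sites Number of acquisition sites (additive voxel offsets).
#' @param site_sd SD of the per-site voxel offset field.
#' @param beta_truth Numeric matrix (14 predictors x K bins) of true
#'   coefficient curves on the z-scale, rows named by
#'   `predictor_names()`. Default: `HIP_GMV` declines linearly 0.8 to 0.2,
#'   all other rows zero.
#' @param memory_noise_sd SD of the memory residual.
#' @param bin_size Participants per pseudo-stage bin (fixes K: each
#'   pathology group holds `3 * n_per_cell` participants, so
#'   `K = ceiling(3 * n_per_cell / bin_size)`).
#' @param rng_seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_cell = 15,
                       grid_dims = c(24, 24, 24),
                       voxel_mm = 4,
                       loci = default_loci(),
                       pattern_sd_mm = 7,
                       loading_mu = c(CN = 0.8, MCI = 0, AD = -0.8),
                       loading_sd = 1,
                       noise_sd = 0.3,
                       n_sites = 3,
                       site_sd = 0.1,
                       beta_truth = NULL,
                       memory_noise_sd = 0.6,
                       bin_size = 10,
                       rng_seed = 1L) {
  if (n_per_cell < 1) abort("n_per_cell must be >= 1")
  if (noise_sd <= 0) abort("noise_sd must be > 0")
  if (prod(grid_dims) < nrow(loci))
    abort("grid too small for the requested pattern loci")
  K <- ceiling(3 * n_per_cell / bin_size)
  preds <- predictor_names(unique(loci$region))
  if (is.null(beta_truth)) {
    beta_truth <- matrix(0, length(preds), K,
                         dimnames = list(preds, NULL))
    beta_truth["HIP_GMV", ] <- seq(0.8, 0.2, length.out = K)
  }
  beta_truth <- as.matrix(beta_truth)
  if (ncol(beta_truth) != K)
    abort(paste0("beta_truth must have one column per bin (K = ", K, ")"))
  if (is.null(rownames(beta_truth))) rownames(beta_truth) <- preds
  structure(list(
    n_per_cell = as.integer(n_per_cell), grid_dims = as.integer(grid_dims),
    voxel_mm = voxel_mm, loci = loci, pattern_sd_mm = pattern_sd_mm,
    loading_mu = loading_mu, loading_sd = loading_sd, noise_sd = noise_sd,
    n_sites = as.integer(n_sites), site_sd = site_sd,
    beta_truth = beta_truth, memory_noise_sd = memory_noise_sd,
    bin_size = as.integer(bin_size), n_bins = K,
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

# CSF sampling intervals strictly inside/outside the 192/23 cutoffs, so the
# generated strata match the intended labels without boundary ambiguity
csf_intervals <- list(
  "A+"   = list(abeta = c(110, 180), ptau = c(15, 45)),
  "A-T+" = list(abeta = c(205, 280), ptau = c(26, 45)),
  "A-T-" = list(abeta = c(205, 280), ptau = c(8, 20))
)

sample_phenotypes <- function(cfg) {
  stages <- c("CN", "MCI", "AD")
  strata <- c("A-T-", "A-T+", "A+")
  cells <- expand.grid(stage = stages, pathology = strata,
                       stringsAsFactors = FALSE)
  rows <- purrr::pmap(cells, function(stage, pathology) {
    n <- cfg$n_per_cell
    iv <- csf_intervals[[pathology]]
    mmse <- switch(stage,
      CN  = sample(26:30, n, replace = TRUE),
      MCI = sample(24:30, n, replace = TRUE),
      AD  = sample(15:26, n, replace = TRUE))
    cdr_global <- switch(stage,
      CN = rep(0, n), MCI = rep(0.5, n),
      AD = sample(c(1, 2), n, replace = TRUE, prob = c(0.8, 0.2)))
    cdr_sob <- switch(stage,
      CN  = rep(0, n),
      MCI = round(runif(n, 0.5, 4) * 2) / 2,
      AD  = round(runif(n, 4, 14) * 2) / 2)
    apoe_p <- c("A-T-" = 0.25, "A-T+" = 0.3, "A+" = 0.6)[[pathology]]
    tibble(
      stage = stage, pathology = pathology,
      age = round(pmin(90, pmax(55, rnorm(n, 73, 6))), 1),
      gender = sample(c("M", "F"), n, replace = TRUE),
      education = pmin(20, pmax(8, round(rnorm(n, 16, 2.5)))),
      apoe4 = ifelse(runif(n) < apoe_p, "carrier", "non-carrier"),
      icv = round(rnorm(n, 1450, 120), 1),
      site = paste0("site", sample.int(cfg$n_sites, n, replace = TRUE)),
      diagnosis = stage, mmse = mmse, cdr_global = cdr_global,
      cdr_sob = cdr_sob,
      csf_abeta = round(runif(n, iv$abeta[1], iv$abeta[2]), 1),
      csf_ptau = round(runif(n, iv$ptau[1], iv$ptau[2]), 1)
    )
  })
  ph <- purrr::list_rbind(rows)
  ph$id <- sprintf("S%04d", seq_len(nrow(ph)))
  ph$pathology <- factor(ph$pathology, levels = strata)
  dplyr::relocate(ph, "id")
}

#' Generate a synthetic cohort with planted covariance networks
#'
#' Simulates a three-stage (CN/MCI/AD), three-pathology-stratum (A-T-,
#' A-T+, A+) cohort. Each of the 7 regions contributes a smooth bilateral
#' (or midline) Gaussian pattern to both modalities; subject i's map is
#' `sum_j loading_ij * pattern_j + site offset + iid noise`, with loadings
#' drawn `Normal(mu_stage, loading_sd^2)` so network expression declines
#' CN to MCI to dementia. CSF values are sampled strictly inside the
#' intended cutoff intervals, so the A/T classifier reproduces the planted
#' strata exactly. Memory is generated from the (standardised) true network
#' loadings under the configured stage-varying coefficient curves via
#' [generate_memory()].
#'
#' @param config A [sim_config()].
#' @param images Generate voxel maps (set `FALSE` for tabular-only cohorts,
#'   e.g. when only the regression stages are exercised).
#' @return A `synthetic_cohort`: list with `phenotypes` (tibble), `gmv` and
#'   `fdg` ([image_matrix()] or `NULL`), `truth` (loadings, true curves,
#'   loci, patterns), `grid`, and the `config`.
#' @export
generate_cohort <- function(config = sim_config(), images = TRUE) {
  cfg <- config
  grid <- brain_grid(cfg$grid_dims, cfg$voxel_mm)
  # all loci must fall inside the grid
  vox <- mm_to_voxel(grid, as.matrix(cfg$loci[, c("x", "y", "z")]))
  if (any(vox < -0.5) || any(vox > rep(cfg$grid_dims - 0.5, each = nrow(vox))))
    abort("grid too small for the requested pattern loci")

  with_seed(cfg$rng_seed, {
    ph <- sample_phenotypes(cfg)
    n <- nrow(ph)
    regions <- unique(cfg$loci$region)
    preds <- predictor_names(regions)

    # per-region spatial patterns (bilateral loci share one pattern)
    patterns <- t(vapply(regions, function(r) {
      foci <- cfg$loci[cfg$loci$region == r, c("x", "y", "z")]
      p <- rep(0, grid$n_voxels)
      for (i in seq_len(nrow(foci)))
        p <- p + gaussian_pattern(grid, as.numeric(foci[i, ]),
                                  cfg$pattern_sd_mm)
      p
    }, numeric(grid$n_voxels)))

    mu <- cfg$loading_mu[ph$stage]
    loadings <- matrix(rnorm(n * length(preds), mean = mu,
                             sd = cfg$loading_sd),
                       n, length(preds), dimnames = list(ph$id, preds))

    gmv <- fdg <- NULL
    if (images) {
      site_levels <- sort(unique(ph$site))
      maps <- lapply(c("GMV", "FDG"), function(mod) {
        site_off <- matrix(rnorm(length(site_levels) * grid$n_voxels,
                                 sd = cfg$site_sd),
                           length(site_levels), grid$n_voxels,
                           dimnames = list(site_levels, NULL))
        vals <- loadings[, paste(regions, mod, sep = "_"), drop = FALSE] %*%
          patterns +
          site_off[ph$site, , drop = FALSE] +
          matrix(rnorm(n * grid$n_voxels, sd = cfg$noise_sd), n)
        image_matrix(vals, grid, modality = mod, subject_ids = ph$id)
      })
      gmv <- maps[[1]]; fdg <- maps[[2]]
    }

    cohort <- structure(list(
      phenotypes = ph, gmv = gmv, fdg = fdg,
      truth = list(loadings = loadings, beta_truth = cfg$beta_truth,
                   loci = cfg$loci, patterns = patterns, regions = regions),
      grid = grid, config = cfg
    ), class = "synthetic_cohort")
    generate_memory(cohort)
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$phenotypes), " participants, ",
      length(x$truth$regions), " planted networks",
      if (!is.null(x$gmv)) paste0(", grid ",
                                  paste(x$grid$dims, collapse = "x")),
      "\n", sep = "")
  invisible(x)
}

#' Generate the memory outcome from planted network loadings
#'
#' Orders and bins the cohort within each pathology group, standardises the
#' true network loadings to z-scores within pathology group, and sets
#' `memory_i = sum_j beta_truth[j, bin(i)] * x_ij + eps_i` with iid
#' Gaussian residuals. Run inside [generate_cohort()]; exposed so the
#' outcome can be regenerated under alternative coefficient curves or noise
#' levels without resimulating images. Uses the current RNG stream.
#'
#' @param cohort A `synthetic_cohort`.
#' @param beta_truth True coefficient matrix (predictors x bins); default
#'   the cohort config's.
#' @param memory_noise_sd Residual SD; default the config's.
#' @param strategy Ordering strategy passed to [stage_cohort()].
#' @return The cohort with `phenotypes$memory` filled in (and the truth
#'   record updated).
#' @export
generate_memory <- function(cohort, beta_truth = NULL,
                            memory_noise_sd = NULL,
                            strategy = "split") {
  cfg <- cohort$config
  if (is.null(beta_truth)) beta_truth <- cfg$beta_truth
  if (is.null(memory_noise_sd)) memory_noise_sd <- cfg$memory_noise_sd
  ph <- cohort$phenotypes
  staged <- stage_cohort(ph, strategy = strategy, bin_size = cfg$bin_size)
  if (anyNA(staged$bin)) abort("bin assignment missing")
  staged <- staged[match(ph$id, staged$id), ]
  if (max(staged$bin) > ncol(beta_truth))
    abort("beta_truth has fewer columns than bins")

  x <- cohort$truth$loadings[, rownames(beta_truth), drop = FALSE]
  # standardise within pathology group
  for (g in levels(ph$pathology)) {
    rows <- which(ph$pathology == g)
    x[rows, ] <- scale(x[rows, , drop = FALSE])
  }
  signal <- rowSums(x * t(beta_truth)[staged$bin, , drop = FALSE])
  memory <- signal + rnorm(nrow(ph), sd = memory_noise_sd)
  cohort$phenotypes$memory <- round(memory, 6)
  cohort$truth$beta_truth <- beta_truth
  cohort$truth$x_std <- x
  cohort
}

#' Write a synthetic cohort to disk as NIfTI + TSV + JSON
#'
#' One uncompressed NIfTI per subject per modality
#' (`<id>_GMV.nii`, `<id>_FDG.nii`), the phenotype table as
#' `phenotypes.tsv`, and the ground truth (loadings, true coefficient
#' curves, loci) as `truth.json`. The fixture round-trips losslessly
#' through [read_cohort_fixture()] up to float storage precision.
#'
#' @param cohort A `synthetic_cohort` with images.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_cohort_fixture <- function(cohort, out_dir) {
  if (nrow(cohort$phenotypes) == 0) abort("cohort is empty")
  if (is.null(cohort$gmv)) abort("cohort has no images to write")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ph <- cohort$phenotypes
  for (i in seq_len(nrow(ph))) {
    for (mod in c("gmv", "fdg")) {
      im <- cohort[[mod]]
      write_map_nifti(im$values[i, ], im$grid,
                      file.path(out_dir, paste0(ph$id[i], "_",
                                                im$modality, ".nii")),
                      mask = im$mask)
    }
  }
  write.table(ph, file.path(out_dir, "phenotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(list(
    loadings = as.data.frame(truth$loadings),
    ids = ph$id,
    beta_truth = as.data.frame(truth$beta_truth),
    loci = truth$loci, regions = truth$regions,
    pattern_sd_mm = cohort$config$pattern_sd_mm,
    bin_size = cohort$config$bin_size,
    rng_seed = cohort$config$rng_seed
  ), file.path(out_dir, "truth.json"), digits = NA)
  invisible(out_dir)
}

#' Read a cohort fixture written by [write_cohort_fixture()]
#'
#' @param dir Fixture directory.
#' @return A `synthetic_cohort` (without the full config; truth and images
#'   restored).
#' @export
read_cohort_fixture <- function(dir) {
  ph <- as_tibble(read.delim(file.path(dir, "phenotypes.tsv"),
                             colClasses = c(id = "character",
                                            gender = "character",
                                            apoe4 = "character",
                                            site = "character")))
  ph$pathology <- factor(ph$pathology, levels = c("A-T-", "A-T+", "A+"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  gmv <- read_image_matrix(file.path(dir, paste0(ph$id, "_GMV.nii")),
                           modality = "GMV", subject_ids = ph$id)
  fdg <- read_image_matrix(file.path(dir, paste0(ph$id, "_FDG.nii")),
                           modality = "FDG", subject_ids = ph$id)
  structure(list(
    phenotypes = ph, gmv = gmv, fdg = fdg,
    truth = list(loadings = as.matrix(truth$loadings),
                 beta_truth = as.matrix(truth$beta_truth),
                 loci = as_tibble(truth$loci), regions = truth$regions),
    grid = gmv$grid,
    config = NULL
  ), class = "synthetic_cohort")
}
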