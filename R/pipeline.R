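# effect-coded nuisance predictor matrix for the varying-coefficient model:
# gender, education, APOE e4 carriage, ICV, and site (effect-coded levels)
nuisance_predictors <- function(phenotypes) {
  ph <- phenotypes
  out <- cbind(
    gender = ifelse(ph$gender == "M", 1, -1),
    education = as.numeric(ph$education),
    apoe4 = ifelse(ph$apoe4 == "carrier", 1, -1),
    icv = as.numeric(ph$icv)
  )
  site <- as.factor(ph$site)
  if (nlevels(site) > 1) {
    contrasts(site) <- stats::contr.sum(nlevels(site))
    sm <- stats::model.matrix(~ site)[, -1, drop = FALSE]
    colnames(sm) <- paste0("site_", seq_len(ncol(sm)))
    out <- cbind(out, sm)
  }
  out
}

#' Stage-varying network-memory model for one pathology group
#'
#' Wires the staging and regression stages together for a single pathology
#' group: orders and bins the group's participants along the pseudo-stage
#' axis, standardises memory and all predictors (network scores plus
#' nuisance variables, which enter as penalised varying-coefficient
#' predictors exactly like the network scores), builds the B-spline basis,
#' and runs the repeated cross-validated sparse fits.
#'
#' @param scores Network score tibble (`id` + score columns).
#' @param phenotypes Phenotype tibble (must contain `memory` and the
#'   nuisance columns).
#' @param pathology Optional pathology level to subset to (e.g. `"A+"`);
#'   `NULL` uses all rows.
#' @param strategy Ordering strategy, see [order_participants()].
#' @param bin_size Participants per bin (default 10).
#' @param M,degree Spline basis controls (defaults 6, cubic).
#' @param include_nuisance Add the nuisance predictor block (default TRUE).
#' @param ... Passed to [repeat_and_summarize()] (`n_rep`, `threshold`,
#'   `folds`, `penalty`, `n_lambda`, `base_seed`, ...).
#' @return A `selection_summary` with the staged data attached as
#'   attribute `staged` (`y`, `X`, `bins`, `basis`, ids).
#' @export
svc_memory_analysis <- function(scores, phenotypes, pathology = NULL,
                                strategy = "split", bin_size = 10,
                                M = 6, degree = 3,
                                include_nuisance = TRUE, ...) {
  ph <- phenotypes
  if (!is.null(pathology)) ph <- ph[ph$pathology == pathology, ]
  staged <- bin_participants(order_participants(ph, strategy), bin_size)
  sc <- scores[match(staged$id, scores$id), ]
  X <- as.matrix(sc[, setdiff(names(sc), "id"), drop = FALSE])
  if (include_nuisance) X <- cbind(X, nuisance_predictors(staged))
  std <- standardize_inputs(staged$memory, X, group = NULL)
  K <- max(staged$bin)
  if (K < M) {
    warn(paste0("only ", K, " bins; reducing basis size to match"))
    M <- K
    degree <- min(degree, M - 1)
  }
  basis <- build_basis(K, M = M, degree = degree)
  out <- repeat_and_summarize(std$y, std$X, staged$bin, basis, ...)
  attr(out, "staged") <- list(y = std$y, X = std$X, bins = staged$bin,
                              basis = basis, ids = staged$id)
  out
}

# canonical stage order of the pipeline
PIPELINE_STAGES <- c("simulate", "seeds", "pls", "scores", "groupstats",
                     "svc")

#' Default pipeline configuration
#'
#' All stage parameters at their reference values: pathology cutoffs
#' 192/23 pg/mL, bins of 10, 5000 permutations for the seed contrast and
#' the group comparisons, 1000 for the latent-variable test, 500
#' bootstraps, 100 repetitions with the >90 selection rule, fivefold
#' cross-validation over a 50-point penalty grid.
#'
#' @param output Output directory.
#' @param seed Master RNG seed; every stage derives its own stream.
#' @return Nested configuration list.
#' @export
default_config <- function(output = tempfile("stagenet_run"), seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = PIPELINE_STAGES,
    output = output,
    cutoffs = list(abeta = 192, ptau = 23),
    sim = list(n_per_cell = 15, grid_dims = c(24, 24, 24), voxel_mm = 4,
               noise_sd = 0.3, loading_sd = 1, memory_noise_sd = 0.6,
               n_sites = 3, site_sd = 0.1, bin_size = 10),
    seeds = list(n_perm = 5000, alpha = 0.05, search_radius_mm = 12,
                 radius_mm = 4),
    pls = list(n_perm = 1000, n_boot = 500, reference_group = "all"),
    staging = list(bin_size = 10, strategy = "split"),
    groupstats = list(n_perm = 5000, alpha = 0.05),
    svc = list(n_rep = 100, threshold = 90, folds = 5, n_lambda = 50,
               ratio = 1e-3, M = 6, degree = 3, penalty = "group_lasso",
               pathology_groups = c("A-T-", "A-T+", "A+"))
  )
}

#' Validate a pipeline configuration
#'
#' Merges the supplied configuration (a nested list, or path to a YAML
#' file) over [default_config()], rejects unknown keys, checks every
#' range constraint, and returns a report of the effective values.
#'
#' @param config Nested list or YAML file path; `NULL` gives the defaults.
#' @return List with `config` (effective, merged) and `report` (tibble of
#'   `key`, `value`); aborts with the offending key on violation.
#' @export
validate_config <- function(config = NULL) {
  defaults <- default_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()

  check_known <- function(user, ref, path = "") {
    unknown <- setdiff(names(user), names(ref))
    if (length(unknown))
      abort(paste0("unknown config key: ", path, unknown[1]))
    for (k in names(user))
      if (is.list(ref[[k]]) && !is.null(names(ref[[k]])))
        check_known(user[[k]], ref[[k]], paste0(path, k, "."))
  }
  check_known(config, defaults)
  cfg <- modifyList(defaults, config)

  chk <- function(ok, key, constraint) {
    if (!isTRUE(ok)) abort(paste0("config ", key, ": ", constraint))
  }
  chk(all(cfg$stages %in% PIPELINE_STAGES), "stages",
      "must be pipeline stage names")
  pos <- match(cfg$stages, PIPELINE_STAGES)
  chk(all(diff(pos) == 1) || length(pos) == 1, "stages",
      "must be a contiguous subsequence")
  chk(cfg$cutoffs$abeta > 0 && cfg$cutoffs$ptau > 0, "cutoffs",
      "must be positive")
  chk(cfg$sim$n_per_cell >= 1, "sim.n_per_cell", "must be >= 1")
  chk(cfg$sim$noise_sd > 0, "sim.noise_sd", "must be > 0")
  chk(cfg$seeds$n_perm >= 1, "seeds.n_perm", "must be >= 1")
  chk(cfg$pls$n_perm >= 1, "pls.n_perm", "must be >= 1")
  chk(cfg$pls$n_boot >= 2, "pls.n_boot", "must be >= 2")
  chk(cfg$pls$reference_group %in% c("all", "CN"), "pls.reference_group",
      "must be 'all' or 'CN'")
  chk(cfg$staging$bin_size >= 1, "staging.bin_size", "must be >= 1")
  chk(cfg$staging$strategy %in% c("split", "merged"), "staging.strategy",
      "must be 'split' or 'merged'")
  chk(cfg$groupstats$n_perm >= 1, "groupstats.n_perm", "must be >= 1")
  chk(cfg$svc$n_rep >= 1, "svc.n_rep", "must be >= 1")
  chk(cfg$svc$threshold <= cfg$svc$n_rep, "svc.threshold",
      "must not exceed n_rep")
  chk(cfg$svc$folds >= 2, "svc.folds", "must be >= 2")
  chk(cfg$svc$penalty %in% c("group_lasso", "ridge"), "svc.penalty",
      "must be 'group_lasso' or 'ridge'")
  chk(cfg$seeds$alpha > 0 && cfg$seeds$alpha < 1, "seeds.alpha",
      "must be in (0, 1)")
  if ("svc" %in% cfg$stages && !"simulate" %in% cfg$stages &&
      !"scores" %in% cfg$stages && is.null(cfg$output))
    abort("config output: svc stage needs serialized scores/phenotypes")

  flat <- function(x, path = "") {
    purrr::imap(x, function(v, k) {
      if (is.list(v) && !is.null(names(v))) flat(v, paste0(path, k, "."))
      else tibble(key = paste0(path, k),
                  value = paste(format(v), collapse = ", "))
    }) |> purrr::list_rbind()
  }
  list(config = cfg, report = flat(cfg))
}

#' Run the analysis pipeline
#'
#' Executes the configured contiguous subsequence of stages
#' (simulate, seeds, pls, scores, groupstats, svc) with deterministic
#' per-stage seeds derived from the master seed, writing every artifact
#' under the output directory: the cohort fixture, the seed table, score
#' table, group comparisons, the selection/curve tables of the
#' varying-coefficient models, and a run summary stamped with a
#' configuration hash and the seed. Stages not run in this invocation load
#' their inputs from previously serialised artifacts and fail with the
#' name of the missing artifact otherwise.
#'
#' @param config Configuration list or YAML path (see
#'   [validate_config()]).
#' @return The output directory, invisibly; the run summary is written as
#'   `run_summary.json`.
#' @export
run_pipeline <- function(config = NULL) {
  vc <- validate_config(config)
  cfg <- vc$config
  out <- cfg$output
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  stages <- cfg$stages
  log_path <- file.path(out, "pipeline.log")
  logmsg <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                              "\n", sep = "", file = log_path,
                              append = TRUE)

  cohort <- NULL; seeds_tbl <- NULL; pls_tbl <- NULL; scores <- NULL
  need_cohort <- function() {
    if (!is.null(cohort)) return(cohort)
    dir <- file.path(out, "cohort")
    if (!dir.exists(dir))
      abort("missing artifact: cohort/ (run the simulate stage first)")
    read_cohort_fixture(dir)
  }
  need_seeds <- function(grid) {
    if (!is.null(seeds_tbl)) return(seeds_tbl)
    path <- file.path(out, "seeds.tsv")
    if (!file.exists(path))
      abort("missing artifact: seeds.tsv (run the seeds stage first)")
    tb <- as_tibble(read.delim(path))
    tb$mask <- purrr::pmap(tb[, c("x", "y", "z", "radius_mm")],
                           function(x, y, z, radius_mm)
                             sphere_mask(grid, c(x, y, z), radius_mm))
    tb
  }

  if ("simulate" %in% stages) {
    logmsg("simulate: seed ", derive_seed(seed, 1))
    sim_args <- cfg$sim
    sim_args$rng_seed <- derive_seed(seed, 1)
    cohort <- generate_cohort(do.call(sim_config, sim_args))
    write_cohort_fixture(cohort, file.path(out, "cohort"))
    write.table(cohort$phenotypes, file.path(out, "phenotypes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if ("seeds" %in% stages) {
    cohort <- need_cohort()
    logmsg("seeds: ", cfg$seeds$n_perm, " permutations")
    seeds_tbl <- define_seeds(cohort, n_perm = cfg$seeds$n_perm,
                              alpha = cfg$seeds$alpha,
                              search_radius_mm = cfg$seeds$search_radius_mm,
                              radius_mm = cfg$seeds$radius_mm,
                              seed = derive_seed(seed, 2))
    write_seeds_tsv(seeds_tbl, file.path(out, "seeds.tsv"))
    con_dir <- file.path(out, "contrasts")
    dir.create(con_dir, showWarnings = FALSE)
    maps <- attr(seeds_tbl, "contrasts")
    for (mod in names(maps)) {
      gd <- maps[[mod]]
      for (what in c("t", "tfce", "p_fwe"))
        write_map_nifti(gd[[what]], gd$grid,
                        file.path(con_dir, paste0(mod, "_", what, ".nii")),
                        mask = gd$mask)
    }
  }
  if ("pls" %in% stages) {
    cohort <- need_cohort()
    seeds_tbl <- need_seeds(cohort$gmv$grid)
    logmsg("pls: ", nrow(seeds_tbl), " seeds x 2 modalities")
    pls_tbl <- run_seed_pls(cohort, seeds_tbl, n_perm = cfg$pls$n_perm,
                            n_boot = cfg$pls$n_boot,
                            seed = derive_seed(seed, 3))
    sal_dir <- file.path(out, "salience")
    dir.create(sal_dir, showWarnings = FALSE)
    grid <- cohort$gmv$grid
    purrr::pwalk(pls_tbl, function(seed, modality, lv, ...) {
      write_map_nifti(lv$u, grid,
                      file.path(sal_dir, paste0(seed, "_", modality,
                                                "_salience.nii")),
                      mask = cohort$gmv$mask)
      write_map_nifti(lv$bsr, grid,
                      file.path(sal_dir, paste0(seed, "_", modality,
                                                "_bsr.nii")),
                      mask = cohort$gmv$mask)
    })
  }
  if ("scores" %in% stages) {
    if (is.null(pls_tbl))
      abort("missing artifact: in-memory PLS results (run the pls stage)")
    cohort <- need_cohort()
    scores <- compute_network_scores(cohort, pls_tbl,
                                     reference_group =
                                       cfg$pls$reference_group)
    write_scores_tsv(scores, file.path(out, "scores.tsv"))
    logmsg("scores: ", ncol(scores) - 1, " network columns")
  }
  need_scores <- function() {
    if (!is.null(scores)) return(scores)
    path <- file.path(out, "scores.tsv")
    if (!file.exists(path))
      abort("missing artifact: scores.tsv (run the scores stage first)")
    as_tibble(read.delim(path, check.names = FALSE))
  }
  if ("groupstats" %in% stages) {
    cohort <- need_cohort()
    scores <- need_scores()
    res <- purrr::map(c("diagnosis", "pathology"), function(fc) {
      compare_network_scores(scores, cohort$phenotypes, factor_col = fc,
                             n_perm = cfg$groupstats$n_perm,
                             alpha = cfg$groupstats$alpha,
                             seed = derive_seed(seed, 4))
    }) |> purrr::list_rbind()
    flat <- tidyr::unnest(res, "posthoc")
    write.table(flat, file.path(out, "groupstats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    logmsg("groupstats: ", nrow(flat), " pairwise tests")
  }
  if ("svc" %in% stages) {
    cohort <- need_cohort()
    scores <- need_scores()
    for (pg in cfg$svc$pathology_groups) {
      logmsg("svc: pathology group ", pg)
      sm <- svc_memory_analysis(
        scores, cohort$phenotypes, pathology = pg,
        strategy = cfg$staging$strategy,
        bin_size = cfg$staging$bin_size,
        M = cfg$svc$M, degree = cfg$svc$degree,
        n_rep = cfg$svc$n_rep, threshold = cfg$svc$threshold,
        folds = cfg$svc$folds, penalty = cfg$svc$penalty,
        n_lambda = cfg$svc$n_lambda, ratio = cfg$svc$ratio,
        base_seed = derive_seed(seed, 5))
      tag <- gsub("[^A-Za-z0-9]", "", pg)
      write.table(sm$frequency,
                  file.path(out, paste0("svc_selection_", tag, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(sm$curves,
                  file.path(out, paste0("svc_curves_", tag, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(pathology = pg, n_rep = sm$n_rep, threshold = sm$threshold,
             penalty = sm$penalty,
             kept = sm$frequency$predictor[sm$frequency$kept],
             lambda_median = stats::median(sm$lambdas)),
        file.path(out, paste0("svc_summary_", tag, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
  }
  jsonlite::write_json(
    list(config_hash = rlang::hash(cfg), seed = seed, stages = stages,
         finished = format(Sys.time())),
    file.path(out, "run_summary.json"), auto_unbox = TRUE)
  invisible(out)
}
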