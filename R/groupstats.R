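#' Residualise network scores on nuisance variables
#'
#' OLS residuals of each score column on the nuisance design (age, gender,
#' education, APOE e4, intracranial volume, site in the reference
#' analysis); residuals are orthogonal to every nuisance column. Collinear
#' designs are refused with the offending columns named.
#'
#' @param scores Data frame or matrix of score columns (an `id` column, if
#'   present, is carried through untouched).
#' @param nuisance Data frame of nuisance covariates, row-aligned.
#' @return Tibble of residualised scores (same columns).
#' @export
residualize_scores <- function(scores, nuisance) {
  scores <- as_tibble(scores)
  id <- NULL
  if ("id" %in% names(scores)) { id <- scores$id; scores$id <- NULL }
  res <- regress_nuisance(as.matrix(scores), nuisance)
  out <- as_tibble(as.data.frame(res))
  if (!is.null(id)) out <- dplyr::bind_cols(tibble(id = id), out)
  out
}

# one-way ANOVA F statistic, between/within mean square ratio
f_stat_oneway <- function(x, g) {
  n <- length(x); k <- nlevels(g)
  gm <- tapply(x, g, mean); gn <- tabulate(g)
  ssb <- sum(gn * (gm - mean(x))^2)
  ssw <- sum((x - gm[g])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Permutation one-way ANOVA
#'
#' Non-parametric omnibus test of a group effect: the observed F statistic
#' is referred to the distribution of F under random permutation of the
#' group labels; `p = (1 + #\{F_perm >= F_obs\}) / (n_perm + 1)`.
#'
#' @param x Numeric response (typically a residualised network score).
#' @param groups Factor of group labels (>= 2 levels, >= 2 per group).
#' @param n_perm Number of permutations (default 5000).
#' @param seed Optional RNG seed.
#' @return Named list: `f`, `p`.
#' @export
perm_anova <- function(x, groups, n_perm = 5000, seed = NULL) {
  g <- droplevels(as.factor(groups))
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(tabulate(g) < 2)) abort("every group needs >= 2 subjects")
  f_obs <- f_stat_oneway(x, g)
  run <- function()
    vapply(seq_len(n_perm),
           function(b) f_stat_oneway(x, g[sample.int(length(x))]),
           numeric(1))
  f_null <- if (is.null(seed)) run() else with_seed(seed, run())
  list(f = f_obs, p = (1 + sum(f_null >= f_obs)) / (n_perm + 1))
}

# two-sided permutation two-sample t-test p-value
perm_t_test <- function(x, g2, n_perm = 5000) {
  is_a <- g2 == levels(g2)[1]
  t_obs <- t_stat_two_sample(matrix(x, ncol = 1), is_a)
  t_null <- vapply(seq_len(n_perm), function(b) {
    t_stat_two_sample(matrix(x[sample.int(length(x))], ncol = 1), is_a)
  }, numeric(1))
  list(t = t_obs, p = (1 + sum(abs(t_null) >= abs(t_obs))) / (n_perm + 1))
}

#' Post-hoc pairwise permutation t-tests with Holm correction
#'
#' Two-sided permutation two-sample t-tests for each group pair, with
#' Bonferroni-Holm step-down correction over the pair family and decisions
#' at the adjusted alpha.
#'
#' @param x Numeric response.
#' @param groups Group factor.
#' @param pairs Optional list of length-2 character vectors; default all
#'   pairs of observed levels.
#' @param n_perm Permutations per pair (default 5000).
#' @param alpha Family-wise level (default 0.05).
#' @param seed Optional RNG seed (one stream for the whole family).
#' @return Tibble: `pair`, `t`, `p_raw`, `p_holm`, `reject`.
#' @export
posthoc_holm <- function(x, groups, pairs = NULL, n_perm = 5000,
                         alpha = 0.05, seed = NULL) {
  g <- droplevels(as.factor(groups))
  if (is.null(pairs)) {
    lv <- levels(g)
    pairs <- utils::combn(lv, 2, simplify = FALSE)
  }
  run <- function() {
    purrr::map(pairs, function(pr) {
      sel <- g %in% pr
      gg <- factor(as.character(g[sel]), levels = pr)
      res <- perm_t_test(x[sel], gg, n_perm)
      tibble(pair = paste(pr, collapse = " vs "), t = res$t, p_raw = res$p)
    }) |> purrr::list_rbind()
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  out$p_holm <- p.adjust(out$p_raw, method = "holm")
  out$reject <- out$p_holm <= alpha
  out
}

#' Compare network scores across stages or pathology groups
#'
#' The full group-comparison stage: nuisance covariates are regressed out
#' of every network score, then each score is tested for an omnibus group
#' effect by permutation ANOVA and, pairwise, by permutation t-tests with
#' Holm correction.
#'
#' @param scores Score tibble (`id` + network columns) from
#'   [compute_network_scores()].
#' @param phenotypes Phenotype tibble, row-aligned by `id`.
#' @param factor_col `"diagnosis"` (cognitive stage) or `"pathology"`.
#' @param nuisance_cols Phenotype columns regressed out first.
#' @param n_perm Permutations for both omnibus and post-hoc tests.
#' @param alpha Significance level (default 0.05).
#' @param seed Optional RNG seed (one per comparison family).
#' @return Tibble: `network`, `factor`, `omnibus_f`, `omnibus_p`, and a
#'   `posthoc` list-column of pairwise tables.
#' @export
compare_network_scores <- function(scores, phenotypes,
                                   factor_col = c("diagnosis", "pathology"),
                                   nuisance_cols = c("age", "gender",
                                                     "education", "apoe4",
                                                     "icv", "site"),
                                   n_perm = 5000, alpha = 0.05,
                                   seed = NULL) {
  factor_col <- match.arg(factor_col)
  ph <- phenotypes[match(scores$id, phenotypes$id), ]
  adj <- residualize_scores(scores, ph[, nuisance_cols, drop = FALSE])
  networks <- setdiff(names(adj), "id")
  g <- droplevels(as.factor(ph[[factor_col]]))
  purrr::map(networks, function(nw) {
    s <- if (is.null(seed)) NULL else seed + match(nw, networks)
    om <- perm_anova(adj[[nw]], g, n_perm = n_perm, seed = s)
    ph_tbl <- posthoc_holm(adj[[nw]], g, n_perm = n_perm, alpha = alpha,
                           seed = if (is.null(s)) NULL else s + 500L)
    tibble(network = nw, factor = factor_col,
           omnibus_f = om$f, omnibus_p = om$p, posthoc = list(ph_tbl))
  }) |> purrr::list_rbind()
}
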