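#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted varying-coefficient model
#'
#' One row per predictor per bin with the reconstructed coefficient value.
#'
#' @param x An `svc_fit`.
#' @param ... Unused.
#' @return Tibble: `predictor`, `bin`, `estimate`, `selected`.
#' @export
tidy.svc_fit <- function(x, ...) {
  tb <- tidyr::expand_grid(predictor = x$predictors,
                           bin = seq_len(x$basis$K))
  tb$estimate <- as.numeric(t(x$beta_curves)[cbind(tb$bin,
    match(tb$predictor, x$predictors))])
  tb$selected <- tb$predictor %in% x$selected
  tb
}

#' @rdname tidy.svc_fit
#' @export
glance.svc_fit <- function(x, ...) {
  tibble(lambda = x$lambda, penalty = x$penalty,
         n_selected = length(x$selected), objective = x$objective,
         converged = x$converged, n_iter = x$n_iter,
         max_kkt = if (all(is.na(x$kkt))) NA_real_ else max(x$kkt))
}

#' Tidy a repeated-selection summary
#'
#' Coefficient-curve means and standard errors across repetitions, joined
#' with each predictor's selection frequency.
#'
#' @param x A `selection_summary`.
#' @param ... Unused.
#' @return Tibble: `predictor`, `bin`, `mean`, `se`, `n_selected`, `kept`.
#' @export
tidy.selection_summary <- function(x, ...) {
  dplyr::left_join(x$curves, x$frequency, by = "predictor")
}

#' @rdname tidy.selection_summary
#' @export
glance.selection_summary <- function(x, ...) {
  tibble(n_rep = x$n_rep, threshold = x$threshold, penalty = x$penalty,
         n_kept = sum(x$frequency$kept),
         lambda_median = stats::median(x$lambdas))
}

#' Tidy a latent variable
#'
#' @param x A `latent_variable`.
#' @param ... Unused.
#' @return Tibble: `voxel`, `salience`, `bsr` (when computed).
#' @export
tidy.latent_variable <- function(x, ...) {
  tb <- tibble(voxel = seq_along(x$u), salience = x$u)
  if (!is.null(x$bsr)) tb$bsr <- as.numeric(x$bsr)
  tb
}

#' @rdname tidy.latent_variable
#' @export
glance.latent_variable <- function(x, ...) {
  tibble(s = x$s, p_perm = x$p_perm %||% NA_real_,
         degenerate = isTRUE(x$degenerate))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot coefficient trajectories of a repeated-selection summary
#'
#' Mean coefficient curves with pointwise mean +/- 2 SE ribbons across
#' repetitions, one panel per predictor; by default only predictors kept
#' by the selection rule are shown.
#'
#' @param object A `selection_summary`.
#' @param kept_only Show only kept predictors (default TRUE; falls back to
#'   the 5 most frequently selected when none is kept).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.selection_summary <- function(object, kept_only = TRUE, ...) {
  tb <- tidy(object)
  if (kept_only) {
    keep <- unique(tb$predictor[tb$kept])
    if (!length(keep))
      keep <- object$frequency$predictor[
        order(-object$frequency$n_selected)][1:5]
    tb <- tb[tb$predictor %in% keep, ]
  }
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$bin, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - 2 * .data$se,
                                      ymax = .data$mean + 2 * .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~predictor) +
    ggplot2::labs(x = "pseudo-stage bin",
                  y = "coefficient (z-scale)",
                  title = "Stage-varying network-memory associations") +
    ggplot2::theme_minimal()
}

#' Plot the coefficient functions of one fit
#'
#' @param object An `svc_fit`.
#' @param selected_only Show only selected predictors (default TRUE).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.svc_fit <- function(object, selected_only = TRUE, ...) {
  tb <- tidy(object)
  if (selected_only && any(tb$selected)) tb <- tb[tb$selected, ]
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$bin, y = .data$estimate,
                                   colour = .data$predictor)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pseudo-stage bin", y = "coefficient (z-scale)") +
    ggplot2::theme_minimal()
}

#' Plot network scores by group
#'
#' Distribution of each network score across cognitive stages or pathology
#' groups.
#'
#' @param scores Score tibble (`id` + network columns).
#' @param phenotypes Phenotype tibble with `id` and the grouping column.
#' @param group Grouping column name (default `"diagnosis"`).
#' @param networks Optional subset of network columns.
#' @return A ggplot.
#' @export
plot_network_scores <- function(scores, phenotypes, group = "diagnosis",
                                networks = NULL) {
  tb <- dplyr::left_join(scores, phenotypes[, c("id", group)], by = "id")
  long <- tidyr::pivot_longer(tb, cols = -c("id", dplyr::all_of(group)),
                              names_to = "network", values_to = "score")
  if (!is.null(networks)) long <- long[long$network %in% networks, ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[group]], y = .data$score,
                                     fill = .data[[group]])) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~network, scales = "free_y") +
    ggplot2::labs(y = "network score (z)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot an axial slice of a group-difference map
#'
#' @param x A `group_difference_map`.
#' @param slice Axial (z) slice index; default the middle slice.
#' @param what `"t_thresh"`, `"t"`, `"tfce"` or `"p_fwe"`.
#' @return A ggplot.
#' @export
plot_difference_slice <- function(x, slice = NULL,
                                  what = c("t_thresh", "t", "tfce",
                                           "p_fwe")) {
  what <- match.arg(what)
  arr <- embed_map(x$grid, x[[what]], x$mask)
  if (is.null(slice)) slice <- ceiling(dim(arr)[3] / 2)
  sl <- arr[, , slice]
  tb <- tidyr::expand_grid(i = seq_len(nrow(sl)), j = seq_len(ncol(sl)))
  tb$value <- sl[cbind(tb$i, tb$j)]
  ggplot2::ggplot(tb, ggplot2::aes(.data$i, .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0(what, ", axial slice ", slice)) +
    ggplot2::theme_void()
}
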