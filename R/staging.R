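#' Rule-based diagnostic classification from MMSE and CDR
#'
#' Applies the screening rules used to define the cognitive stages:
#' cognitively normal (CN) requires MMSE >= 24 with global CDR 0; mild
#' cognitive impairment (MCI) requires MMSE >= 24 with global CDR 0.5;
#' probable Alzheimer's dementia (AD) requires MMSE <= 26 with global
#' CDR >= 0.5. Where MMSE 24-26 with CDR 0.5 satisfies both the MCI and AD
#' rules the classifier returns MCI: the AD definition additionally rests on
#' clinical criteria a score-based rule cannot reproduce, so AD is only
#' assigned when MCI is excluded. Records matching no rule are flagged
#' `"unclassifiable"`, never silently defaulted. Intended as a helper when a
#' curated diagnosis column is absent; pipelines should pass a given
#' diagnosis through untouched.
#'
#' @param mmse Integer MMSE score, 0-30.
#' @param cdr_global Global CDR: 0, 0.5, 1, 2, 3.
#' @param cdr_sob CDR sum of boxes (unused by the rules; accepted so that
#'   callers can pass the full score triplet).
#' @return Factor with levels CN, MCI, AD, unclassifiable.
#' @export
classify_diagnosis <- function(mmse, cdr_global, cdr_sob = NULL) {
  if (any(mmse < 0 | mmse > 30, na.rm = TRUE))
    abort("mmse must lie in [0, 30]")
  out <- rep("unclassifiable", length(mmse))
  out[mmse >= 24 & cdr_global == 0] <- "CN"
  out[mmse >= 24 & cdr_global == 0.5] <- "MCI"
  ad <- mmse <= 26 & cdr_global >= 0.5 & out == "unclassifiable"
  out[ad] <- "AD"
  factor(out, levels = c("CN", "MCI", "AD", "unclassifiable"))
}

#' Amyloid/tau pathology stratification from CSF biomarkers
#'
#' Classifies participants into three pathology strata from CSF biomarkers
#' using the published cutoffs: amyloid positivity (A+) when
#' A-beta 1-42 < 192 pg/mL, tau positivity when p-tau 181 > 23 pg/mL. Both
#' inequalities are strict. Amyloid-positive participants form a single A+
#' stratum regardless of tau status (A+T- and A+T+ are never analysed
#' separately); amyloid-negative participants split into A-T+ and A-T-.
#'
#' @param csf_abeta CSF A-beta 1-42 in pg/mL (positive).
#' @param csf_ptau CSF p-tau 181 in pg/mL (positive).
#' @param abeta_cutoff,ptau_cutoff Positivity cutoffs in pg/mL.
#' @return Factor with levels `A-T-`, `A-T+`, `A+`; `NA` inputs give `NA`.
#' @export
stratify_pathology <- function(csf_abeta, csf_ptau,
                               abeta_cutoff = 192, ptau_cutoff = 23) {
  if (any(csf_abeta <= 0 | csf_ptau <= 0, na.rm = TRUE))
    abort("CSF values must be positive")
  out <- ifelse(csf_abeta < abeta_cutoff, "A+",
                ifelse(csf_ptau > ptau_cutoff, "A-T+", "A-T-"))
  factor(out, levels = c("A-T-", "A-T+", "A+"))
}

#' Pseudo-stage ordering of a cohort
#'
#' Produces the deterministic disease-severity ordering the varying
#' coefficient model runs along. Participants are ordered primarily by
#' cognitive stage (CN, then MCI, then AD); within CN by decreasing MMSE,
#' within MCI and AD by increasing CDR sum of boxes; remaining ties by
#' increasing age, then by participant id for full determinism. With
#' `strategy = "merged"` the MCI and AD groups are pooled and ordered
#' together by CDR-SOB (the alternative ordering used as a robustness
#' check); with `"split"` they are ordered within their own stage blocks.
#'
#' @param phenotypes Data frame with columns `id`, `diagnosis` (CN/MCI/AD),
#'   `mmse`, `cdr_sob`, `age`.
#' @param strategy `"split"` (default) or `"merged"`.
#' @return The input as a tibble, reordered, with an `order` column
#'   (1..n).
#' @export
order_participants <- function(phenotypes, strategy = c("split", "merged")) {
  strategy <- match.arg(strategy)
  ph <- as_tibble(phenotypes)
  if (nrow(ph) == 0) return(dplyr::mutate(ph, order = integer()))
  need <- c("id", "diagnosis", "mmse", "cdr_sob", "age")
  miss <- setdiff(need, names(ph))
  if (length(miss))
    abort(paste("missing columns:", paste(miss, collapse = ", ")))
  stage <- factor(as.character(ph$diagnosis), levels = c("CN", "MCI", "AD"))
  if (anyNA(stage)) abort("diagnosis must be CN, MCI or AD")
  block <- if (strategy == "merged")
    ifelse(stage == "CN", 1L, 2L) else as.integer(stage)
  # CN: MMSE descending; impaired stages: CDR-SOB ascending
  key1 <- ifelse(block == 1L, -ph$mmse, ph$cdr_sob)
  ord <- order(block, key1, ph$age, as.character(ph$id), method = "radix")
  out <- ph[ord, , drop = FALSE]
  out$order <- seq_len(nrow(out))
  out
}

#' Distribute ordered participants evenly into contiguous bins
#'
#' Cuts the pseudo-stage order into `K = ceiling(n / bin_size)` contiguous
#' bins whose sizes differ by at most one, the larger bins first. With `n`
#' divisible by `bin_size` every bin holds exactly `bin_size` participants
#' (the reference analysis used 10/bin); otherwise the near-even partition
#' preserves both order and balance.
#'
#' @param ordered A data frame carrying an `order` column, as returned by
#'   [order_participants()], or any ordered cohort table.
#' @param bin_size Target participants per bin (default 10).
#' @return The input tibble with a `bin` column (1..K, non-decreasing along
#'   the order).
#' @export
bin_participants <- function(ordered, bin_size = 10) {
  if (bin_size < 1) abort("bin_size must be >= 1")
  ph <- as_tibble(ordered)
  n <- nrow(ph)
  if (n == 0) return(dplyr::mutate(ph, bin = integer()))
  if (!"order" %in% names(ph)) ph$order <- seq_len(n)
  K <- ceiling(n / bin_size)
  base <- n %/% K
  extra <- n %% K # first `extra` bins get one more
  sizes <- rep(base, K) + c(rep(1L, extra), rep(0L, K - extra))
  idx <- rep(seq_len(K), times = sizes)
  ph$bin <- idx[rank(ph$order, ties.method = "first")]
  ph
}

#' Order and bin a cohort in one step
#'
#' Convenience wrapper: [order_participants()] then [bin_participants()],
#' applied within each pathology group when a `pathology` column is present
#' (the varying-coefficient models run per pathology group, each with its
#' own pseudo-stage axis).
#'
#' @inheritParams order_participants
#' @inheritParams bin_participants
#' @param per_pathology Order/bin within `pathology` levels (default TRUE
#'   when the column exists).
#' @return Tibble with `order` and `bin` columns (per group when grouped).
#' @export
stage_cohort <- function(phenotypes, strategy = c("split", "merged"),
                         bin_size = 10,
                         per_pathology = "pathology" %in% names(phenotypes)) {
  strategy <- match.arg(strategy)
  ph <- as_tibble(phenotypes)
  if (!per_pathology)
    return(bin_participants(order_participants(ph, strategy), bin_size))
  ph |>
    dplyr::group_split(.data$pathology) |>
    purrr::map(\(g) bin_participants(order_participants(g, strategy),
                                     bin_size)) |>
    purrr::list_rbind()
}
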