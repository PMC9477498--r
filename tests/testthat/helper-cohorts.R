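# Shared fixtures, built in code and cached per test run.

the_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = the_cache)) assign(key, expr, envir = the_cache)
  get(key, envir = the_cache)
}

# mid-sized cohort with images at the default study conditions
default_cohort <- function() {
  cached("default_cohort", generate_cohort(sim_config(n_per_cell = 45,
                                                      rng_seed = 301)))
}

# small cohort with images, for cheap structural checks
small_cohort <- function() {
  cached("small_cohort", generate_cohort(sim_config(n_per_cell = 5,
                                                    rng_seed = 302)))
}

# tabular-only cohort at the regression-stage study size (300 per
# pathology group, K = 30 bins)
tabular_cohort <- function(seed = 303) {
  cached(paste0("tabular_cohort_", seed),
         generate_cohort(sim_config(n_per_cell = 100, rng_seed = seed),
                         images = FALSE))
}

# score table built from the true loadings (noise-free network measures)
truth_scores <- function(cohort) {
  dplyr::bind_cols(tibble::tibble(id = cohort$phenotypes$id),
                   tibble::as_tibble(cohort$truth$loadings))
}

# independent brute-force TFCE: enumerate thresholds, label clusters by
# repeated neighbour expansion (no union-find), accumulate extent^E h^H dh
tfce_brute <- function(map, E = 0.5, H = 2, dh) {
  dims <- dim(map)
  out <- array(0, dims)
  mx <- max(map)
  if (mx <= 0) return(out)
  hs <- seq(dh, mx, by = dh)
  idx_of <- function(i, j, k) c(i, j, k)
  for (h in hs) {
    supra <- map >= h
    lab <- array(0L, dims)
    nxt <- 0L
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
      for (k in seq_len(dims[3])) {
        if (!supra[i, j, k] || lab[i, j, k] != 0L) next
        nxt <- nxt + 1L
        queue <- list(c(i, j, k))
        lab[i, j, k] <- nxt
        while (length(queue)) {
          v <- queue[[1]]; queue <- queue[-1]
          for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                         c(0, 0, 1), c(0, 0, -1))) {
            w <- v + d
            if (any(w < 1) || any(w > dims)) next
            if (supra[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
              lab[w[1], w[2], w[3]] <- nxt
              queue <- c(queue, list(w))
            }
          }
        }
      }
    sizes <- tabulate(lab[lab > 0L])
    inc <- array(0, dims)
    inc[supra] <- sizes[lab[supra]]^E * h^H * dh
    out <- out + inc
  }
  out
}
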