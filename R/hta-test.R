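#' Test spatial heterogeneity of trait combinations
#'
#' The package's main entry point: computes the HTA statistic of a
#' trait-combination matrix at a given region size and assesses it
#' against the permutation null model (random rearrangement of the
#' observed combinations over the occupied positions), returning the
#' statistic, the estimated null moments, the standardised z and the
#' one-sided and overall p-values in one classed object.
#'
#' Low HTA relative to the null indicates spatial homogeneity
#' (combinations segregated into regions); high HTA indicates spatial
#' heterogeneity (combinations mixed within regions).  Interpretation
#' should rely on the p-values rather than on the raw statistic, since
#' the null depends on the observed combination composition.
#'
#' @param m a [trait_matrix()], e.g. from [encode_combinations()] or one
#'   of the synthetic generators.
#' @inheritParams partition_grid
#' @param n_permutations permutations used to estimate the null moments
#'   (default 1000; 100 is usually enough for very large maps).
#' @param seed integer seed governing all permutations.
#' @param method `"permutation"` (default) estimates per-region null
#'   moments by simulation; `"exact"` enumerates the region-HTI null
#'   exactly under the uniform per-cell model (requires `n_traits`,
#'   equal-size fully-occupied regions and a small region; see
#'   [exact_region_moments()]).
#' @param n_traits trait count, required for `method = "exact"`.
#' @param min_R threshold below which the normal approximation triggers a
#'   warning (default 30).
#' @return an object of class `hta_test`: list with `statistic`
#'   (`hta_stat`), `moments` (`null_moments`), `p` (`hta_pvalues`), plus
#'   `region_size`, `seed` and `call`.  Methods: `print`, `summary`,
#'   `plot`, `simulate`.
#' @examples
#' m <- random_uniform_map(c(32, 32), n_traits = 2, seed = 1)
#' fit <- hta_test(m, region_size = 8, n_permutations = 200, seed = 1)
#' fit
#' @export
hta_test <- function(m, region_size, n_permutations = 1000, seed = NULL,
                     method = c("permutation", "exact"), n_traits = NULL,
                     min_R = 30) {
  method <- match.arg(method)
  assert_trait_matrix(m)
  stat <- hta_index(m, region_size)
  if (method == "exact") {
    if (is.null(n_traits))
      stop("`n_traits` is required for the exact moment path", call. = FALSE)
    if (length(unique(stat$partition$n_r)) != 1L)
      warning("regions have unequal occupancy; the exact path assumes ",
              "equal-weight regions", call. = FALSE)
    moments <- exact_region_moments(stat$region_size, n_traits)
  } else {
    moments <- estimate_null_moments(m, region_size,
                                     n_permutations = n_permutations,
                                     seed = seed)
  }
  p <- hta_p_values(stat, moments, min_R = min_R)
  structure(list(statistic = stat, moments = moments, p = p,
                 region_size = stat$region_size, seed = seed,
                 matrix = m, call = match.call()),
            class = "hta_test")
}

#' @export
print.hta_test <- function(x, digits = 4, ...) {
  cat("\n\tHTA heterogeneity test (", x$moments$method, " null)\n\n",
      sep = "")
  cat(sprintf("HTA = %s, region size (%s), R = %d, C = %d\n",
              format(x$statistic$hta, digits = digits),
              paste(x$region_size, collapse = ", "),
              x$statistic$R, x$statistic$C))
  cat(sprintf("null mean = %s, null sd = %s, z = %s\n",
              format(x$p$null_mean, digits = digits),
              format(x$p$null_sd, digits = digits),
              format(x$p$z, digits = digits)))
  cat(sprintf("P(homogeneity) = %s, P(heterogeneity) = %s, overall P = %s\n",
              format(x$p$p_homogeneity, digits = digits),
              format(x$p$p_heterogeneity, digits = digits),
              format(x$p$p_overall, digits = digits)))
  invisible(x)
}

#' @export
summary.hta_test <- function(object, ...) {
  structure(list(fit = object), class = "summary.hta_test")
}

#' @export
print.summary.hta_test <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  st <- f$statistic
  cat("\nPer-region HTI:\n")
  df <- data.frame(region = seq_len(st$R), n_r = st$partition$n_r,
                   weight = st$weights, hti = st$hti_per_region)
  if (f$moments$method == "permutation") {
    df$null_mu <- f$moments$mu
    df$null_sigma <- f$moments$sigma
  }
  print(df, digits = digits, row.names = FALSE)
  if (f$moments$method == "permutation" && f$moments$n_single_entry > 0)
    cat(sprintf("\n%d single-entry region(s): HTI pinned at 0.\n",
                f$moments$n_single_entry))
  invisible(x)
}

#' Simulate HTA values under the null model
#'
#' Draws `nsim` fresh permutations of the fitted matrix and recomputes
#' HTA for each, giving the empirical null distribution of the statistic
#' at the fitted region size (a debug cross-check of the normal
#' approximation; the CLT p-values are the primary inference).
#'
#' @param object an `hta_test` fit.
#' @param nsim number of null draws.
#' @param seed optional seed.
#' @param ... unused.
#' @return a data.frame with column `hta` of length `nsim`.
#' @export
simulate.hta_test <- function(object, nsim = 100, seed = NULL, ...) {
  part <- object$statistic$partition
  m <- object$matrix
  lab <- label_array(m)
  occ <- which(!is.na(lab))
  lab_occ <- lab[occ]
  reg_occ <- part$region_of[occ]
  R <- part$R; C <- part$C; n <- length(occ)
  vals <- with_seed(seed, vapply(seq_len(nsim), function(i) {
    lp <- lab_occ[sample.int(n)]
    cnt <- matrix(tabulate(reg_occ + R * (lp - 1L), nbins = R * C), R, C)
    sum(part$weights * region_hti(cnt, part$n_r, C))
  }, numeric(1)))
  data.frame(hta = vals)
}
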