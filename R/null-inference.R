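# Null model: a uniform random rearrangement of the observed combination
# labels over the occupied positions.  It preserves the label frequencies
# and the occupancy mask exactly, so region weights n_r/n are constant
# across permutations and only the per-region composition varies.

# run `expr` under a temporary RNG state seeded with `seed` (NULL = leave
# the current RNG stream alone)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Permute the trait combinations of a matrix
#'
#' Draws one realisation of the null model: the multiset of non-`NA`
#' labels is rearranged uniformly at random over the occupied positions,
#' while every `NA` position stays `NA`.
#'
#' @param m a [trait_matrix()] with at least one occupied entry.
#' @param seed optional integer seed making the draw reproducible without
#'   disturbing the session RNG.
#' @return a `trait_matrix` of the same shape, `C` and decoding.
#' @export
permute_combinations <- function(m, seed = NULL) {
  assert_trait_matrix(m)
  lab <- label_array(m)
  occ <- which(!is.na(lab))
  if (!length(occ)) stop("matrix has no occupied entries", call. = FALSE)
  lab[occ] <- with_seed(seed, lab[occ][sample.int(length(occ))])
  trait_matrix(lab, C = attr(m, "C"), decoding = attr(m, "decoding"))
}

#' Estimate per-region null moments by permutation
#'
#' Simulates `n_permutations` random-uniform permutations of the
#' trait-combination matrix (holding the occupied positions fixed) and,
#' for each retained region, estimates the mean and standard deviation of
#' its HTI across the permutations.  These per-region moments feed the
#' Lyapunov CLT normal approximation of [hta_p_values()].
#'
#' The standard deviation is the population (divide-by-N) form.  Regions
#' with a single occupied entry always exhibit one combination, so their
#' HTI is identically 0 and their moments are (0, 0); their count is
#' reported because a growing proportion of such regions undermines the
#' normal approximation.
#'
#' @param m a [trait_matrix()].
#' @inheritParams partition_grid
#' @param n_permutations number of null permutations (default 1000).
#' @param seed integer seed; the whole moment estimate is deterministic
#'   given `(m, region_size, n_permutations, seed)`.
#' @return an object of class `null_moments`: list with `mu`, `sigma`
#'   (length `R`), `weights`, `R`, `n_permutations`, `seed`,
#'   `method = "permutation"` and `n_single_entry` (regions with
#'   `n_r == 1`).
#' @export
estimate_null_moments <- function(m, region_size, n_permutations = 1000,
                                  seed = NULL) {
  assert_trait_matrix(m)
  part <- partition_grid(m, region_size)
  if (part$R < 2L)
    stop("only ", part$R, " non-empty region; at least 2 are needed ",
         "to average over", call. = FALSE)
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 2L)
    stop("`n_permutations` must be at least 2", call. = FALSE)

  lab <- label_array(m)
  occ <- which(!is.na(lab))
  lab_occ <- lab[occ]
  reg_occ <- part$region_of[occ]            # retained-region id per entry
  R <- part$R; C <- part$C
  n <- length(occ)

  s1 <- numeric(R); s2 <- numeric(R)
  with_seed(seed, for (i in seq_len(n_permutations)) {
    lp <- lab_occ[sample.int(n)]
    cnt <- matrix(tabulate(reg_occ + R * (lp - 1L), nbins = R * C), R, C)
    h <- region_hti(cnt, part$n_r, C)
    s1 <- s1 + h
    s2 <- s2 + h * h
  })
  mu <- s1 / n_permutations
  sigma <- sqrt(pmax(s2 / n_permutations - mu^2, 0))
  structure(list(mu = mu, sigma = sigma, weights = part$weights,
                 R = R, n_permutations = n_permutations, seed = seed,
                 method = "permutation",
                 n_single_entry = sum(part$n_r == 1L)),
            class = "null_moments")
}

#' @export
print.null_moments <- function(x, ...) {
  cat(sprintf(
    "Null moments (%s): R = %d, weighted mean = %.4f, weighted sd = %.4f\n",
    x$method, x$R, sum(x$weights * x$mu),
    sqrt(sum(x$weights^2 * x$sigma^2))))
  if (x$n_single_entry > 0)
    cat(sprintf("  %d single-entry region(s) with HTI fixed at 0\n",
                x$n_single_entry))
  invisible(x)
}

# compositions of n into k non-negative parts, as a (choose(n+k-1, k-1) x k)
# integer matrix
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  out <- vector("list", n + 1L)
  for (first in 0:n) {
    rest <- compositions(n - first, k - 1L)
    out[[first + 1L]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Exact null moments of the region HTI by exhaustive enumeration
#'
#' For small regions the null distribution of the region HTI can be
#' computed exactly rather than simulated.  The per-cell model: each of
#' `n_traits` traits is independently present with probability 1/2, so a
#' cell is uniform over all `2^t` states including the empty one; empty
#' cells are excluded from the combination counts and the moments are
#' conditioned on the region containing at least one occupied cell.  The
#' entropy log base is `C = 2^t - 1`, all non-empty combinations.
#'
#' The enumeration is organised over per-state count vectors weighted by
#' their multinomial probabilities, which visits every one of the
#' `(2^t)^cells` equally likely cell configurations exactly once while
#' touching only `choose(cells + 2^t - 1, 2^t - 1)` distinct HTI values.
#' A guard refuses configurations spaces beyond ~1e7; use the permutation
#' path ([estimate_null_moments()]) there.
#'
#' With two traits this reproduces the region HTI null `N(0.57, 0.31^2)`
#' for 2x2 regions and `N(0.83, 0.17^2)` for 3x3 regions.
#'
#' @param region_shape extents of one region, e.g. `c(2, 2)`.
#' @param n_traits number of traits `t`.
#' @param guard maximum admissible number of cell configurations.
#' @return an object of class `null_moments` with scalar `mu` and `sigma`,
#'   `method = "exact"` and `n_configs`.
#' @examples
#' exact_region_moments(c(2, 2), n_traits = 2)  # mu 0.573, sigma 0.310
#' @export
exact_region_moments <- function(region_shape, n_traits, guard = 1e7) {
  cells <- prod(as.integer(region_shape))
  t <- as.integer(n_traits)
  if (cells < 1L || t < 1L)
    stop("region must have >= 1 cell and >= 1 trait", call. = FALSE)
  S <- 2^t                                  # cell states incl. empty
  n_configs <- S^cells
  C <- as.integer(S - 1)
  if (C == 1L)                              # single trait: HTI always 0
    return(structure(list(mu = 0, sigma = 0, method = "exact",
                          region_shape = region_shape, n_traits = t,
                          n_configs = n_configs),
                     class = "null_moments"))
  if (n_configs > guard)
    stop(sprintf(paste0(
      "exhaustive enumeration of %.3g configurations exceeds the guard ",
      "(%.3g); estimate the moments by permutation instead"),
      n_configs, guard), call. = FALSE)
  cc <- compositions(cells, S)              # per-state counts (state 1 = empty)
  lw <- lgamma(cells + 1) - rowSums(lgamma(cc + 1)) - cells * log(S)
  occupied <- cells - cc[, 1L]
  keep <- occupied > 0L                     # condition on >= 1 occupied cell
  h <- vapply(which(keep), function(i) {
    cnt <- cc[i, -1L]
    p <- cnt[cnt > 0] / occupied[i]
    if (occupied[i] == 1L) 0 else -sum(p * log(p)) / log(C)
  }, numeric(1))
  w <- exp(lw[keep]); w <- w / sum(w)
  mu <- sum(w * h)
  sigma <- sqrt(max(sum(w * h^2) - mu^2, 0))
  structure(list(mu = mu, sigma = sigma, method = "exact",
                 region_shape = region_shape, n_traits = t,
                 n_configs = n_configs),
            class = "null_moments")
}

#' Normal-approximation p-values for an HTA statistic
#'
#' Standardises the observed HTA against its null moments and returns the
#' two one-sided tail probabilities plus the doubled overall p-value.
#' Under the permutation null the per-region HTIs are independent but not
#' identically distributed (region occupancies differ), so the Lyapunov
#' CLT applies to the weighted sum:
#' `z = (HTA - sum(w_r mu_r)) / sqrt(sum(w_r^2 sigma_r^2))` with
#' `w_r = n_r / n` held fixed by the preserved occupancy mask.
#'
#' The lower tail (`p_homogeneity`) tests whether combinations are more
#' spatially segregated than random; the upper tail (`p_heterogeneity`)
#' tests whether they are more mixed.  The overall significance doubles
#' the smaller of the two (capped at 1).
#'
#' @param stat an `hta_stat` from [hta_index()].
#' @param moments a `null_moments` object with matching `R` (permutation
#'   method) or an exact single-region model applied with equal weights.
#' @param min_R below this region count a warning flags the normal
#'   approximation as shaky (default 30); results are still returned.
#' @return an object of class `hta_pvalues`: list with `z`,
#'   `p_homogeneity`, `p_heterogeneity`, `p_overall`, `null_mean` and
#'   `null_sd`.
#' @export
hta_p_values <- function(stat, moments, min_R = 30) {
  if (!inherits(stat, "hta_stat"))
    stop("`stat` must come from hta_index()", call. = FALSE)
  if (!inherits(moments, "null_moments"))
    stop("`moments` must be a `null_moments` object", call. = FALSE)
  if (moments$method == "exact") {
    # equal-weight path: all regions share the enumerated (mu, sigma)
    mu0 <- moments$mu
    sd0 <- moments$sigma / sqrt(stat$R)
  } else {
    if (length(moments$mu) != stat$R)
      stop("moments were estimated for R = ", length(moments$mu),
           " regions but the statistic has R = ", stat$R, call. = FALSE)
    w <- stat$weights
    mu0 <- sum(w * moments$mu)
    sd0 <- sqrt(sum(w^2 * moments$sigma^2))
  }
  if (stat$R < min_R)
    warning("R = ", stat$R, " regions; the normal approximation may be ",
            "inaccurate below R = ", min_R, call. = FALSE)
  if (sd0 <= 0)
    stop("null variance is zero (degenerate statistic, e.g. a single ",
         "observed combination); p-values are undefined", call. = FALSE)
  z <- (stat$hta - mu0) / sd0
  p_lo <- stats::pnorm(z)
  p_hi <- stats::pnorm(z, lower.tail = FALSE)
  structure(list(z = z, p_homogeneity = p_lo, p_heterogeneity = p_hi,
                 p_overall = min(2 * min(p_lo, p_hi), 1),
                 null_mean = mu0, null_sd = sd0),
            class = "hta_pvalues")
}

#' @export
print.hta_pvalues <- function(x, digits = 4, ...) {
  cat(sprintf("z = %s; P(homogeneity) = %s, P(heterogeneity) = %s, overall = %s\n",
              format(x$z, digits = digits),
              format(x$p_homogeneity, digits = digits),
              format(x$p_heterogeneity, digits = digits),
              format(x$p_overall, digits = digits)))
  invisible(x)
}
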