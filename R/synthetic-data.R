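# Synthetic trait-combination maps.  These emulate the canonical
# constructions used to exercise the statistic: fully random maps (the
# null), per-region pure maps (extreme spatial homogeneity, HTA = 0),
# per-region balanced maps (extreme spatial heterogeneity, HTA = 1) and
# 3D maps layered along z.  All generators are deterministic given their
# seed.

# decoding for k mutually exclusive single-trait combinations
exclusive_decoding <- function(k) lapply(paste0("T", seq_len(k)), identity)

#' Random uniform trait map
#'
#' Each lattice position draws each of `n_traits` traits independently
#' with probability `p_present`; the resulting subsets are encoded as
#' combination labels and positions with no trait become `NA`.  At
#' `p_present = 0.5` every cell is uniform over all `2^t` states, which
#' is exactly the per-cell model of [exact_region_moments()] and a
#' natural null for calibration studies.
#'
#' @param shape grid extents (2D or 3D).
#' @param n_traits number of traits.
#' @param p_present per-trait presence probability in (0, 1).
#' @param seed integer seed (two runs with the same seed are identical).
#' @param c_mode passed to [encode_combinations()].
#' @return a [trait_matrix()].
#' @export
random_uniform_map <- function(shape, n_traits = 2, p_present = 0.5,
                               seed = NULL, c_mode = "observed") {
  shape <- as.integer(shape)
  if (any(shape < 1L)) stop("extents must be positive", call. = FALSE)
  if (p_present <= 0 || p_present >= 1)
    stop("`p_present` must be in (0, 1)", call. = FALSE)
  t <- as.integer(n_traits)
  pres <- with_seed(seed,
    array(stats::rbinom(prod(shape) * t, 1L, p_present),
          dim = c(shape, t)))
  tensor <- structure(list(presence = pres,
                           occupied = array(TRUE, dim = shape),
                           shape = shape,
                           trait_names = paste0("T", seq_len(t)),
                           origin = rep(0L, length(shape)),
                           threshold = rep(NA_real_, t)),
                      class = "trait_tensor")
  encode_combinations(tensor, c_mode = c_mode)
}

#' Region-pure (perfectly homogeneous) map
#'
#' Fills every grid region entirely with a single combination, cycling
#' the `n_combinations` labels across regions in approximately equal
#' numbers.  At the construction region size every region is pure, so
#' HTA is exactly 0 — the extreme of local homogeneity.
#'
#' @param shape grid extents; must be divisible by `region_size` on every
#'   axis so the construction is exact.
#' @param region_size extent per axis (scalar broadcast).
#' @param n_combinations number of mutually exclusive single-trait
#'   combinations to cycle (default 2).
#' @return a [trait_matrix()] with `C = n_combinations`.
#' @export
region_homogeneous_map <- function(shape, region_size, n_combinations = 2) {
  shape <- as.integer(shape)
  d <- length(shape)
  rs <- rep_len(as.integer(region_size), d)
  if (any(shape %% rs != 0L))
    stop("`region_size` must divide the shape exactly for the pure ",
         "construction", call. = FALSE)
  k <- as.integer(n_combinations)
  if (k < 1L) stop("need at least one combination", call. = FALSE)
  nblk <- shape %/% rs
  mult <- cumprod(c(1L, nblk[-d]))
  blk <- array(0L, dim = shape)
  for (ax in seq_len(d)) {
    ax_block <- (seq_len(shape[ax]) - 1L) %/% rs[ax]
    blk <- blk + ax_block[slice.index(blk, ax)] * mult[ax]
  }
  lab <- (blk %% k) + 1L                    # cycle combinations over regions
  trait_matrix(lab, C = k, decoding = exclusive_decoding(k))
}

#' Region-balanced (perfectly heterogeneous) map
#'
#' Fills every grid region with all `n_combinations` combinations in
#' exactly equal counts, cycling labels deterministically in array order
#' within each region.  At the construction region size every region
#' attains the maximal HTI, so HTA is exactly 1 — the extreme of local
#' heterogeneity.  (HTA depends only on within-region counts, so the
#' particular deterministic arrangement is immaterial.)
#'
#' @inheritParams region_homogeneous_map
#' @return a [trait_matrix()] with `C = n_combinations`.
#' @export
region_heterogeneous_map <- function(shape, region_size, n_combinations = 2) {
  shape <- as.integer(shape)
  d <- length(shape)
  rs <- rep_len(as.integer(region_size), d)
  if (any(shape %% rs != 0L))
    stop("`region_size` must divide the shape exactly for the balanced ",
         "construction", call. = FALSE)
  k <- as.integer(n_combinations)
  cells <- prod(rs)
  if (cells %% k != 0L)
    stop("region cell count (", cells, ") must be divisible by the ",
         k, " combinations for exact balance", call. = FALSE)
  # within-region running index in array order, cycled through the labels
  nblk <- shape %/% rs
  mult <- cumprod(c(1L, nblk[-d]))
  cmult <- cumprod(c(1L, rs[-d]))
  blk <- array(0L, dim = shape)
  within <- array(0L, dim = shape)
  for (ax in seq_len(d)) {
    ax_idx <- seq_len(shape[ax]) - 1L
    blk <- blk + (ax_idx %/% rs[ax])[slice.index(blk, ax)] * mult[ax]
    within <- within + (ax_idx %% rs[ax])[slice.index(within, ax)] * cmult[ax]
  }
  lab <- (within %% k) + 1L
  trait_matrix(lab, C = k, decoding = exclusive_decoding(k))
}

#' Layered 3D map
#'
#' Builds a 3D map in which z-layer `k` is filled entirely with
#' combination `k`.  Evaluated with regions confined to single layers
#' (e.g. region size `c(8, 8, 1)`) every region is pure and HTA = 0;
#' with regions spanning all layers (e.g. `c(8, 8, 3)`) every region
#' holds the layers' combinations in equal counts and HTA = 1.
#'
#' @param shape 3D grid extents `c(nx, ny, nz)`.
#' @param n_combinations number of distinct combinations available; must
#'   be at least the number of layers (default: one per layer).
#' @return a [trait_matrix()] with `C = n_combinations`.
#' @export
layered_z_map <- function(shape, n_combinations = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L)
    stop("`shape` must be 3-dimensional", call. = FALSE)
  nz <- shape[3L]
  if (is.null(n_combinations)) n_combinations <- nz
  k <- as.integer(n_combinations)
  if (nz > k)
    stop(nz, " layers need at least as many combinations (got ", k, ")",
         call. = FALSE)
  lab <- array(rep(seq_len(nz), each = shape[1L] * shape[2L]), dim = shape)
  trait_matrix(lab, C = k, decoding = exclusive_decoding(k))
}
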