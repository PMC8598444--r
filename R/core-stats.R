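#' Heterogeneity index of a set of combination counts
#'
#' The HTI (HeTerogeneity Index) of a region is the Shannon entropy of the
#' trait-combination proportions among its occupied positions, taken with
#' logarithm base `C` so that the index lies in `[0, 1]`:
#' `HTI = -sum(p_c * log_C(p_c))` over combinations with `p_c > 0`.
#' HTI is 0 when a single combination dominates and 1 when all `C`
#' combinations occur in equal proportion.
#'
#' Degenerate cases: with `C = 1` there is only one possible combination,
#' and with a single occupied position only one combination can manifest;
#' both give HTI = 0.
#'
#' @param counts non-negative occupancy counts per combination (zeros
#'   allowed; combinations absent from the region may be omitted).
#' @param C the combination count used as log base; must be at least the
#'   number of positive counts.
#' @return a number in `[0, 1]`.
#' @examples
#' hti(c(5, 5, 5), C = 3)       # equal thirds: 1
#' hti(c(3, 1, 0), C = 3)       # 0.512...
#' @export
hti <- function(counts, C) {
  if (!is.numeric(counts) || any(counts < 0) || any(!is.finite(counts)))
    stop("`counts` must be finite and non-negative", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("`counts` are all zero", call. = FALSE)
  C <- as.integer(C)
  k <- sum(counts > 0)
  if (C < k)
    stop("C = ", C, " is smaller than the ", k,
         " combinations present", call. = FALSE)
  if (C == 1L || total == 1) return(0)
  p <- counts[counts > 0] / total
  -sum(p * log(p)) / log(C)
}

#' Partition a trait matrix into grid regions
#'
#' Tiles the position lattice with axis-aligned blocks of the given
#' per-axis extents, anchored at the origin; trailing blocks are smaller
#' when the extents do not divide the matrix shape.  Blocks in which every
#' entry is `NA` are discarded.  All counts refer to occupied (non-`NA`)
#' entries only.
#'
#' @param m a [trait_matrix()].
#' @param region_size positive integer extent per axis; a scalar is
#'   broadcast to all axes (so `8` on a 3D matrix means `c(8, 8, 8)`;
#'   pass e.g. `c(8, 8, 1)` for slice-wise regions).  An extent larger
#'   than the matrix is clamped to one region on that axis, with a
#'   warning.
#' @return an object of class `grid_partition`: list with `R` (number of
#'   retained regions), `n` (total occupied entries), `n_r`, `counts`
#'   (`R x C` matrix of per-region combination counts), `weights`
#'   (`n_r / n`), `ranges` (per-region 0-based half-open index ranges per
#'   axis), `region_of` (integer array assigning each lattice position to
#'   its retained region, `NA` for discarded regions), `region_size`, `C`
#'   and `decoding`.
#' @export
partition_grid <- function(m, region_size) {
  assert_trait_matrix(m)
  shp <- dim(m)
  d <- length(shp)
  rs <- as.integer(region_size)
  if (length(rs) == 1L) rs <- rep(rs, d)
  if (length(rs) != d)
    stop("`region_size` must be a scalar or one extent per axis (",
         d, ")", call. = FALSE)
  if (any(rs < 1L)) stop("region extents must be positive", call. = FALSE)
  if (any(rs > shp)) {
    warning("region extent exceeds matrix extent on axis ",
            paste(which(rs > shp), collapse = ", "),
            "; clamped to a single region there", call. = FALSE)
    rs <- pmin(rs, shp)
  }
  C <- attr(m, "C")
  lab <- label_array(m)

  # block index per axis, then linear region id (column-major over blocks)
  nblk <- (shp + rs - 1L) %/% rs
  mult <- cumprod(c(1L, nblk[-d]))
  blk <- array(0L, dim = shp)
  for (ax in seq_len(d)) {
    ax_block <- (seq_len(shp[ax]) - 1L) %/% rs[ax]
    blk <- blk + ax_block[slice.index(blk, ax)] * mult[ax]
  }
  blk <- blk + 1L                           # 1..prod(nblk)

  occ <- !is.na(lab)
  n <- sum(occ)
  if (n == 0L) stop("matrix has no occupied entries", call. = FALSE)
  nb <- prod(nblk)
  # counts per (block, label) over occupied entries
  cnt <- tabulate(blk[occ] + nb * (lab[occ] - 1L), nbins = nb * C)
  cnt <- matrix(cnt, nrow = nb, ncol = C)
  n_b <- rowSums(cnt)
  keep <- which(n_b > 0L)                   # discard all-None regions
  R <- length(keep)

  region_of <- array(match(blk, keep), dim = shp)
  sub <- arrayInd(keep, nblk)
  ranges <- lapply(seq_len(R), function(r) {
    lo <- (sub[r, ] - 1L) * rs
    hi <- pmin(lo + rs, shp)
    cbind(start = lo, end = hi)             # 0-based half-open per axis
  })
  structure(list(R = R, n = n, n_r = n_b[keep],
                 counts = cnt[keep, , drop = FALSE],
                 weights = n_b[keep] / n,
                 ranges = ranges, region_of = region_of,
                 region_size = rs, shape = shp, C = C,
                 decoding = attr(m, "decoding")),
            class = "grid_partition")
}

#' @export
print.grid_partition <- function(x, ...) {
  cat(sprintf(
    "Grid partition: region size (%s) on (%s); R = %d region(s), n = %d\n",
    paste(x$region_size, collapse = ", "), paste(x$shape, collapse = ", "),
    x$R, x$n))
  invisible(x)
}

# per-region HTI from a counts matrix (R x C), base C; C == 1 -> all zero
region_hti <- function(counts, n_r, C) {
  if (C == 1L) return(numeric(length(n_r)))
  p <- counts / n_r                      # column recycling over R rows
  h <- -p * log(p)
  h[counts == 0L] <- 0
  rowSums(h) / log(C)
}

#' HeTerogeneity Average of a trait-combination matrix
#'
#' The HTA statistic is the occupancy-weighted mean of region-level
#' heterogeneity indices over a grid partition:
#' `HTA = sum_r (n_r / n) * HTI(region r)`, with the per-region entropy
#' taken in log base `C` (the matrix's combination count).  HTA lies in
#' `[0, 1]`: low values mean combinations are locally segregated
#' (spatially homogeneous regions), high values mean combinations are
#' mixed within regions.
#'
#' On a single whole-matrix region HTA reduces to the global HTI, and it
#' decreases monotonically as the grid is refined.
#'
#' @inheritParams partition_grid
#' @return an object of class `hta_stat`: list with `hta`, `hti_per_region`,
#'   `weights`, `R`, `C`, `region_size` and the underlying `partition`.
#' @examples
#' m <- region_heterogeneous_map(c(32, 32), region_size = 8)
#' hta_index(m, 8)$hta   # 1 by construction
#' @export
hta_index <- function(m, region_size) {
  assert_trait_matrix(m)
  part <- partition_grid(m, region_size)
  hta_from_partition(part)
}

# HTA from a ready-made partition (shared with the permutation machinery)
hta_from_partition <- function(part) {
  h <- region_hti(part$counts, part$n_r, part$C)
  structure(list(hta = sum(part$weights * h), hti_per_region = h,
                 weights = part$weights, R = part$R, C = part$C,
                 region_size = part$region_size, partition = part),
            class = "hta_stat")
}

#' @export
print.hta_stat <- function(x, digits = 4, ...) {
  cat(sprintf("HTA = %s  (region size (%s), R = %d, C = %d)\n",
              format(x$hta, digits = digits),
              paste(x$region_size, collapse = ", "), x$R, x$C))
  invisible(x)
}

#' Ranked combination frequencies within one region
#'
#' Reports which trait combinations occupy a region and in what
#' proportion, ranked by descending within-region fraction — e.g. "the
#' most frequent combination is all 7 driver genes, accounting for 73% of
#' the entries".
#'
#' @param partition a [partition_grid()] result.
#' @param region_id index of a retained region, `1..R`.
#' @return a `data.frame` with columns `label`, `combination` (trait names
#'   joined by `+`), `count` and `fraction`, sorted by decreasing
#'   fraction; the region's index ranges are attached as attribute
#'   `region_ranges`.
#' @export
region_report <- function(partition, region_id) {
  if (!inherits(partition, "grid_partition"))
    stop("expected a `grid_partition`", call. = FALSE)
  region_id <- as.integer(region_id)
  if (length(region_id) != 1L || is.na(region_id) ||
      region_id < 1L || region_id > partition$R)
    stop("unknown region id; valid ids are 1..", partition$R, call. = FALSE)
  cnt <- partition$counts[region_id, ]
  lab <- which(cnt > 0L)
  combo <- vapply(partition$decoding[lab], paste, "", collapse = "+")
  out <- data.frame(label = lab, combination = combo, count = cnt[lab],
                    fraction = cnt[lab] / partition$n_r[region_id],
                    row.names = NULL)
  out <- out[order(-out$fraction, out$label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "region_ranges") <- partition$ranges[[region_id]]
  out
}
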