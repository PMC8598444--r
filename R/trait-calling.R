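#' Read a spot table from TSV/CSV
#'
#' A spot table is a long-format table with one row per measured spatial
#' position: integer coordinate columns `x`, `y` (optionally `z`),
#' recognised case-insensitively, and one numeric column per trait
#' (e.g. per-gene expression at each barcoded spot).
#'
#' @param path path to a delimited text file with a header row.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @param traits optional character vector restricting which trait columns
#'   to keep (all non-coordinate columns by default).
#' @return a `data.frame` of class `spot_table` with integer coordinate
#'   columns named `x`, `y`(, `z`) followed by numeric trait columns; the
#'   attribute `coord_cols` names the coordinate columns.
#' @export
read_spot_table <- function(path, sep = NULL, traits = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as_spot_table(df, traits = traits)
}

#' @rdname read_spot_table
#' @param df a data.frame already in memory.
#' @export
as_spot_table <- function(df, traits = NULL) {
  nm <- names(df)
  coord <- c(x = match("x", tolower(nm)), y = match("y", tolower(nm)),
             z = match("z", tolower(nm)))
  if (is.na(coord["x"]) || is.na(coord["y"]))
    stop("spot table must contain coordinate columns x and y ",
         "(case-insensitive); found: ", paste(nm, collapse = ", "),
         call. = FALSE)
  coord <- coord[!is.na(coord)]
  names(df)[coord] <- names(coord)
  trait_cols <- setdiff(nm[-coord], c())
  trait_cols <- names(df)[-coord]
  if (!is.null(traits)) {
    missing <- setdiff(traits, trait_cols)
    if (length(missing))
      stop("trait column(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    trait_cols <- traits
  }
  if (!length(trait_cols))
    stop("spot table has no trait columns", call. = FALSE)
  for (cc in names(coord)) {
    v <- df[[cc]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != round(v)))
      stop("coordinate column `", cc, "` must be integer-valued",
           call. = FALSE)
    df[[cc]] <- as.integer(round(v))
  }
  key <- do.call(paste, c(df[names(coord)], sep = ","))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate spot coordinates: (", dup, ")", call. = FALSE)
  }
  for (tc in trait_cols) {
    v <- df[[tc]]
    if (!is.numeric(v))
      stop("trait column `", tc, "` is not numeric", call. = FALSE)
  }
  out <- df[c(names(coord), trait_cols)]
  structure(out, coord_cols = names(coord), trait_cols = trait_cols,
            class = c("spot_table", "data.frame"))
}

#' Call traits present/absent at each spot
#'
#' Converts numeric trait measurements into a binary presence tensor on the
#' position lattice spanned by the spot coordinates.  The default rule is
#' the median threshold: a trait is called present at a spot iff its value
#' is strictly greater than that trait's median across all spots, so ties
#' at the median are called absent.  A fixed numeric threshold (one value,
#' or one per trait) can be supplied instead.
#'
#' Positions inside the bounding lattice that carry no spot are marked
#' unoccupied, which downstream code distinguishes from "spot measured but
#' no trait present".
#'
#' @param table a `spot_table` (see [read_spot_table()]).
#' @param threshold `"median"` (default) or a numeric vector of fixed
#'   thresholds, length 1 or one per trait; presence is strictly-greater
#'   in either case.
#' @return an object of class `trait_tensor`: a list with `presence`
#'   (0/1 array of dim `c(shape, n_traits)`, `NA` off-spot), `occupied`
#'   (logical array of dim `shape`), `shape`, `trait_names` and `origin`
#'   (the minimum coordinate per axis, subtracted to anchor the lattice
#'   at index 1).
#' @examples
#' tab <- as_spot_table(data.frame(x = 0:3, y = 0, g = c(1, 2, 3, 4)))
#' binarize_traits(tab)$presence[, 1, 1]   # 0 0 1 1: median is 2.5
#' @export
binarize_traits <- function(table, threshold = "median") {
  if (!inherits(table, "spot_table")) table <- as_spot_table(table)
  coord_cols <- attr(table, "coord_cols")
  trait_cols <- attr(table, "trait_cols")
  t <- length(trait_cols)
  vals <- as.matrix(table[trait_cols])
  if (identical(threshold, "median")) {
    thr <- numeric(t)
    for (j in seq_len(t)) {
      v <- vals[, j]
      if (all(is.na(v)))
        stop("trait column `", trait_cols[j], "` has no finite values",
             call. = FALSE)
      thr[j] <- stats::median(v, na.rm = TRUE)
    }
  } else {
    if (!is.numeric(threshold) || !(length(threshold) %in% c(1L, t)))
      stop("`threshold` must be \"median\" or a numeric vector of length 1 or ",
           t, call. = FALSE)
    thr <- rep_len(threshold, t)
  }
  pres_rows <- sweep(vals, 2L, thr, `>`) * 1L
  pres_rows[is.na(pres_rows)] <- 0L

  origin <- unname(vapply(coord_cols, function(cc) min(table[[cc]]),
                          integer(1)))
  idx <- mapply(function(cc, o) table[[cc]] - o + 1L, coord_cols, origin,
                SIMPLIFY = FALSE)
  shape <- unname(vapply(idx, max, integer(1)))
  d <- length(shape)
  occupied <- array(FALSE, dim = shape)
  occupied[do.call(cbind, idx)] <- TRUE
  presence <- array(NA_integer_, dim = c(shape, t))
  pos <- do.call(cbind, idx)
  for (j in seq_len(t))
    presence[cbind(pos, j)] <- pres_rows[, j]
  structure(list(presence = presence, occupied = occupied, shape = shape,
                 trait_names = trait_cols, origin = origin,
                 threshold = thr),
            class = "trait_tensor")
}

#' @export
print.trait_tensor <- function(x, ...) {
  cat(sprintf("Binary trait tensor: %s, %d trait(s) [%s], %d spot(s)\n",
              paste(x$shape, collapse = " x "), length(x$trait_names),
              paste(utils::head(x$trait_names, 5), collapse = ", "),
              sum(x$occupied)))
  invisible(x)
}

#' Encode binary traits as combination labels
#'
#' Maps each occupied position to the label of the exact subset of traits
#' present there.  Positions with no present trait, and unoccupied
#' positions, become `NA` ("None"): the index only counts entries that
#' manifest at least one trait.
#'
#' The combination count `C` used as the entropy log base is either the
#' number of distinct subsets actually observed (`c_mode = "observed"`,
#' the default) or all `2^t - 1` non-empty subsets of the `t` traits
#' (`c_mode = "full"`); e.g. 7 traits give `C = 127` in full mode.
#'
#' @param tensor a `trait_tensor` from [binarize_traits()].
#' @param c_mode `"observed"` or `"full"`.
#' @return a [trait_matrix()] whose `decoding` lists the trait subset for
#'   each label.
#' @export
encode_combinations <- function(tensor, c_mode = c("observed", "full")) {
  c_mode <- match.arg(c_mode)
  if (!inherits(tensor, "trait_tensor"))
    stop("expected a `trait_tensor`; see ?binarize_traits", call. = FALSE)
  t <- length(tensor$trait_names)
  if (t < 1L) stop("tensor has zero traits", call. = FALSE)
  if (t > 30L) stop("more than 30 traits cannot be bitmask-encoded",
                    call. = FALSE)
  shape <- tensor$shape
  ncell <- prod(shape)
  pres <- matrix(tensor$presence, nrow = ncell, ncol = t)
  mask <- as.integer(pres %*% (2^(seq_len(t) - 1)))
  mask[!as.vector(tensor$occupied)] <- NA_integer_
  mask[!is.na(mask) & mask == 0L] <- NA_integer_

  subset_names <- function(bit)
    tensor$trait_names[bitwAnd(bit, 2^(seq_len(t) - 1)) > 0]
  if (c_mode == "full") {
    C <- 2L^t - 1L
    labels <- mask                       # bitmask 1..2^t-1 is the label
    decoding <- lapply(seq_len(C), subset_names)
  } else {
    present <- sort(unique(mask[!is.na(mask)]))
    C <- length(present)
    if (C == 0L)
      stop("no position manifests any trait; nothing to encode",
           call. = FALSE)
    labels <- match(mask, present)
    decoding <- lapply(present, subset_names)
  }
  trait_matrix(array(labels, dim = shape), C = C, decoding = decoding)
}

#' Nearest-neighbour resize of a label matrix
#'
#' Rescales a trait-combination matrix to new grid extents using
#' nearest-neighbour sampling, so that every output label is drawn from
#' the input (no interpolation-created labels) and the `NA` mask is
#' resampled alongside.  Used to harmonize maps of different sizes before
#' comparing their heterogeneity (e.g. bringing a cohort of binary
#' expression maps to a common shape).
#'
#' Output position `i` (0-based) on an axis samples input position
#' `floor((i + 0.5) * n_in / n_out)`, the standard pixel-centre mapping.
#'
#' @param m a [trait_matrix()].
#' @param target_shape integer vector of new extents, same dimensionality.
#' @return a `trait_matrix` of the requested shape with the same `C` and
#'   decoding.
#' @export
resize_nearest <- function(m, target_shape) {
  assert_trait_matrix(m)
  src <- dim(m)
  d <- length(src)
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != d)
    stop("`target_shape` must have ", d, " extents", call. = FALSE)
  if (any(target_shape < 1L))
    stop("target extents must be positive", call. = FALSE)
  idx <- lapply(seq_len(d), function(ax) {
    i <- seq_len(target_shape[ax]) - 1L
    pmin(as.integer(floor((i + 0.5) * src[ax] / target_shape[ax])) + 1L,
         src[ax])
  })
  out <- do.call(`[`, c(list(label_array(m)), idx, list(drop = FALSE)))
  trait_matrix(out, C = attr(m, "C"), decoding = attr(m, "decoding"))
}
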