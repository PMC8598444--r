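#' Trait-combination matrices
#'
#' A trait-combination matrix is the central data container of the package:
#' a dense d-dimensional integer array (d = 2 or 3) in which each entry holds
#' the label of the trait combination manifesting at that spatial position,
#' or `NA` ("None") where no spot was measured or no trait was called
#' present.  Labels are consecutive integers `1..C`; the attached
#' `decoding` maps each label to the subset of trait names it denotes, and
#' `C` is the combination count used as the logarithm base of the
#' heterogeneity index (see [hti()]).
#'
#' `C` may exceed the number of labels actually present (e.g. when all
#' `2^t - 1` non-empty subsets of `t` traits are counted, "full" mode) but
#' never falls below it.
#'
#' @param labels an integer matrix or 3D array; `NA` marks empty positions.
#' @param C combination count (log base).  Defaults to the number of
#'   distinct non-`NA` labels.
#' @param decoding optional list of character vectors, one per label
#'   `1..C`, naming the traits in that combination.  Defaults to
#'   single-pseudo-trait names `"c1".."cC"`.
#' @return an object of class `trait_matrix`: the label array with
#'   attributes `C` and `decoding`.
#' @examples
#' m <- trait_matrix(matrix(c(1, 2, NA, 1), 2, 2))
#' n_occupied(m)
#' @export
trait_matrix <- function(labels, C = NULL, decoding = NULL) {
  if (!is.array(labels) && !is.matrix(labels))
    stop("`labels` must be a matrix or array", call. = FALSE)
  d <- length(dim(labels))
  if (d < 2L || d > 3L)
    stop("trait matrices must be 2- or 3-dimensional, got ", d, " dims",
         call. = FALSE)
  lab <- labels
  storage.mode(lab) <- "integer"
  present <- sort(unique(lab[!is.na(lab)]))
  if (length(present) && (min(present) < 1L))
    stop("labels must be positive integers (NA for empty positions)",
         call. = FALSE)
  if (is.null(C)) C <- length(present)
  C <- as.integer(C)
  if (length(present) && max(present) > C)
    stop("label ", max(present), " exceeds C = ", C, call. = FALSE)
  if (C < 1L) stop("C must be >= 1", call. = FALSE)
  if (is.null(decoding)) decoding <- as.list(paste0("c", seq_len(C)))
  if (length(decoding) != C)
    stop("`decoding` must have one entry per label 1..C", call. = FALSE)
  structure(lab, C = C, decoding = decoding, class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Trait-combination matrix: %s, C = %d, %d/%d occupied\n",
              paste(d, collapse = " x "), attr(x, "C"),
              sum(!is.na(x)), length(x)))
  invisible(x)
}

#' @rdname trait_matrix
#' @param m a `trait_matrix`.
#' @export
n_occupied <- function(m) sum(!is.na(unclass(m)))

#' @export
`[.trait_matrix` <- function(x, ...) {
  out <- NextMethod()
  if (is.array(out) && length(dim(out)) >= 2L)
    trait_matrix(out, C = attr(x, "C"), decoding = attr(x, "decoding"))
  else out
}

# internal: strip class, keep plain array
label_array <- function(m) {
  a <- unclass(m)
  attr(a, "C") <- NULL
  attr(a, "decoding") <- NULL
  a
}

assert_trait_matrix <- function(m) {
  if (!inherits(m, "trait_matrix"))
    stop("expected a `trait_matrix`; see ?trait_matrix", call. = FALSE)
  invisible(m)
}
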