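# On-disk formats are plain text: label matrices as TSV (empty cell =
# "None" by default), with a JSON sidecar carrying the combination
# decoding, C and — for 3D maps — the shape needed to restack the slices.

#' Write / read a label matrix as TSV with a JSON sidecar
#'
#' 2D matrices are written as a plain TSV grid; 3D arrays are written as
#' z-slices stacked vertically, with the true shape recorded in the
#' sidecar so the reader can restack them.  Empty ("None") positions are
#' written as `sentinel` (default: an empty field).  The sidecar
#' `<path>.json` stores `C`, the combination decoding and the shape, so a
#' write/read round trip reproduces the matrix exactly, including the
#' `NA` mask.
#'
#' @param m a [trait_matrix()].
#' @param path output TSV path; the sidecar goes to `<path>.json`.
#' @param sentinel string representing `NA` cells.
#' @return `write_label_matrix` returns `path` invisibly;
#'   `read_label_matrix` returns a `trait_matrix`.
#' @export
write_label_matrix <- function(m, path, sentinel = "") {
  assert_trait_matrix(m)
  shp <- dim(m)
  lab <- label_array(m)
  flat <- if (length(shp) == 3L) {
    do.call(rbind, lapply(seq_len(shp[3L]), function(k) lab[, , k]))
  } else lab
  utils::write.table(flat, path, sep = "\t", na = sentinel,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  sidecar <- list(shape = shp, C = attr(m, "C"),
                  decoding = attr(m, "decoding"), sentinel = sentinel)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_label_matrix
#' @export
read_label_matrix <- function(path, sentinel = "") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  side_path <- paste0(path, ".json")
  sidecar <- if (file.exists(side_path)) jsonlite::read_json(side_path)
             else NULL
  if (!is.null(sidecar$sentinel)) sentinel <- sidecar$sentinel
  flat <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                      na.strings = sentinel,
                                      colClasses = "integer"))
  dimnames(flat) <- NULL
  C <- if (!is.null(sidecar)) as.integer(sidecar$C) else NULL
  decoding <- if (!is.null(sidecar))
    lapply(sidecar$decoding, function(s) unlist(s, use.names = FALSE))
  else NULL
  shp <- if (!is.null(sidecar)) as.integer(unlist(sidecar$shape))
         else dim(flat)
  lab <- if (length(shp) == 3L) {
    a <- array(NA_integer_, dim = shp)
    for (k in seq_len(shp[3L]))
      a[, , k] <- flat[(k - 1L) * shp[1L] + seq_len(shp[1L]), ]
    a
  } else flat
  trait_matrix(lab, C = C, decoding = decoding)
}

# serializable summary of a fit, one list per region size
result_record <- function(fit) {
  st <- fit$statistic
  list(hta = st$hta,
       region_size = as.integer(st$region_size),
       R = st$R, C = st$C,
       method = fit$moments$method,
       n_permutations = if (fit$moments$method == "permutation")
         fit$moments$n_permutations else NULL,
       seed = fit$seed,
       mu_null = fit$p$null_mean,
       sigma_null = fit$p$null_sd,
       z = fit$p$z,
       p_homogeneity = fit$p$p_homogeneity,
       p_heterogeneity = fit$p$p_heterogeneity,
       p_overall = fit$p$p_overall,
       n_single_entry_regions = if (fit$moments$method == "permutation")
         fit$moments$n_single_entry else 0L)
}

#' Run the full heterogeneity analysis end to end
#'
#' Orchestrates the pipeline: read a spot table (or take a ready
#' `trait_matrix`), call traits at the median (or a fixed threshold),
#' encode combinations, and for each requested region size compute the
#' HTA statistic with permutation-null p-values.  Optionally writes
#' `<prefix>.result.json`, `<prefix>.labels.tsv` (+ `.json` sidecar),
#' `<prefix>.map.png` and `<prefix>.report.tsv`.
#'
#' Each region size gets its own set of permutations (the region
#' structure changes the null), all driven by the one `seed`.
#'
#' @param input path to a spot-table TSV/CSV, a `spot_table`, or a
#'   [trait_matrix()].
#' @param traits optional trait-column selection for table input.
#' @param region_sizes one or more region sizes (list for per-axis
#'   extents).
#' @param threshold passed to [binarize_traits()].
#' @param c_mode passed to [encode_combinations()].
#' @param n_permutations,seed passed to [hta_test()].
#' @param out_prefix if non-`NULL`, write result files with this path
#'   prefix.
#' @param report_regions optional region ids for [region_report()]s
#'   (computed at the first region size).
#' @param render if `TRUE` and 2D, write a PNG heterogeneity map at the
#'   first region size.
#' @param sep field separator for file input (`NULL` = auto).
#' @return invisibly, a list with `matrix`, `fits` (one `hta_test` per
#'   region size), `results` (the serializable records) and `reports`.
#' @export
run_hta <- function(input, traits = NULL, region_sizes = 8,
                    threshold = "median", c_mode = "observed",
                    n_permutations = 1000, seed = NULL,
                    out_prefix = NULL, report_regions = NULL,
                    render = FALSE, sep = NULL) {
  m <- if (inherits(input, "trait_matrix")) {
    input
  } else {
    tab <- if (inherits(input, "spot_table")) input
           else if (is.character(input)) read_spot_table(input, sep = sep,
                                                         traits = traits)
           else as_spot_table(input, traits = traits)
    encode_combinations(binarize_traits(tab, threshold = threshold),
                        c_mode = c_mode)
  }
  if (!is.list(region_sizes)) region_sizes <- as.list(region_sizes)
  fits <- lapply(region_sizes, function(rs)
    hta_test(m, rs, n_permutations = n_permutations, seed = seed))
  names(fits) <- vapply(region_sizes, function(rs)
    paste(rs, collapse = "x"), "")
  results <- lapply(fits, result_record)

  reports <- NULL
  if (!is.null(report_regions)) {
    part <- fits[[1L]]$statistic$partition
    reports <- lapply(report_regions, function(rid)
      region_report(part, rid))
    names(reports) <- paste0("region_", report_regions)
  }
  if (!is.null(out_prefix)) {
    jsonlite::write_json(results, paste0(out_prefix, ".result.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_label_matrix(m, paste0(out_prefix, ".labels.tsv"))
    if (!is.null(reports)) {
      rep_df <- do.call(rbind, lapply(names(reports), function(nm)
        cbind(region = nm, reports[[nm]])))
      utils::write.table(rep_df, paste0(out_prefix, ".report.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (render && length(dim(m)) == 2L) {
      grDevices::png(paste0(out_prefix, ".map.png"), width = 800,
                     height = 800)
      plot_heterogeneity_map(m, region_size = region_sizes[[1L]])
      grDevices::dev.off()
    }
  }
  invisible(list(matrix = m, fits = fits, results = results,
                 reports = reports))
}
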