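# Microarray processing: replicate averaging and normalization of raw
# fluorescence into selectivity profiles.

#' Average replicate fluorescence per array feature
#'
#' @param scan a `data.frame`/`data.table` with columns `feature_id`,
#'   `replicate`, `raw_signal` (additional columns such as `antibody_id`
#'   are ignored). Every feature must have at least one replicate;
#'   negative signals are rejected.
#' @return named numeric vector of per-feature arithmetic means, in first
#'   order of appearance.
#' @export
average_replicates <- function(scan) {
  scan <- as.data.table(scan)
  need <- c("feature_id", "replicate", "raw_signal")
  if (!all(need %in% names(scan))) {
    stop("scan must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(scan) == 0L) stop("scan is empty", call. = FALSE)
  if (anyNA(scan$raw_signal) || any(scan$raw_signal < 0)) {
    stop("raw_signal must be non-negative and non-missing", call. = FALSE)
  }
  means <- scan[, .(mean_signal = mean(raw_signal)),
                by = .(feature_id)]
  setNames(means$mean_signal, means$feature_id)
}

#' Globally normalize feature means to the array maximum
#'
#' Divides every value by the global maximum so the brightest feature maps
#' to exactly 1. An all-zero array is a degenerate input and raises an
#' error rather than returning silent zeros.
#'
#' @param means named numeric vector of non-negative feature means.
#' @return named numeric vector in `[0, 1]`.
#' @export
normalize_global <- function(means) {
  if (any(means < 0)) stop("means must be non-negative", call. = FALSE)
  m <- max(means)
  if (!is.finite(m) || m <= 0) {
    stop("degenerate array: all signals are zero", call. = FALSE)
  }
  means / m
}

#' Normalize a features x antibodies matrix per column
#'
#' Histone-peptide array convention: each antibody (column) is scaled by
#' its own maximum, so the strongest feature per antibody maps to 1.
#'
#' @param mat numeric matrix, features in rows, antibodies in columns.
#' @return matrix of the same shape with values in `[0, 1]`.
#' @export
normalize_per_column <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("signals must be non-negative", call. = FALSE)
  cmax <- apply(mat, 2L, max)
  if (any(cmax <= 0)) {
    bad <- colnames(mat)[cmax <= 0]
    if (is.null(bad)) bad <- which(cmax <= 0)
    stop("degenerate column(s) with all-zero signal: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sweep(mat, 2L, cmax, "/")
}

#' Build a selectivity profile from an array scan
#'
#' Averages replicates, normalizes to the highest feature mean on the whole
#' array (including any off-target libraries or control features printed on
#' the same slide), and arranges the on-target K-OPL features into a
#' 19 x 6 matrix (amino acids x positions P-3..P+3).
#'
#' @param scan scan table as in [average_replicates()]; may carry an
#'   `antibody_id` column (a single value).
#' @param library the [kopl_library()] defining the on-target sets; every
#'   `set_id` must appear in the scan.
#' @param norm_mode `"global_max"` (the K-OPL convention; only mode
#'   supported here, per-column scaling applies to multi-antibody matrices
#'   via [normalize_per_column()]).
#' @return an object of class `selectivity_profile`: list with
#'   `antibody_id`, `state`, `matrix` (19 x 6, rownames amino acids,
#'   colnames position labels), `norm_mode` and `max_signal` (the raw
#'   global maximum feature mean, kept for intensity-vs-pan analyses).
#' @export
build_profile <- function(scan, library, norm_mode = "global_max") {
  norm_mode <- match.arg(norm_mode, "global_max")
  scan <- as.data.table(scan)
  ab <- if ("antibody_id" %in% names(scan)) unique(scan$antibody_id) else NA
  if (length(ab) > 1L) {
    stop("scan contains multiple antibodies; profile one at a time",
         call. = FALSE)
  }
  means <- average_replicates(scan)
  missing_sets <- setdiff(library$set_id, names(means))
  if (length(missing_sets) > 0L) {
    stop("incomplete scan; missing set_id(s): ",
         paste(head(missing_sets, 10L), collapse = ", "),
         if (length(missing_sets) > 10L) " ...", call. = FALSE)
  }
  norm <- normalize_global(means)
  mat <- matrix(NA_real_, nrow = length(AA_KOPL), ncol = length(KOPL_OFFSETS),
                dimnames = list(AA_KOPL, offset_label(KOPL_OFFSETS)))
  lib <- as.data.table(library)
  mat[cbind(lib$fixed_aa, offset_label(lib$fixed_offset))] <- norm[lib$set_id]
  structure(
    list(antibody_id = as.character(ab), state = lib$state[1], matrix = mat,
         norm_mode = norm_mode, max_signal = max(means)),
    class = "selectivity_profile"
  )
}

#' @export
print.selectivity_profile <- function(x, ...) {
  cat("Selectivity profile:", x$antibody_id, "on", x$state, "K-OPL\n")
  cat("  normalization:", x$norm_mode,
      "| raw max signal:", format(x$max_signal), "\n")
  cat("  matrix 19 aa x 6 positions; mean cell:",
      format(mean(x$matrix), digits = 4), "\n")
  invisible(x)
}

#' Write a selectivity-profile matrix to TSV
#'
#' Rows are amino acids, columns positions P-3..P+3.
#' @param profile a `selectivity_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  dt <- as.data.table(profile$matrix, keep.rownames = "aa")
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read an array scan TSV
#'
#' Expected columns: `antibody_id`, `feature_id`, `replicate`, `raw_signal`.
#' @param path scan file path.
#' @return a `data.table`.
#' @export
read_array_scan <- function(path) {
  fread(path, sep = "\t")
}
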