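# Sequence motif analysis around methylated lysines: per-position amino
# acid frequencies for a site set (f_d) and for the detected-proteome
# background (f_p), combined as log2(f_d / f_p).

# Build a frequency table from 7-mer windows. Padding characters are not
# residues: they are excluded from both counts and the per-offset
# denominator, so frequencies at each offset sum to 1 over observed
# residues.
freq_from_windows <- function(windows, role) {
  counts <- matrix(0L, nrow = length(AA_STANDARD),
                   ncol = length(KOPL_OFFSETS),
                   dimnames = list(AA_STANDARD, offset_label(KOPL_OFFSETS)))
  for (j in seq_along(KOPL_OFFSETS)) {
    pos <- 4L + KOPL_OFFSETS[j]
    res <- substr(windows, pos, pos)
    tab <- table(factor(res[res %in% AA_STANDARD], levels = AA_STANDARD))
    counts[, j] <- as.integer(tab)
  }
  totals <- colSums(counts)
  freq <- sweep(counts, 2L, pmax(totals, 1L), "/")
  structure(
    list(counts = counts, freq = freq, n_windows = length(windows),
         role = role),
    class = "freq_table"
  )
}

#' Background amino-acid frequencies around proteome lysines
#'
#' Pools 7-mer windows around every lysine of the restricted protein set
#' (typically the proteins identified in unenriched runs) and tabulates
#' per-offset residue frequencies. Window positions lost to a protein
#' terminus are excluded from that offset's denominator.
#'
#' @param proteome named character vector or `AAStringSet`.
#' @param restrict_to optional accession set; must be non-empty and a
#'   subset of the proteome.
#' @return object of class `freq_table`: `counts` and `freq` (20 x 6
#'   matrices), `n_windows`, `role = "background"`.
#' @export
background_frequencies <- function(proteome, restrict_to = NULL) {
  proteome <- as_proteome(proteome)
  if (!is.null(restrict_to)) {
    restrict_to <- unique(restrict_to)
    if (length(restrict_to) == 0L) {
      stop("empty accession restriction", call. = FALSE)
    }
    missing_acc <- setdiff(restrict_to, names(proteome))
    if (length(missing_acc) > 0L) {
      stop("restriction accessions absent from proteome: ",
           paste(head(missing_acc, 5L), collapse = ", "), call. = FALSE)
    }
    proteome <- proteome[restrict_to]
  }
  win <- lysine_windows(proteome, pad = TRUE)
  freq_from_windows(win$window, role = "background")
}

#' Amino-acid frequencies around methylation sites
#'
#' As [background_frequencies()] but over the 7-mer windows of a site
#' catalog. Sites that cannot be resolved (unknown accession, position out
#' of range, or non-lysine residue) are excluded, counted, and reported in
#' the `n_unresolved` field.
#'
#' @param sites site table with `accession`, `position`.
#' @param proteome named character vector or `AAStringSet`.
#' @return a `freq_table` with `role = "dataset"` and an extra
#'   `n_unresolved` field.
#' @export
dataset_frequencies <- function(sites, proteome) {
  sites <- as.data.table(sites)
  proteome <- as_proteome(proteome)
  known <- sites$accession %in% names(proteome)
  pos_ok <- known
  pos_ok[known] <- sites$position[known] >= 1L &
    sites$position[known] <= nchar(proteome[sites$accession[known]])
  res <- rep(NA_character_, nrow(sites))
  res[pos_ok] <- substr(proteome[sites$accession[pos_ok]],
                        sites$position[pos_ok], sites$position[pos_ok])
  ok <- pos_ok & !is.na(res) & res == "K"
  win <- fetch_windows(proteome, sites$accession[ok], sites$position[ok])
  ft <- freq_from_windows(win, role = "dataset")
  ft$n_unresolved <- sum(!ok)
  ft
}

#' log2 frequency-ratio motif matrix
#'
#' For each (position, amino acid) cell, `log2(f_d / f_p)` where `f_d` is
#' the dataset frequency and `f_p` the background frequency. Cells with a
#' zero dataset count are not evidence of depletion but of non-detection
#' and render as missing (`NA`); cells with positive dataset frequency but
#' zero background frequency are infinite enrichment and are returned as
#' `Inf` with their coordinates listed in the `infinite_cells` attribute.
#'
#' @param fd dataset `freq_table`.
#' @param fp background `freq_table`.
#' @param pseudocount optional count added to every cell of both tables
#'   before forming frequencies (default 0 = none).
#' @return matrix of class `motif_matrix` (20 x 6) with attributes
#'   `dataset_n`, `background_n`, `infinite_cells`.
#' @export
log2_enrichment <- function(fd, fp, pseudocount = 0) {
  stopifnot(inherits(fd, "freq_table"), inherits(fp, "freq_table"))
  if (!identical(dimnames(fd$counts), dimnames(fp$counts))) {
    stop("frequency tables have mismatched dimensions", call. = FALSE)
  }
  if (pseudocount > 0) {
    fdc <- fd$counts + pseudocount
    fpc <- fp$counts + pseudocount
    fdf <- sweep(fdc, 2L, colSums(fdc), "/")
    fpf <- sweep(fpc, 2L, colSums(fpc), "/")
  } else {
    fdf <- fd$freq
    fpf <- fp$freq
  }
  m <- log2(fdf / fpf)
  zero_fd <- fd$counts + pseudocount == 0
  m[zero_fd] <- NA_real_
  inf_cells <- which(is.infinite(m) & m > 0, arr.ind = TRUE)
  structure(m, class = c("motif_matrix", class(m)),
            dataset_n = fd$n_windows, background_n = fp$n_windows,
            infinite_cells = inf_cells)
}

#' Flank context of modified lysines within identified peptides
#'
#' For every methyl modification, counts the residues N-terminal and
#' C-terminal of the modified lysine within the peptide. Used to check
#' that identified peptides carry enough flanking sequence (at least three
#' residues on each side) to support motif analysis.
#'
#' @param records record table with `sequence` and `mods`.
#' @return list with `joint` (`data.table`: `n_left`, `n_right`, `count`),
#'   `fraction_ge3` (percent of methyl mods with >= 3 residues on both
#'   sides), `n_mods`.
#' @export
flank_context <- function(records) {
  records <- as.data.table(records)
  ml <- parse_mods(records)
  ml <- ml[type %in% METHYL_TYPES]
  if (nrow(ml) == 0L) {
    return(list(joint = data.table(n_left = integer(), n_right = integer(),
                                   count = integer()),
                fraction_ge3 = NA_real_, n_mods = 0L))
  }
  lens <- nchar(records$sequence)[ml$record_id]
  dt <- data.table(n_left = ml$residue_index - 1L,
                   n_right = lens - ml$residue_index)
  joint <- dt[, .(count = .N), by = .(n_left, n_right)]
  setorder(joint, n_left, n_right)
  list(joint = joint[],
       fraction_ge3 = 100 * mean(dt$n_left >= 3L & dt$n_right >= 3L),
       n_mods = nrow(dt))
}

#' Write a motif matrix to TSV
#'
#' Missing (not-detected) cells are written as `NA`.
#' @param m a `motif_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motif_matrix <- function(m, path) {
  dt <- as.data.table(unclass(m), keep.rownames = "aa")
  fwrite(dt, path, sep = "\t", na = "NA")
  invisible(path)
}
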