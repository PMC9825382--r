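# Antibody pan metric and PSSM machinery: quantify sequence bias of a
# pan-methyllysine antibody and score lysine-centered 7-mers proteome-wide.

#' Pan metric score of a selectivity profile
#'
#' The pan metric summarizes antibody sequence bias on a 0-100 scale as
#' 100 times the mean globally-normalized signal across all 114 on-target
#' K-OPL sets. A perfectly unbiased antibody that saturates every set
#' scores 100; higher scores mean less sequence bias.
#'
#' @param profile a complete [build_profile()] result (no missing cells).
#' @return an object of class `pan_score`: list with `antibody_id`,
#'   `state`, `score` (in `[0, 100]`) and `max_signal` (raw array maximum,
#'   for intensity-vs-pan correlation).
#' @export
pan_metric <- function(profile) {
  stopifnot(inherits(profile, "selectivity_profile"))
  if (anyNA(profile$matrix)) {
    stop("incomplete selectivity profile: matrix has missing cells",
         call. = FALSE)
  }
  structure(
    list(antibody_id = profile$antibody_id, state = profile$state,
         score = 100 * mean(profile$matrix), max_signal = profile$max_signal),
    class = "pan_score"
  )
}

#' @export
print.pan_score <- function(x, ...) {
  cat(sprintf("Pan metric score: %.1f (%s, %s; raw max %.3g)\n",
              x$score, x$antibody_id, x$state, x$max_signal))
  invisible(x)
}

#' Correlate array intensity with pan metric score
#'
#' Pearson correlation between the raw array maximum signal and the pan
#' metric score across a panel of antibodies.
#'
#' @param scores list of `pan_score` objects, or a `data.frame` with
#'   columns `score` and `max_signal`.
#' @return list with `r`, `r_squared`, `n`. Degenerate panels (constant
#'   score or intensity) return `NA` correlation with a `degenerate` flag.
#' @export
pan_vs_intensity <- function(scores) {
  if (is.list(scores) && !is.data.frame(scores) &&
      all(vapply(scores, inherits, logical(1), "pan_score"))) {
    scores <- data.table(
      score = vapply(scores, `[[`, numeric(1), "score"),
      max_signal = vapply(scores, `[[`, numeric(1), "max_signal")
    )
  }
  scores <- as.data.table(scores)
  if (nrow(scores) < 3L) {
    stop("need at least 3 antibodies for a correlation", call. = FALSE)
  }
  degenerate <- sd(scores$score) == 0 || sd(scores$max_signal) == 0
  r <- if (degenerate) NA_real_ else cor(scores$max_signal, scores$score)
  list(r = r, r_squared = r^2, n = nrow(scores), degenerate = degenerate)
}

#' Build a PSSM from a selectivity profile
#'
#' Each measured amino acid at each flank position gets a frequency score
#' equal to its replicate-averaged, globally normalized on-target array
#' signal. Cysteine is never printed on the library and carries an explicit
#' missing value.
#'
#' @param profile a complete [build_profile()] result.
#' @return object of class `pssm`: list with `antibody_id` and `scores`, a
#'   20 x 6 matrix (rows [AA_STANDARD], columns P-3..P+3) with `NA` on the
#'   cysteine row.
#' @export
build_pssm <- function(profile) {
  stopifnot(inherits(profile, "selectivity_profile"))
  if (anyNA(profile$matrix)) {
    stop("incomplete selectivity profile", call. = FALSE)
  }
  scores <- matrix(NA_real_, nrow = length(AA_STANDARD),
                   ncol = length(KOPL_OFFSETS),
                   dimnames = list(AA_STANDARD, offset_label(KOPL_OFFSETS)))
  scores[rownames(profile$matrix), ] <- profile$matrix
  structure(list(antibody_id = profile$antibody_id, scores = scores),
            class = "pssm")
}

#' Construct a PSSM directly from a score matrix
#'
#' Mostly useful for simulation and testing; [build_pssm()] is the data
#' path. Rows not supplied default to missing.
#'
#' @param scores numeric matrix with amino-acid rownames and position
#'   colnames (`"P-3"`..`"P+3"`, no P0).
#' @param antibody_id identifier carried along.
#' @return a `pssm` object.
#' @export
as_pssm <- function(scores, antibody_id = "pssm") {
  full <- matrix(NA_real_, nrow = length(AA_STANDARD),
                 ncol = length(KOPL_OFFSETS),
                 dimnames = list(AA_STANDARD, offset_label(KOPL_OFFSETS)))
  stopifnot(all(rownames(scores) %in% AA_STANDARD),
            all(colnames(scores) %in% colnames(full)))
  full[rownames(scores), colnames(scores)] <- scores
  structure(list(antibody_id = antibody_id, scores = full), class = "pssm")
}

#' Score one lysine-centered 7-mer
#'
#' The PSSM score of a window is the sum over the six flank positions of
#' the frequency score of the residue at that position. Missing PSSM
#' entries (cysteine) and terminal padding (`"X"`) contribute 0.
#'
#' @param pssm a `pssm` object.
#' @param window 7-residue string with `"K"` at position 4.
#' @return numeric score.
#' @export
#' @examples
#' p <- as_pssm(matrix(0.8, 1, 1, dimnames = list("F", "P-1")))
#' score_7mer(p, "AAFKAAA")  # 0.8
score_7mer <- function(pssm, window) {
  if (nchar(window) != 7L) stop("window must have 7 residues", call. = FALSE)
  if (substr(window, 4L, 4L) != "K") {
    stop("window residue 4 must be lysine", call. = FALSE)
  }
  score_windows(pssm, window)
}

# Vectorized scoring; windows assumed pre-validated (length 7, K center).
score_windows <- function(pssm, windows) {
  stopifnot(inherits(pssm, "pssm"))
  total <- numeric(length(windows))
  cols <- colnames(pssm$scores)
  for (j in seq_along(KOPL_OFFSETS)) {
    pos <- 4L + KOPL_OFFSETS[j]
    res <- substr(windows, pos, pos)
    idx <- match(res, rownames(pssm$scores))
    contrib <- ifelse(is.na(idx), 0, pssm$scores[cbind(idx, j)])
    contrib[is.na(contrib)] <- 0  # cysteine / unmeasured cells
    total <- total + contrib
  }
  names(total) <- NULL
  total
}

# Coerce proteome inputs (named character vector or Biostrings::AAStringSet)
# to a named character vector.
as_proteome <- function(proteome) {
  if (methods::is(proteome, "XStringSet")) {
    proteome <- setNames(as.character(proteome), names(proteome))
  }
  if (!is.character(proteome) || is.null(names(proteome)) ||
      any(names(proteome) == "")) {
    stop("proteome must be a named character vector or AAStringSet",
         call. = FALSE)
  }
  proteome
}

#' Extract lysine-centered 7-mer windows from a proteome
#'
#' One window per lysine per protein; windows that run past a terminus are
#' padded with `"X"` (which scores 0 and is excluded from frequency
#' denominators).
#'
#' @param proteome named character vector (or `AAStringSet`) of protein
#'   sequences.
#' @param pad if `FALSE`, windows touching a terminus are dropped instead
#'   of padded.
#' @return `data.table` with columns `accession`, `position` (1-based
#'   lysine coordinate), `window`.
#' @export
lysine_windows <- function(proteome, pad = TRUE) {
  proteome <- as_proteome(proteome)
  res <- lapply(names(proteome), function(acc) {
    s <- proteome[[acc]]
    kpos <- gregexpr("K", s, fixed = TRUE)[[1]]
    if (kpos[1] == -1L) return(NULL)
    data.table(accession = acc, position = as.integer(kpos))
  })
  win <- rbindlist(res)
  if (nrow(win) == 0L) {
    return(data.table(accession = character(), position = integer(),
                      window = character()))
  }
  lens <- nchar(proteome)[win$accession]
  padded <- fetch_windows(proteome, win$accession, win$position)
  win[, window := padded]
  if (!pad) {
    win <- win[position >= 4L & position <= lens - 3L]
  }
  win[]
}

# Extract padded 7-mers at the given (accession, position) pairs.
fetch_windows <- function(proteome, accession, position) {
  seqs <- proteome[accession]
  lens <- nchar(seqs)
  from <- pmax(position - 3L, 1L)
  to <- pmin(position + 3L, lens)
  core <- substr(seqs, from, to)
  lpad <- strrep(PAD_CHAR, pmax(0L, 4L - position))
  rpad <- strrep(PAD_CHAR, pmax(0L, position + 3L - lens))
  paste0(lpad, core, rpad)
}

#' Score and rank every lysine-centered 7-mer in a proteome
#'
#' @param pssm a `pssm` object.
#' @param proteome named character vector or `AAStringSet`.
#' @return `data.table` with one row per lysine: `accession`, `position`,
#'   `window`, `score`, `rank` (1-based, score descending; ties broken by
#'   accession then position for reproducibility).
#' @export
rank_proteome <- function(pssm, proteome) {
  proteome <- as_proteome(proteome)
  if (length(proteome) == 0L) stop("empty proteome", call. = FALSE)
  win <- lysine_windows(proteome, pad = TRUE)
  win[, score := score_windows(pssm, window)]
  setorder(win, -score, accession, position)
  win[, rank := seq_len(.N)]
  win[]
}

#' Mean PSSM score per site group
#'
#' Resolves each methyl site to its 7-mer window in the proteome, scores it
#' with the PSSM, and averages per group (typically the enrichment
#' strategy). Sites near a terminus are scored on padded windows and their
#' count reported.
#'
#' @param sites `data.frame` with columns `accession`, `position` and the
#'   grouping column.
#' @param proteome named character vector or `AAStringSet`.
#' @param pssm a `pssm`.
#' @param group name of the grouping column (default `"strategy_label"`).
#' @return `data.table` with columns `<group>`, `n`, `n_padded`,
#'   `mean_score`.
#' @export
mean_pssm_score_by_group <- function(sites, proteome, pssm,
                                     group = "strategy_label") {
  sites <- as.data.table(sites)
  stopifnot(group %in% names(sites))
  proteome <- as_proteome(proteome)
  unknown <- setdiff(sites$accession, names(proteome))
  if (length(unknown) > 0L) {
    stop("sites reference accessions absent from the proteome: ",
         paste(head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  win <- fetch_windows(proteome, sites$accession, sites$position)
  sc <- score_windows(pssm, win)
  padded <- grepl(PAD_CHAR, win, fixed = TRUE)
  dt <- data.table(grp = sites[[group]], score = sc, padded = padded)
  out <- dt[, .(n = .N, n_padded = sum(padded), mean_score = mean(score)),
            by = .(grp)]
  setnames(out, "grp", group)
  out[]
}

#' Write a PSSM to TSV
#'
#' Rows amino acids, columns positions; missing entries are written as NA.
#' @param pssm a `pssm` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, path) {
  dt <- as.data.table(pssm$scores, keep.rownames = "aa")
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a PSSM from TSV
#' @param path file written by [write_pssm()].
#' @param antibody_id identifier to attach.
#' @return a `pssm` object.
#' @export
read_pssm <- function(path, antibody_id = "pssm") {
  dt <- fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  as_pssm(m, antibody_id = antibody_id)
}
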