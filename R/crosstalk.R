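# PTM crosstalk proximity: how often a methylated lysine lies within a
# fixed window of another PTM in a reference catalog, and within-peptide
# co-occurrence of methylation and phosphorylation.

#' Proximity of methyl sites to other PTMs
#'
#' For each methyl site and each reference PTM type, records a hit at
#' offset `d` iff the reference holds that PTM type at protein position
#' `site +/- d` on the same accession (unsigned distances by default;
#' offset 0 is the same residue, i.e. direct competition). Percentages at
#' each offset are over all methyl sites, counting each site at most once
#' per (type, offset).
#'
#' @param sites methyl site table (`accession`, `position`).
#' @param reference reference catalog (`accession`, `position`,
#'   `ptm_type`); duplicated records are ignored. Phosphorylation should
#'   already be subdivided into types such as `"phospho-S"`,
#'   `"phospho-T"`, `"phospho-Y"`.
#' @param window maximum distance considered (default 9).
#' @param signed if `TRUE`, report signed offsets `-window..window`
#'   instead of unsigned `0..window`.
#' @return object of class `proximity_profile`: list with `percent` (matrix
#'   PTM types x offsets of per-offset site percentages),
#'   `overall_within` (percent of sites with any listed PTM within the
#'   window), `window`, `signed`, `n_sites`.
#' @export
proximity_profile <- function(sites, reference, window = 9L,
                              signed = FALSE) {
  stopifnot(window >= 1L)
  sites <- unique(as.data.table(sites)[, .(accession,
                                           position = as.integer(position))])
  ref <- unique(as.data.table(reference)[, .(accession,
                                             position = as.integer(position),
                                             ptm_type)])
  types <- sort(unique(ref$ptm_type))
  offsets <- if (signed) seq(-window, window) else 0:window
  pct <- matrix(0, nrow = length(types), ncol = length(offsets),
                dimnames = list(types, as.character(offsets)))
  n_sites <- nrow(sites)
  if (n_sites == 0L) {
    return(structure(list(percent = pct, overall_within = NA_real_,
                          window = window, signed = signed, n_sites = 0L),
                     class = "proximity_profile"))
  }
  sites[, site_id := .I]
  hits <- merge(sites, ref, by = "accession", allow.cartesian = TRUE,
                suffixes = c("", ".ref"))
  hits <- hits[abs(position.ref - position) <= window]
  hits[, dist := if (signed) position.ref - position
                 else abs(position.ref - position)]
  if (nrow(hits) > 0L) {
    cell <- unique(hits[, .(site_id, ptm_type, dist)])
    tab <- cell[, .(count = .N), by = .(ptm_type, dist)]
    pct[cbind(tab$ptm_type, as.character(tab$dist))] <-
      100 * tab$count / n_sites
  }
  overall <- 100 * uniqueN(hits$site_id) / n_sites
  structure(list(percent = pct, overall_within = overall, window = window,
                 signed = signed, n_sites = n_sites),
            class = "proximity_profile")
}

#' @export
print.proximity_profile <- function(x, ...) {
  cat(sprintf(
    "PTM crosstalk proximity (window %d, %s offsets, %d methyl sites)\n",
    x$window, if (x$signed) "signed" else "unsigned", x$n_sites))
  cat(sprintf("  %.1f%% of sites have a listed PTM within the window\n",
              x$overall_within))
  invisible(x)
}

#' Percentage of methyl sites with any PTM within the window
#'
#' Site-level union over PTM types and offsets: a site hit at several
#' offsets or by several PTM types counts once.
#'
#' @param profile a [proximity_profile()].
#' @return percentage in `[0, 100]`.
#' @export
overall_within_window <- function(profile) {
  stopifnot(inherits(profile, "proximity_profile"))
  profile$overall_within
}

#' Methylation-phosphorylation co-occurrence on peptides
#'
#' Percentage of methylated peptides (records with at least one methyl
#' modification) that also carry a phosphorylation, per enrichment
#' strategy.
#'
#' @param records record table with `mods` and `strategy_label`.
#' @return `data.table` with `strategy_label`, `n_methyl_peptides`,
#'   `n_cooccur`, `percent` (`NA` for strategies without methyl peptides).
#' @export
peptide_cooccurrence <- function(records) {
  records <- as.data.table(records)
  ml <- parse_mods(records)
  has_methyl <- tabulate(ml[type %in% METHYL_TYPES, record_id],
                         nbins = nrow(records)) > 0L
  has_phospho <- tabulate(ml[grepl("^phospho", type), record_id],
                          nbins = nrow(records)) > 0L
  dt <- data.table(strategy_label = records$strategy_label,
                   methyl = has_methyl, phospho = has_phospho)
  out <- dt[, .(n_methyl_peptides = sum(methyl),
                n_cooccur = sum(methyl & phospho)),
            by = .(strategy_label)]
  out[, percent := ifelse(n_methyl_peptides == 0L, NA_real_,
                          100 * n_cooccur / n_methyl_peptides)]
  setorder(out, strategy_label)
  out[]
}

#' Write a proximity profile to TSV (long format)
#' @param profile a `proximity_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_proximity_profile <- function(profile, path) {
  m <- profile$percent
  dt <- data.table(ptm_type = rep(rownames(m), ncol(m)),
                   offset = rep(as.integer(colnames(m)), each = nrow(m)),
                   percentage = as.vector(m))
  setorder(dt, ptm_type, offset)
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
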