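# Site-level methylome accounting: call sites from filtered records,
# compare enrichment strategies, and measure novelty against a reference
# PTM catalog.

#' Call lysine methylation sites from filtered peptide records
#'
#' Each surviving methyl modification maps to protein coordinate
#' `protein_start + residue_index - 1`. Sites are deduplicated on the site
#' key — `(accession, position, state)` by default, or
#' `(accession, position)` when `collapse_state = TRUE` (a site observed in
#' two states then counts once, keeping the state with most evidence) —
#' and evidence is aggregated per (run, strategy).
#'
#' @param records filtered record table (see [filter_peptides()]).
#' @param proteome optional named character vector / `AAStringSet`; when
#'   supplied, sites whose protein coordinate is not a lysine are
#'   quarantined into the `mapping_errors` attribute instead of the catalog.
#' @param collapse_state use the state-free site key.
#' @return `data.table` of class `methyl_sites`, one row per unique site:
#'   `accession`, `position`, `state`, `n_psms`, `n_strategies`,
#'   `strategies` (comma-joined). Attributes: `evidence` (long table of
#'   per-(site, run, strategy) PSM counts) and `mapping_errors` (quarantined
#'   rows, empty unless a proteome was supplied).
#' @export
call_sites <- function(records, proteome = NULL, collapse_state = FALSE) {
  records <- as.data.table(records)
  ml <- parse_mods(records)
  ml <- ml[type %in% METHYL_TYPES]
  if (nrow(ml) == 0L) {
    empty <- data.table(accession = character(), position = integer(),
                        state = character(), n_psms = integer(),
                        n_strategies = integer(), strategies = character())
    setattr(empty, "evidence", empty[0])
    setattr(empty, "mapping_errors", empty[0])
    setattr(empty, "class", c("methyl_sites", class(empty)))
    return(empty)
  }
  ev <- data.table(
    accession = records$accession[ml$record_id],
    position = as.integer(records$protein_start[ml$record_id]) +
      ml$residue_index - 1L,
    state = ml$type,
    run_label = records$run_label[ml$record_id],
    strategy_label = records$strategy_label[ml$record_id]
  )
  errors <- ev[0]
  if (!is.null(proteome)) {
    proteome <- as_proteome(proteome)
    res <- substr(proteome[ev$accession], ev$position, ev$position)
    bad <- is.na(res) | res != "K"
    errors <- ev[bad]
    ev <- ev[!bad]
  }
  key <- if (collapse_state) c("accession", "position")
         else c("accession", "position", "state")
  by_cols <- unique(c(key, "state", "run_label", "strategy_label"))
  ev_counts <- ev[, .(n_psms = .N), by = by_cols]
  sites <- ev_counts[, .(
    n_psms = sum(n_psms),
    n_strategies = uniqueN(strategy_label),
    strategies = paste(sort(unique(strategy_label)), collapse = ",")
  ), by = key]
  if (collapse_state) {
    # a site observed in two states keeps the state with most PSM evidence
    state_tot <- ev_counts[, .(tot = sum(n_psms)), by = c(key, "state")]
    pick <- state_tot[, .(state = state[which.max(tot)]), by = key]
    sites <- merge(sites, pick, by = key)
  }
  setcolorder(sites, unique(c("accession", "position", "state")))
  setorderv(sites, c("accession", "position"))
  setattr(sites, "evidence", ev_counts)
  setattr(sites, "mapping_errors", errors)
  setattr(sites, "class", c("methyl_sites", class(sites)))
  sites[]
}

#' Per-site detection evidence
#'
#' @param sites result of [call_sites()].
#' @return long `data.table` of (site, run, strategy, PSM count) rows.
#' @export
site_evidence <- function(sites) {
  ev <- attr(sites, "evidence")
  if (is.null(ev)) stop("sites carry no evidence attribute", call. = FALSE)
  ev
}

#' Upset-style intersection counts between enrichment strategies
#'
#' Counts, for every non-empty combination of strategies, the number of
#' sites detected by exactly that combination, together with per-strategy
#' marginal totals and the fraction of sites unique to a single strategy.
#'
#' @param sites result of [call_sites()] (uses the evidence attribute), or
#'   a `data.table` with columns `accession`, `position`, `state`,
#'   `strategy_label` (one row per site-strategy detection).
#' @return list with `intersections` (`data.table`: `combo` — strategy
#'   names joined by `"&"` in sorted order — and `count`), `marginals`
#'   (per-strategy site totals), `n_sites`, and `unique_fraction`
#'   (percentage of sites seen by exactly one strategy).
#' @export
strategy_overlap <- function(sites) {
  det <- if (inherits(sites, "methyl_sites")) site_evidence(sites)
         else as.data.table(sites)
  need <- c("accession", "position", "state", "strategy_label")
  stopifnot(all(need %in% names(det)))
  det <- unique(det[, .(accession, position, state, strategy_label)])
  if (uniqueN(det$strategy_label) < 2L) {
    stop("need at least two strategies for an overlap analysis",
         call. = FALSE)
  }
  per_site <- det[, .(combo = paste(sort(unique(strategy_label)),
                                    collapse = "&"),
                      n_strategies = uniqueN(strategy_label)),
                  by = .(accession, position, state)]
  inter <- per_site[, .(count = .N), by = .(combo)]
  setorder(inter, -count, combo)
  marg <- det[, .(count = uniqueN(paste(accession, position, state))),
              by = .(strategy_label)]
  setorder(marg, -count)
  list(
    intersections = inter[],
    marginals = marg[],
    n_sites = nrow(per_site),
    unique_fraction = 100 * mean(per_site$n_strategies == 1L)
  )
}

#' Read a reference PTM catalog from TSV
#'
#' Columns: `accession`, `position`, `ptm_type`. Duplicate rows are
#' dropped.
#' @param path file path.
#' @return a `data.table`.
#' @export
read_reference_catalog <- function(path) {
  ref <- fread(path, sep = "\t")
  need <- c("accession", "position", "ptm_type")
  if (!all(need %in% names(ref))) {
    stop("reference catalog needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  unique(ref[, .(accession, position = as.integer(position), ptm_type)])
}

#' Tag sites as novel or known against a reference catalog
#'
#' A site is known iff the reference holds a methyl record at the same
#' `(accession, position, state)` — or `(accession, position)` for any
#' methyl state under the relaxed key.
#'
#' @param sites site table with `accession`, `position`, `state`.
#' @param reference reference catalog (`accession`, `position`,
#'   `ptm_type`); only methyl rows (`me1`/`me2`/`me3`) are consulted.
#' @param collapse_state match on `(accession, position)` only.
#' @return list with `sites` (input plus logical `novel` column),
#'   `per_state` (`data.table`: `state`, `n`, `n_novel`,
#'   `novel_percent`), and `novel_percent` overall.
#' @export
annotate_novelty <- function(sites, reference, collapse_state = FALSE) {
  sites <- as.data.table(sites)
  ref <- as.data.table(reference)[ptm_type %in% METHYL_TYPES]
  if (collapse_state) {
    known_keys <- unique(paste(ref$accession, ref$position))
    site_keys <- paste(sites$accession, sites$position)
  } else {
    known_keys <- unique(paste(ref$accession, ref$position, ref$ptm_type))
    site_keys <- paste(sites$accession, sites$position, sites$state)
  }
  out <- copy(sites)[, novel := !(site_keys %in% known_keys)]
  per_state <- out[, .(n = .N, n_novel = sum(novel),
                       novel_percent = 100 * mean(novel)), by = .(state)]
  setorder(per_state, state)
  list(sites = out[], per_state = per_state[],
       novel_percent = 100 * mean(out$novel))
}

#' Merge called sites with a reference catalog into a union methylome
#'
#' @param sites site table (`accession`, `position`, `state`).
#' @param reference reference catalog; only methyl rows are used.
#' @return list with `catalog` (`data.table`: site key columns plus
#'   `provenance` in `{"this-study", "reference", "both"}`), `n_sites`,
#'   `n_proteins`.
#' @export
merge_methylome <- function(sites, reference) {
  sites <- as.data.table(sites)
  ref <- as.data.table(reference)[ptm_type %in% METHYL_TYPES]
  ours <- unique(sites[, .(accession, position = as.integer(position),
                           state)])
  theirs <- unique(ref[, .(accession, position = as.integer(position),
                           state = ptm_type)])
  ours[, seen := "this-study"]
  theirs[, seen := "reference"]
  catalog <- rbindlist(list(ours, theirs))
  catalog <- catalog[, .(provenance = if (uniqueN(seen) == 2L) "both"
                                      else seen[1]),
                     by = .(accession, position, state)]
  setorderv(catalog, c("accession", "position", "state"))
  list(catalog = catalog[], n_sites = nrow(catalog),
       n_proteins = uniqueN(catalog$accession))
}

#' Per-protein methylation-event statistics
#'
#' Counts methylation events per protein, the fraction of methylated
#' proteins carrying one to three events, and the squared Pearson
#' correlation between events per protein and the number of lysines in the
#' protein's identified methylated-peptide sequences.
#'
#' @param sites site table (`accession`, `position`, `state`).
#' @param records record table; only records with a methyl mod contribute
#'   peptide sequences to the lysine count.
#' @return list with `per_protein` (`data.table`: `accession`, `events`,
#'   `lysines`), `fraction_1_3` (percent), `r_squared` (`NA` with an
#'   `insufficient` flag when fewer than 3 proteins).
#' @export
per_protein_stats <- function(sites, records) {
  sites <- as.data.table(sites)
  records <- as.data.table(records)
  events <- sites[, .(events = .N), by = .(accession)]
  ml <- parse_mods(records)
  methyl_rec <- unique(ml[type %in% METHYL_TYPES, record_id])
  pep <- unique(records[methyl_rec, .(accession, sequence)])
  lys <- pep[, .(lysines = sum(nchar(sequence) -
                                 nchar(gsub("K", "", sequence, fixed = TRUE)))),
             by = .(accession)]
  per_protein <- merge(events, lys, by = "accession", all.x = TRUE)
  per_protein[is.na(lysines), lysines := 0L]
  insufficient <- nrow(per_protein) < 3L
  r2 <- if (insufficient || sd(per_protein$events) == 0 ||
            sd(per_protein$lysines) == 0) NA_real_
        else cor(per_protein$events, per_protein$lysines)^2
  list(per_protein = per_protein[],
       fraction_1_3 = 100 * mean(per_protein$events %in% 1:3),
       r_squared = r2, insufficient = insufficient)
}

#' Write a site table to TSV
#' @param sites site table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  fwrite(as.data.table(sites), path, sep = "\t")
  invisible(path)
}

#' Read a site table from TSV
#' @param path file with columns `accession`, `position`, `state`.
#' @return a `data.table`.
#' @export
read_sites <- function(path) {
  dt <- fread(path, sep = "\t")
  need <- c("accession", "position", "state")
  if (!all(need %in% names(dt))) {
    stop("site table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dt[, position := as.integer(position)]
  dt[]
}
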