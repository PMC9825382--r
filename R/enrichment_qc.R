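# Enrichment-efficiency QC: fraction of PSMs carrying a methylated lysine,
# per run, with a per-state breakdown.

#' PSM methyl fraction per run
#'
#' For every run, the percentage of peptide spectral matches with at least
#' one methylated lysine, the per-state PSM counts, and the dominant
#' methyl state. A successfully enriched run is expected to exceed a few
#' percent methyl PSMs, with the dominant state matching the antibody's
#' target; unenriched runs sit well below one percent. A PSM carrying two
#' differently-stated methyl lysines counts once toward the overall
#' percentage and once in each state's breakdown.
#'
#' @param records record table; only rows with `is_psm` true enter the
#'   denominators.
#' @return `data.table` with one row per run: `run_label`,
#'   `strategy_label`, `total_psms`, `me1_psms`, `me2_psms`, `me3_psms`,
#'   `percent_methyl` (`NA` for a run with zero PSMs), `dominant_state`
#'   (`NA` when no methyl PSMs).
#' @export
psm_methyl_fraction <- function(records) {
  records <- as.data.table(records)
  stopifnot(all(c("run_label", "strategy_label", "is_psm", "mods") %in%
                  names(records)))
  ml <- parse_mods(records)
  runs <- unique(records[, .(run_label, strategy_label)])
  out <- lapply(seq_len(nrow(runs)), function(i) {
    rows <- which(records$run_label == runs$run_label[i] &
                    records$strategy_label == runs$strategy_label[i] &
                    as.logical(records$is_psm))
    mods_i <- ml[record_id %in% rows & type %in% METHYL_TYPES]
    per_state <- vapply(METHYL_TYPES, function(st)
      uniqueN(mods_i[type == st, record_id]), integer(1))
    n_methyl <- uniqueN(mods_i$record_id)
    total <- length(rows)
    data.table(
      run_label = runs$run_label[i],
      strategy_label = runs$strategy_label[i],
      total_psms = total,
      me1_psms = per_state[["me1"]],
      me2_psms = per_state[["me2"]],
      me3_psms = per_state[["me3"]],
      percent_methyl = if (total == 0L) NA_real_ else 100 * n_methyl / total,
      dominant_state = if (n_methyl == 0L) NA_character_
                       else METHYL_TYPES[which.max(per_state)]
    )
  })
  res <- rbindlist(out)
  setorder(res, run_label)
  res[]
}

#' Write run QC to TSV
#' @param qc result of [psm_methyl_fraction()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_qc <- function(qc, path) {
  fwrite(as.data.table(qc), path, sep = "\t")
  invisible(path)
}
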