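# Peptide/PSM record handling. Records emulate a search-engine export:
# one row per peptide spectral match (or peptide), with modifications
# encoded as "index:type:prob" triples joined by ";" — e.g.
# "3:me2:0.99;7:phospho:0.95". Methyl types are me1/me2/me3; anything else
# (phospho, other) is carried but never site-called.

METHYL_TYPES <- c("me1", "me2", "me3")

#' Parse the modification column of a record table into long format
#'
#' @param records `data.frame` with at least a `mods` column of
#'   semicolon-encoded `"index:type:prob"` strings (empty string or `NA`
#'   for unmodified).
#' @return `data.table` with one row per modification: `record_id` (row
#'   index into `records`), `residue_index`, `type`,
#'   `localization_probability`.
#' @export
parse_mods <- function(records) {
  records <- as.data.table(records)
  mods <- records$mods
  mods[is.na(mods)] <- ""
  parts <- strsplit(mods, ";", fixed = TRUE)
  n_each <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  if (length(flat) == 0L) {
    return(data.table(record_id = integer(), residue_index = integer(),
                      type = character(),
                      localization_probability = numeric()))
  }
  fields <- tstrsplit(flat, ":", fixed = TRUE)
  out <- data.table(
    record_id = rep.int(seq_len(nrow(records)), n_each),
    residue_index = as.integer(fields[[1]]),
    type = fields[[2]],
    localization_probability = as.numeric(fields[[3]])
  )
  bad <- out[is.na(residue_index) | is.na(localization_probability) |
               localization_probability < 0 | localization_probability > 1]
  if (nrow(bad) > 0L) {
    stop("malformed mods entries (need index:type:prob, prob in [0,1])",
         call. = FALSE)
  }
  out[]
}

# Re-encode a long mod table (record_id, residue_index, type,
# localization_probability) into per-record strings for n records.
encode_mods <- function(mod_long, n_records) {
  out <- rep("", n_records)
  if (nrow(mod_long) == 0L) return(out)
  enc <- mod_long[, .(s = paste(sprintf("%d:%s:%g", residue_index, type,
                                        localization_probability),
                                collapse = ";")),
                  by = .(record_id)]
  out[enc$record_id] <- enc$s
  out
}

#' Filter methyl modifications by localization probability
#'
#' Methyl modifications below the localization threshold are removed from
#' each record; non-methyl modifications are untouched. Records are never
#' dropped — a record whose methyl mods all fail the cut simply contributes
#' no sites downstream, but still counts in QC denominators.
#'
#' @param records record table (see [parse_mods()] for the `mods` format).
#' @param min_localization retain methyl mods with localization
#'   probability `>=` this value (default 0.75).
#' @return the record table with the `mods` column rewritten.
#' @export
filter_peptides <- function(records, min_localization = 0.75) {
  stopifnot(min_localization >= 0, min_localization <= 1)
  records <- as.data.table(records)
  ml <- parse_mods(records)
  keep <- !(ml$type %in% METHYL_TYPES) |
    ml$localization_probability >= min_localization
  records <- copy(records)
  records[, mods := encode_mods(ml[keep], nrow(records))]
  records[]
}

#' Read a PSM/peptide table from TSV
#'
#' Columns: `sequence`, `mods`, `accession`, `protein_start`, `run_label`,
#' `strategy_label`, `is_psm`.
#' @param path file path.
#' @return a `data.table`.
#' @export
read_psm_table <- function(path) {
  dt <- fread(path, sep = "\t", colClasses = list(character = "mods"))
  need <- c("sequence", "mods", "accession", "protein_start", "run_label",
            "strategy_label", "is_psm")
  miss <- setdiff(need, names(dt))
  if (length(miss) > 0L) {
    stop("PSM table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dt
}

#' Write a PSM/peptide table to TSV
#' @param records record table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(records, path) {
  fwrite(as.data.table(records), path, sep = "\t")
  invisible(path)
}
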