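# Combinatorial model of the lysine-oriented peptide library (K-OPL).
#
# The library for one methyl state consists of 114 sets of 9-mer peptides
# with a fixed central (methyl)lysine at position 5. Each set additionally
# fixes one amino acid (19 choices, no cysteine) at one flank offset
# (P-3..P+3); all remaining flank positions are degenerate over the same
# 19-letter alphabet. Residues at +/-4 exist on the physical peptide but
# carry no fixed identity and are ignored analytically.

#' Enumerate the K-OPL for one methyl state
#'
#' Generates all 6 x 19 = 114 sets of the lysine-oriented peptide library:
#' one set per (flank offset, fixed amino acid) pair, in deterministic order
#' (offset ascending, amino acid alphabetical). Set identifiers have the
#' stable form `"<state>_P<offset>_<aa>"`, e.g. `"me2_P-1_F"`, and serve as
#' the join key against microarray scan tables.
#'
#' @param state methyl state of the central lysine, one of
#'   `"me0"`, `"me1"`, `"me2"`, `"me3"`.
#' @return A `data.table` of class `kopl_library` with columns `set_id`,
#'   `state`, `fixed_offset`, `fixed_aa` and one row per set.
#' @export
#' @examples
#' lib <- kopl_library("me2")
#' nrow(lib)              # 114
#' table(lib$fixed_offset) # 19 sets per position group
kopl_library <- function(state = "me2") {
  assert_state(state)
  grid <- CJ(fixed_offset = KOPL_OFFSETS, fixed_aa = AA_KOPL)
  lib <- data.table(
    set_id = paste0(state, "_", offset_label(grid$fixed_offset), "_",
                    grid$fixed_aa),
    state = state,
    fixed_offset = grid$fixed_offset,
    fixed_aa = grid$fixed_aa
  )
  stopifnot(!anyDuplicated(lib$set_id))
  setattr(lib, "class", c("kopl_library", class(lib)))
  lib[]
}

#' Test whether a 9-mer peptide belongs to a K-OPL set
#'
#' A peptide is a member of a set iff its central-lysine methyl state equals
#' the set's state, the residue at the set's fixed offset equals the set's
#' fixed amino acid, and every other flank residue (P-3..P+3, excluding the
#' fixed one) is drawn from the 19-letter degenerate alphabet (no cysteine).
#' The terminal residues at +/-4 are unconstrained.
#'
#' @param set a single-row selection from [kopl_library()] (or any list with
#'   `fixed_offset`, `fixed_aa`, `state`).
#' @param peptide 9-residue character string; residue 5 must be `"K"`.
#' @param central_state methyl state of the central lysine of `peptide`.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' lib <- kopl_library("me2")
#' s <- lib[fixed_offset == -1 & fixed_aa == "F"]
#' kopl_set_membership(s, "AAAFKAAAA", "me2")  # TRUE
kopl_set_membership <- function(set, peptide, central_state) {
  if (!is.character(peptide) || length(peptide) != 1L ||
      nchar(peptide) != 9L) {
    stop("'peptide' must be a single 9-residue string", call. = FALSE)
  }
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  if (res[5] != "K") {
    stop("central residue (position 5) must be lysine", call. = FALSE)
  }
  assert_state(central_state)
  if (central_state != set$state[1]) return(FALSE)
  fixed_pos <- 5L + as.integer(set$fixed_offset[1])
  if (res[fixed_pos] != set$fixed_aa[1]) return(FALSE)
  flank_pos <- setdiff(5L + KOPL_OFFSETS, fixed_pos)
  all(res[flank_pos] %in% AA_KOPL)
}

#' Write a K-OPL manifest to TSV
#'
#' @param library a [kopl_library()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kopl_manifest <- function(library, path) {
  fwrite(as.data.table(library)[, .(set_id, state, fixed_offset, fixed_aa)],
         path, sep = "\t")
  invisible(path)
}

#' Read a K-OPL manifest from TSV
#'
#' @param path manifest written by [write_kopl_manifest()].
#' @return a `kopl_library` data.table.
#' @export
read_kopl_manifest <- function(path) {
  lib <- fread(path, sep = "\t",
               colClasses = list(character = c("set_id", "state", "fixed_aa"),
                                 integer = "fixed_offset"))
  need <- c("set_id", "state", "fixed_offset", "fixed_aa")
  if (!all(need %in% names(lib))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  setattr(lib, "class", c("kopl_library", class(lib)))
  lib[]
}
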