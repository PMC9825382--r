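# Alphabets and enumerations shared across the package.

#' Standard amino-acid alphabet (one-letter, alphabetical)
#'
#' The 20 proteinogenic amino acids in alphabetical one-letter order.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Degenerate-position alphabet of the K-OPL (cysteine excluded)
#'
#' The 19 amino acids permitted at fixed and degenerate flank positions of
#' the lysine-oriented peptide library. Cysteine is excluded from library
#' synthesis, so it never appears at a fixed position and is treated as
#' excluded from degenerate positions as well.
#' @export
AA_KOPL <- setdiff(AA_STANDARD, "C")

#' Lysine methyl states
#'
#' The four central-lysine states of the peptide libraries: unmodified
#' (`me0`) and mono-, di-, tri-methyl (`me1`, `me2`, `me3`). Methylome
#' site catalogs use only `me1`/`me2`/`me3`.
#' @export
METHYL_STATES <- c("me0", "me1", "me2", "me3")

#' Flank offsets relative to the central lysine
#'
#' The six analytic positions P-3..P+3 (P0 is always the central lysine).
#' @export
KOPL_OFFSETS <- c(-3L, -2L, -1L, 1L, 2L, 3L)

# Residue used to pad 7-mer windows that extend past a protein terminus.
# Contributes zero to PSSM scores and is excluded from frequency tables.
PAD_CHAR <- "X"

#' Format a flank offset as a position label
#'
#' @param offset integer offset(s) in `-3..3` excluding 0.
#' @return character such as `"P-1"`, `"P+2"`.
#' @export
#' @examples
#' offset_label(c(-3L, 1L))
offset_label <- function(offset) {
  sprintf("P%+d", as.integer(offset))
}

assert_state <- function(state, allow_me0 = TRUE) {
  allowed <- if (allow_me0) METHYL_STATES else setdiff(METHYL_STATES, "me0")
  if (length(state) != 1L || !state %in% allowed) {
    stop("'state' must be one of: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  state
}
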