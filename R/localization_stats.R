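# Subcellular-compartment enrichment: compare the proportion of methylome
# proteins in each compartment against the full proteome with a pooled
# two-proportion z-test.

#' Assign proteins to subcellular compartments
#'
#' A protein belongs to every compartment where its annotation score is at
#' least `min_score` (multi-membership allowed). Proteins below threshold
#' in every compartment keep an empty assignment but still count in test
#' denominators.
#'
#' @param table `data.frame` with columns `accession`, `compartment`,
#'   `score` (non-negative).
#' @param min_score inclusion threshold (default 3; the score-3-or-greater
#'   convention of stringApp-style compartment tables).
#' @return `data.table` with columns `accession`, `compartment`, one row
#'   per retained assignment.
#' @export
assign_compartments <- function(table, min_score = 3) {
  stopifnot(min_score >= 0)
  dt <- as.data.table(table)
  need <- c("accession", "compartment", "score")
  if (!all(need %in% names(dt))) {
    stop("compartment table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(dt$score < 0)) stop("scores must be non-negative", call. = FALSE)
  unique(dt[score >= min_score, .(accession, compartment)])
}

#' Two-proportion z-test of compartment enrichment
#'
#' For each compartment, compares the proportion of methylome proteins
#' assigned to it against the proportion of all proteome proteins, using
#' the pooled-variance two-proportion z statistic with a two-sided normal
#' p-value. Positive z means the compartment is over-represented in the
#' methylome.
#'
#' @param methylome_accessions accessions of methylated proteins.
#' @param proteome_accessions accessions of the full comparison proteome.
#' @param assignments result of [assign_compartments()].
#' @param alpha significance level for the `significant` flag.
#' @param bonferroni divide `alpha` by the number of tested compartments.
#' @return `data.table` with per-compartment `k1`, `n1`, `p1` (methylome),
#'   `k2`, `n2`, `p2` (proteome), `z`, `p_value`, `significant`.
#'   Compartments with no members in either group are dropped and listed
#'   in the `skipped` attribute.
#' @export
compare_proportions <- function(methylome_accessions, proteome_accessions,
                                assignments, alpha = 0.05,
                                bonferroni = FALSE) {
  meth <- unique(methylome_accessions)
  prot <- unique(proteome_accessions)
  n1 <- length(meth)
  n2 <- length(prot)
  if (n1 == 0L || n2 == 0L) {
    stop("both protein groups must be non-empty", call. = FALSE)
  }
  assignments <- as.data.table(assignments)
  comps <- sort(unique(assignments$compartment))
  rows <- lapply(comps, function(cmp) {
    members <- assignments[compartment == cmp, accession]
    k1 <- sum(meth %in% members)
    k2 <- sum(prot %in% members)
    data.table(compartment = cmp, k1 = k1, n1 = n1, k2 = k2, n2 = n2)
  })
  out <- rbindlist(rows)
  skipped <- out[k1 + k2 == 0L, compartment]
  out <- out[k1 + k2 > 0L]
  out[, `:=`(p1 = k1 / n1, p2 = k2 / n2)]
  out[, z := two_prop_z(k1, n1, k2, n2)]
  out[, p_value := 2 * pnorm(-abs(z))]
  thr <- if (bonferroni) alpha / nrow(out) else alpha
  out[, significant := p_value < thr]
  setattr(out, "skipped", skipped)
  out[]
}

#' Pooled-variance two-proportion z statistic
#'
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with pooled
#' `p = (k1 + k2) / (n1 + n2)`. Equal proportions give exactly 0
#' (including the degenerate pooled-proportion-0-or-1 case).
#'
#' @param k1,n1 successes and total in group 1.
#' @param k2,n2 successes and total in group 2.
#' @return numeric z (vectorized).
#' @export
two_prop_z <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1
  p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  ifelse(p1 == p2, 0, (p1 - p2) / se)
}

#' Read a compartment annotation table from TSV
#' @param path file with columns `accession`, `compartment`, `score`.
#' @return a `data.table`.
#' @export
read_compartment_table <- function(path) {
  fread(path, sep = "\t")
}
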