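# Independent oracles used across the suite. These are deliberately naive
# (loops, enumeration, closed forms) and never share code with the
# implementation paths they check.

# Brute-force K-OPL set membership: explicit per-residue loop.
oracle_membership <- function(peptide, central_state, set_state,
                              fixed_offset, fixed_aa) {
  res <- strsplit(peptide, "")[[1]]
  stopifnot(length(res) == 9, res[5] == "K")
  if (central_state != set_state) return(FALSE)
  ok <- TRUE
  for (off in c(-3, -2, -1, 1, 2, 3)) {
    r <- res[5 + off]
    if (off == fixed_offset) {
      if (r != fixed_aa) ok <- FALSE
    } else {
      if (r == "C" || !(r %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])) {
        ok <- FALSE
      }
    }
  }
  ok
}

# Naive 7-mer scoring: per-position lookup and sum, NA -> 0.
oracle_score_7mer <- function(score_matrix, window) {
  res <- strsplit(window, "")[[1]]
  total <- 0
  offsets <- c(-3, -2, -1, 1, 2, 3)
  for (j in seq_along(offsets)) {
    r <- res[4 + offsets[j]]
    if (r %in% rownames(score_matrix)) {
      v <- score_matrix[r, j]
      if (!is.na(v)) total <- total + v
    }
  }
  total
}

# Closed-form Pearson correlation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# Power-set enumeration of exact-combination intersection counts.
# sets: named list of character vectors of site keys.
oracle_upset <- function(sets) {
  nm <- sort(names(sets))
  all_keys <- unique(unlist(sets))
  out <- list()
  for (mask in seq_len(2^length(nm) - 1)) {
    members <- nm[bitwAnd(mask, 2^(seq_along(nm) - 1)) > 0]
    inside <- all_keys
    for (s in members) inside <- intersect(inside, sets[[s]])
    for (s in setdiff(nm, members)) inside <- setdiff(inside, sets[[s]])
    if (length(inside) > 0) {
      out[[paste(members, collapse = "&")]] <- length(inside)
    }
  }
  out
}

# Hand two-proportion pooled-variance z.
oracle_two_prop_z <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1
  p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
}

# Build a record table row by row; mods given as list of
# c(index, type, prob) triples.
make_records <- function(...) {
  rows <- list(...)
  data.table::rbindlist(lapply(rows, function(r) {
    mods <- r$mods
    mod_str <- if (is.null(mods) || length(mods) == 0) "" else
      paste(vapply(mods, function(m)
        sprintf("%s:%s:%s", m[1], m[2], m[3]), character(1)),
        collapse = ";")
    data.table::data.table(
      sequence = r$sequence, mods = mod_str,
      accession = if (is.null(r$accession)) "P1" else r$accession,
      protein_start = if (is.null(r$protein_start)) 1L else
        as.integer(r$protein_start),
      run_label = if (is.null(r$run_label)) "r1" else r$run_label,
      strategy_label = if (is.null(r$strategy_label)) "s1" else
        r$strategy_label,
      is_psm = if (is.null(r$is_psm)) TRUE else r$is_psm
    )
  }))
}

# A uniform-signal scan for a library: every on-target set at `value`.
uniform_scan <- function(library, value = 1000, n_replicates = 3,
                         antibody_id = "Ab") {
  data.table::data.table(
    antibody_id = antibody_id,
    feature_id = rep(library$set_id, each = n_replicates),
    replicate = rep(seq_len(n_replicates), times = nrow(library)),
    raw_signal = value
  )
}
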