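# Synthetic-data generators: a seeded world with known ground truth for
# every input the pipeline consumes — proteome FASTA, K-OPL array scans,
# site catalogs with controlled novelty and planted crosstalk, and PSM
# tables with configurable enrichment bias.

#' Average amino-acid composition of reviewed human proteins
#'
#' UniProt-style average residue frequencies (normalized to sum to 1);
#' the default composition of [gen_proteome()].
#' @export
AA_COMPOSITION_HUMAN <- local({
  f <- c(A = 8.25, C = 1.38, D = 5.45, E = 6.75, F = 3.86, G = 7.07,
         H = 2.27, I = 5.96, K = 5.84, L = 9.66, M = 2.42, N = 4.06,
         P = 4.70, Q = 3.93, R = 5.53, S = 6.56, T = 5.34, V = 6.87,
         W = 1.08, Y = 2.92)
  f / sum(f)
})

#' Bundle and validate simulation parameters
#'
#' Collects the generator defaults in one validated list, mainly for the
#' command-line interface; the individual generators also accept these
#' values directly.
#'
#' @param seed integer RNG seed.
#' @param n_proteins,mean_length proteome size parameters.
#' @param aa_composition named 20-vector of residue frequencies summing
#'   to 1 (within 1e-9).
#' @param noise_cv coefficient of variation of multiplicative array noise.
#' @param n_replicates array replicates per feature.
#' @param site_rates named per-state fraction of lysines methylated.
#' @param reference_fraction fraction of planted sites copied into the
#'   reference catalog (1 - true novelty).
#' @param enrichment_bias_strength logistic slope of PSSM-biased capture.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_proteins = 300L, mean_length = 450L,
                       aa_composition = AA_COMPOSITION_HUMAN,
                       noise_cv = 0.2, n_replicates = 3L,
                       site_rates = c(me1 = 0.02, me2 = 0.012, me3 = 0.008),
                       reference_fraction = 0.4,
                       enrichment_bias_strength = 0) {
  stopifnot(length(aa_composition) == 20L,
            setequal(names(aa_composition), AA_STANDARD),
            abs(sum(aa_composition) - 1) < 1e-9,
            noise_cv >= 0, n_replicates >= 1L,
            all(site_rates >= 0 & site_rates <= 1),
            reference_fraction >= 0, reference_fraction <= 1)
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 mean_length = as.integer(mean_length),
                 aa_composition = aa_composition[AA_STANDARD],
                 noise_cv = noise_cv, n_replicates = as.integer(n_replicates),
                 site_rates = site_rates,
                 reference_fraction = reference_fraction,
                 enrichment_bias_strength = enrichment_bias_strength),
            class = "sim_config")
}

#' Generate a synthetic proteome
#'
#' Seeded i.i.d. protein sequences with lognormal length variation around
#' `mean_length` and the requested residue composition; accessions are
#' `"SYN0001"` onwards. Same seed, same output, byte for byte.
#'
#' @param n_proteins number of proteins.
#' @param mean_length mean protein length (residues); lengths are
#'   lognormal with ~45% CV, floored at 50.
#' @param aa_composition named residue-frequency vector summing to 1.
#' @param seed RNG seed.
#' @return named character vector of sequences.
#' @export
gen_proteome <- function(n_proteins = 300L, mean_length = 450L,
                         aa_composition = AA_COMPOSITION_HUMAN, seed = 1L) {
  stopifnot(abs(sum(aa_composition) - 1) < 1e-9)
  set.seed(seed)
  sdlog <- 0.45
  lens <- pmax(50L, as.integer(round(rlnorm(
    n_proteins, meanlog = log(mean_length) - sdlog^2 / 2, sdlog = sdlog))))
  aas <- names(aa_composition)
  seqs <- vapply(lens, function(n) {
    paste(sample(aas, n, replace = TRUE, prob = aa_composition),
          collapse = "")
  }, character(1))
  setNames(seqs, sprintf("SYN%04d", seq_len(n_proteins)))
}

#' Write a proteome to FASTA
#' @param proteome named character vector or `AAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  proteome <- as_proteome(proteome)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteome), path)
  invisible(path)
}

#' Read a proteome from FASTA
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_proteome_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  setNames(as.character(x), names(x))
}

#' Define a ground-truth antibody for array simulation
#'
#' The truth is a per-(position, amino acid) affinity weight matrix over
#' the 19 x 6 K-OPL grid, a cross-reactivity scalar per methyl state
#' (1 for the target state), and a global intensity. Preferences are drawn
#' from a Beta distribution whose mean sets the expected pan metric;
#' optional `boost` cells emulate the strong position-specific biases seen
#' in real antibodies (e.g. hydrophobic preference at P-1).
#'
#' @param antibody_id identifier.
#' @param target_state methyl state the antibody is raised against.
#' @param pan_mean mean affinity weight of the Beta draw (default 0.35:
#'   most antibodies are substantially biased).
#' @param boost optional named list, position label -> amino acids, whose
#'   cells are set to 1 (maximal preference).
#' @param cross_reactivity named weights for the other states (target is
#'   forced to 1); default small off-state binding.
#' @param global_intensity raw fluorescence scale.
#' @param seed RNG seed.
#' @return list of class `truth_antibody` with fields `antibody_id`,
#'   `target_state`, `preference` (19 x 6 matrix), `cross_reactivity`,
#'   `global_intensity`.
#' @export
truth_antibody <- function(antibody_id, target_state = "me2",
                           pan_mean = 0.35, boost = NULL,
                           cross_reactivity = c(me0 = 0.01, me1 = 0.05,
                                                me2 = 0.05, me3 = 0.05),
                           global_intensity = 50000, seed = 1L) {
  assert_state(target_state)
  set.seed(seed)
  a <- 2
  b <- a * (1 - pan_mean) / pan_mean
  pref <- matrix(rbeta(length(AA_KOPL) * length(KOPL_OFFSETS), a, b),
                 nrow = length(AA_KOPL), ncol = length(KOPL_OFFSETS),
                 dimnames = list(AA_KOPL, offset_label(KOPL_OFFSETS)))
  if (!is.null(boost)) {
    for (poslab in names(boost)) {
      pref[boost[[poslab]], poslab] <- 1
    }
  }
  cr <- cross_reactivity
  cr[target_state] <- 1
  cr <- cr[METHYL_STATES]
  names(cr) <- METHYL_STATES
  cr[is.na(cr)] <- 0
  stopifnot(all(pref >= 0), any(pref > 0), all(cr >= 0 & cr <= 1))
  structure(list(antibody_id = antibody_id, target_state = target_state,
                 preference = pref, cross_reactivity = cr,
                 global_intensity = global_intensity),
            class = "truth_antibody")
}

#' Simulate a K-OPL microarray scan for one antibody
#'
#' Expected signal of set (state, offset, aa) is
#' `global_intensity * cross_reactivity(state) * preference(offset, aa)`;
#' replicates get multiplicative lognormal noise of unit mean and
#' coefficient of variation `noise_cv` (0 = exact expectations). All four
#' state libraries are printed on the slide, so off-target binding is
#' visible under global normalization.
#'
#' @param truth a [truth_antibody()].
#' @param states methyl-state libraries printed on the array.
#' @param noise_cv replicate noise CV (default 0.2).
#' @param n_replicates replicates per feature (default 3).
#' @param seed RNG seed.
#' @return `data.table` with columns `antibody_id`, `feature_id`,
#'   `replicate`, `raw_signal`.
#' @export
sim_kopl_array <- function(truth, states = METHYL_STATES, noise_cv = 0.2,
                           n_replicates = 3L, seed = 1L) {
  stopifnot(inherits(truth, "truth_antibody"), noise_cv >= 0,
            n_replicates >= 1L)
  set.seed(seed)
  feats <- rbindlist(lapply(states, function(st) {
    lib <- kopl_library(st)
    data.table(feature_id = lib$set_id,
               expected = truth$global_intensity *
                 truth$cross_reactivity[[st]] *
                 truth$preference[cbind(lib$fixed_aa,
                                        offset_label(lib$fixed_offset))])
  }))
  scan <- feats[rep(seq_len(.N), each = n_replicates)]
  scan[, replicate := rep(seq_len(n_replicates), times = nrow(feats))]
  if (noise_cv > 0) {
    sdl <- sqrt(log(1 + noise_cv^2))
    noise <- rlnorm(nrow(scan), meanlog = -sdl^2 / 2, sdlog = sdl)
  } else {
    noise <- 1
  }
  scan[, raw_signal := expected * noise]
  scan[, `:=`(antibody_id = truth$antibody_id, expected = NULL)]
  setcolorder(scan, c("antibody_id", "feature_id", "replicate",
                      "raw_signal"))
  scan[]
}

#' Simulate a methylome with controlled novelty and planted crosstalk
#'
#' Selects lysines per methyl state at the given rates (each lysine gets
#' at most one state). With `motif_bias`, selection is weighted by
#' `exp(motif_strength * z)` of the standardized PSSM window score, which
#' plants recoverable motif structure. A `reference_fraction` of planted
#' sites is copied into the reference catalog, so true novelty is
#' `1 - reference_fraction`. Crosstalk PTMs are planted near methyl sites
#' at the configured rates: acetylation/ubiquitylation mostly at offset 0
#' (direct competition), sumoylation and phosphorylation at offsets 1..9
#' (phosphorylation never at offset 0 — a lysine cannot be
#' phosphorylated).
#'
#' @param proteome named character vector or `AAStringSet`.
#' @param site_rates named fractions of lysines methylated per state.
#' @param reference_fraction fraction of sites copied into the reference.
#' @param motif_bias optional `pssm` used to bias site selection.
#' @param motif_strength logistic-weight scale of the bias (default 1).
#' @param crosstalk named list, ptm_type -> list(rate, offsets, weights);
#'   `NULL` for the built-in defaults, empty list to disable.
#' @param seed RNG seed.
#' @return list with `sites` (`accession`, `position`, `state`) and
#'   `reference` (`accession`, `position`, `ptm_type`).
#' @export
sim_methylome <- function(proteome,
                          site_rates = c(me1 = 0.02, me2 = 0.012,
                                         me3 = 0.008),
                          reference_fraction = 0.4, motif_bias = NULL,
                          motif_strength = 1, crosstalk = NULL,
                          seed = 1L) {
  proteome <- as_proteome(proteome)
  stopifnot(all(site_rates >= 0 & site_rates <= 1),
            reference_fraction >= 0, reference_fraction <= 1)
  set.seed(seed)
  win <- lysine_windows(proteome, pad = TRUE)
  if (nrow(win) == 0L) stop("proteome contains no lysines", call. = FALSE)
  w <- rep(1, nrow(win))
  if (!is.null(motif_bias)) {
    sc <- score_windows(motif_bias, win$window)
    z <- if (sd(sc) > 0) (sc - mean(sc)) / sd(sc) else sc * 0
    w <- exp(motif_strength * z)
  }
  available <- rep(TRUE, nrow(win))
  sites <- list()
  for (st in names(site_rates)) {
    n_st <- min(round(site_rates[[st]] * nrow(win)), sum(available))
    if (n_st == 0L) next
    idx <- sample(which(available), n_st, prob = w[available])
    available[idx] <- FALSE
    sites[[st]] <- data.table(accession = win$accession[idx],
                              position = win$position[idx], state = st)
  }
  sites <- rbindlist(sites)
  if (nrow(sites) == 0L) {
    return(list(sites = sites,
                reference = data.table(accession = character(),
                                       position = integer(),
                                       ptm_type = character())))
  }
  setorderv(sites, c("accession", "position"))
  in_ref <- runif(nrow(sites)) < reference_fraction
  reference <- sites[in_ref, .(accession, position, ptm_type = state)]
  if (is.null(crosstalk)) {
    crosstalk <- list(
      acetyl = list(rate = 0.20, offsets = 0:9,
                    weights = c(6, rep(1, 9))),
      ubiquityl = list(rate = 0.20, offsets = 0:9,
                       weights = c(6, rep(1, 9))),
      sumo = list(rate = 0.05, offsets = 0:9,
                  weights = c(3, rep(1, 9))),
      `phospho-S` = list(rate = 0.25, offsets = 1:9, weights = rep(1, 9)),
      `phospho-T` = list(rate = 0.10, offsets = 1:9, weights = rep(1, 9)),
      `phospho-Y` = list(rate = 0.05, offsets = 1:9, weights = rep(1, 9))
    )
  }
  lens <- nchar(proteome)
  planted <- list()
  for (pt in names(crosstalk)) {
    cfgp <- crosstalk[[pt]]
    hit <- runif(nrow(sites)) < cfgp$rate
    if (!any(hit)) next
    d <- sample(cfgp$offsets, sum(hit), replace = TRUE,
                prob = cfgp$weights)
    sgn <- sample(c(-1L, 1L), sum(hit), replace = TRUE)
    pos <- sites$position[hit] + sgn * d
    acc <- sites$accession[hit]
    ok <- pos >= 1L & pos <= lens[acc]
    planted[[pt]] <- data.table(accession = acc[ok],
                                position = as.integer(pos[ok]),
                                ptm_type = pt)
  }
  reference <- unique(rbindlist(c(list(reference), planted)))
  setorderv(reference, c("accession", "position", "ptm_type"))
  list(sites = sites[], reference = reference[])
}

# Tryptic digest boundaries for one protein: cleave after K/R except at
# blocked (methylated) positions. Returns peptide (start, end) pairs.
digest_boundaries <- function(seq, blocked = integer()) {
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  cleav <- which(res %in% c("K", "R"))
  cleav <- setdiff(cleav, blocked)
  ends <- sort(unique(c(cleav, length(res))))
  starts <- c(1L, head(ends, -1L) + 1L)
  keep <- starts <= ends
  data.table(start = starts[keep], end = ends[keep])
}

#' Default enrichment-strategy design for PSM simulation
#'
#' One unenriched run plus one enriched run per methyl state. Capture and
#' background rates are chosen so enriched runs land above a few percent
#' methyl PSMs and unenriched runs below one percent, as seen in practice.
#'
#' @return `data.table` with columns `strategy_label`, `run_label`,
#'   `target_state` (`NA` = all states captured equally), `capture`,
#'   `background_psms`.
#' @export
sim_strategies <- function() {
  data.table(
    strategy_label = c("unenriched", "Kme1-A", "Kme2-A", "Kme3-A"),
    run_label = c("run_unenriched", "run_kme1a", "run_kme2a", "run_kme3a"),
    target_state = c(NA, "me1", "me2", "me3"),
    capture = c(0.03, 0.55, 0.55, 0.55),
    background_psms = c(4000L, 900L, 900L, 900L)
  )
}

#' Simulate a PSM table from a site catalog
#'
#' Proteins are digested tryptic-style (cleavage after K/R; methylated
#' lysines block cleavage). Per strategy, each site is captured with
#' probability `plogis(qlogis(capture) + bias_strength * z)` where `z` is
#' the standardized `capture_pssm` window score (bias 0 = uniform
#' capture); enriched strategies with a `target_state` capture off-state
#' sites at one tenth the rate. Captured peptides carry all their methyl
#' sites as modifications with high localization probabilities (or exactly
#' 1 under `localization = "perfect"`); decoy methyl mods with low
#' localization are sprinkled on background peptides at `decoy_rate`, and
#' methyl peptides pick up a phosphorylation at `phospho_rate` when the
#' peptide has an S/T/Y.
#'
#' @param sites planted site catalog (`accession`, `position`, `state`).
#' @param proteome named character vector or `AAStringSet`.
#' @param strategies strategy design table, see [sim_strategies()].
#' @param capture_pssm optional `pssm` driving capture bias.
#' @param bias_strength logistic slope of the capture bias (default 0);
#'   a `bias_strength` column in `strategies` overrides it per strategy.
#' @param phospho_rate per-methyl-peptide phosphorylation co-occurrence
#'   rate (default 0.2).
#' @param decoy_rate fraction of background peptides with a spurious,
#'   poorly localized methyl mod (default 0.002).
#' @param localization `"noisy"` (Beta-distributed probabilities) or
#'   `"perfect"` (all 1).
#' @param seed RNG seed.
#' @return record `data.table` with columns `sequence`, `mods`,
#'   `accession`, `protein_start`, `run_label`, `strategy_label`,
#'   `is_psm`.
#' @export
sim_psm_table <- function(sites, proteome, strategies = sim_strategies(),
                          capture_pssm = NULL, bias_strength = 0,
                          phospho_rate = 0.2, decoy_rate = 0.002,
                          localization = c("noisy", "perfect"),
                          seed = 1L) {
  localization <- match.arg(localization)
  proteome <- as_proteome(proteome)
  sites <- as.data.table(sites)
  strategies <- as.data.table(strategies)
  set.seed(seed)

  # peptide containing each methyl site, under methyl-blocked digestion
  site_pep <- rbindlist(lapply(split(sites, by = "accession"), function(ps) {
    acc <- ps$accession[1]
    b <- digest_boundaries(proteome[[acc]], blocked = ps$position)
    idx <- findInterval(ps$position, b$start)
    data.table(accession = acc, position = ps$position, state = ps$state,
               start = b$start[idx], end = b$end[idx])
  }))

  # capture weights from PSSM bias
  z <- rep(0, nrow(site_pep))
  if (!is.null(capture_pssm)) {
    win <- fetch_windows(proteome, site_pep$accession, site_pep$position)
    sc <- score_windows(capture_pssm, win)
    if (sd(sc) > 0) z <- (sc - mean(sc)) / sd(sc)
  }

  # background tryptic peptide pool (unmodified digestion)
  pool <- rbindlist(lapply(names(proteome), function(acc) {
    b <- digest_boundaries(proteome[[acc]])
    b[, accession := acc]
    b
  }))
  pool <- pool[end - start + 1L >= 6L]

  loc_true <- function(n) {
    if (localization == "perfect") rep(1, n) else rbeta(n, 18, 1.5)
  }

  out <- lapply(seq_len(nrow(strategies)), function(i) {
    strat <- strategies[i]
    bs <- if ("bias_strength" %in% names(strategies)) strat$bias_strength
          else bias_strength
    p <- stats::plogis(stats::qlogis(strat$capture) + bs * z)
    if (!is.na(strat$target_state)) {
      p <- p * ifelse(site_pep$state == strat$target_state, 1, 0.1)
    }
    captured <- site_pep[runif(nrow(site_pep)) < p]
    rows <- list()
    if (nrow(captured) > 0L) {
      peps <- unique(captured[, .(accession, start, end)])
      n_psm <- if (localization == "perfect") rep(1L, nrow(peps))
               else 1L + rpois(nrow(peps), 0.5)
      peps <- peps[rep(seq_len(.N), n_psm)]
      pep_seq <- substr(proteome[peps$accession], peps$start, peps$end)
      mods <- vapply(seq_len(nrow(peps)), function(k) {
        ms <- site_pep[accession == peps$accession[k] &
                         position >= peps$start[k] &
                         position <= peps$end[k]]
        entries <- sprintf("%d:%s:%g", ms$position - peps$start[k] + 1L,
                           ms$state, loc_true(nrow(ms)))
        if (phospho_rate > 0 && runif(1) < phospho_rate) {
          sty <- gregexpr("[STY]", pep_seq[k])[[1]]
          if (sty[1] != -1L) {
            j <- sample(length(sty), 1L)
            resk <- substr(pep_seq[k], sty[j], sty[j])
            entries <- c(entries, sprintf("%d:phospho-%s:%g",
                                          as.integer(sty[j]), resk,
                                          loc_true(1L)))
          }
        }
        paste(entries, collapse = ";")
      }, character(1))
      rows$methyl <- data.table(sequence = pep_seq, mods = mods,
                                accession = peps$accession,
                                protein_start = peps$start)
    }
    if (strat$background_psms > 0L && nrow(pool) > 0L) {
      bg <- pool[sample(.N, strat$background_psms, replace = TRUE)]
      bg_seq <- substr(proteome[bg$accession], bg$start, bg$end)
      bg_mods <- rep("", nrow(bg))
      if (decoy_rate > 0) {
        # decoys land on lysine-containing peptides so the realized methyl
        # fraction matches the nominal rate (binomially)
        candidates <- which(grepl("K", bg_seq, fixed = TRUE))
        n_decoy <- min(rbinom(1L, nrow(bg), decoy_rate),
                       length(candidates))
        decoy <- sample(candidates, n_decoy)
        for (k in decoy) {
          kpos <- gregexpr("K", bg_seq[k], fixed = TRUE)[[1]]
          j <- sample(length(kpos), 1L)
          bg_mods[k] <- sprintf("%d:%s:%g", as.integer(kpos[j]),
                                sample(METHYL_TYPES, 1L), rbeta(1, 2, 6))
        }
      }
      rows$background <- data.table(sequence = bg_seq, mods = bg_mods,
                                    accession = bg$accession,
                                    protein_start = bg$start)
    }
    res <- rbindlist(rows)
    if (nrow(res) == 0L) return(NULL)
    res[, `:=`(run_label = strat$run_label,
               strategy_label = strat$strategy_label, is_psm = TRUE)]
    res
  })
  rbindlist(out)[]
}
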