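test_that("localization filtering keeps methyl mods at or above threshold", {
  probs <- c(0.5, 0.74, 0.75, 0.9, 1.0)
  recs <- do.call(make_records, lapply(probs, function(p)
    list(sequence = "AAAKAAA", mods = list(c(4, "me1", p)))))
  # threshold 0 -> identity
  expect_equal(filter_peptides(recs, 0)$mods, recs$mods)
  # threshold 1 -> only the prob-1 mod survives
  expect_equal(sum(filter_peptides(recs, 1)$mods != ""), 1L)
  # threshold 0.75 -> 3 survive (>= comparison)
  expect_equal(sum(filter_peptides(recs, 0.75)$mods != ""), 3L)
  # non-methyl mods are untouched by the methyl threshold
  rec_p <- make_records(list(sequence = "AAAKSAA",
                             mods = list(c(4, "me2", 0.2),
                                         c(5, "phospho-S", 0.2))))
  filt <- filter_peptides(rec_p, 0.75)
  expect_match(filt$mods, "phospho-S")
  expect_no_match(filt$mods, "me2")
})

test_that("site calling maps peptide mods to protein coordinates", {
  rec <- make_records(
    list(sequence = "AAKAA", protein_start = 10,
         mods = list(c(3, "me2", 0.99))),
    list(sequence = "AKAAX", protein_start = 11, run_label = "r2",
         strategy_label = "s2", mods = list(c(2, "me2", 0.95)))
  )
  sites <- call_sites(rec)
  expect_equal(nrow(sites), 1L)  # same (accession, position, state)
  expect_equal(sites$position, 12L)
  expect_equal(sites$state, "me2")
  expect_equal(sites$n_psms, 2L)
  expect_equal(sites$strategies, "s1,s2")
  expect_equal(nrow(site_evidence(sites)), 2L)
})

test_that("non-lysine mappings are quarantined when a proteome is given", {
  prot <- c(P1 = "AAAKAAAAAA")
  rec <- make_records(
    list(sequence = "AAAKAA", protein_start = 1,
         mods = list(c(4, "me1", 1))),
    list(sequence = "AAAAA", protein_start = 5,
         mods = list(c(2, "me1", 1)))  # maps to position 6 = A
  )
  sites <- call_sites(rec, proteome = prot)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$position, 4L)
  errs <- attr(sites, "mapping_errors")
  expect_equal(nrow(errs), 1L)
  expect_equal(errs$position, 6L)
})

test_that("collapsing the state key never increases the site count", {
  set.seed(21)
  prot <- gen_proteome(40, 250, seed = 22)
  sim <- sim_methylome(prot, seed = 23)
  psms <- sim_psm_table(sim$sites, prot, seed = 24)
  filt <- filter_peptides(psms)
  with_state <- call_sites(filt)
  collapsed <- call_sites(filt, collapse_state = TRUE)
  expect_lte(nrow(collapsed), nrow(with_state))
})

test_that("strategy overlap matches the power-set oracle on hand-built sets", {
  sets <- list(
    alpha = c("P1:10", "P1:20", "P2:5", "P3:7"),
    beta  = c("P1:10", "P2:5", "P9:1"),
    gamma = c("P1:20", "P2:5", "P4:4", "P5:2")
  )
  det <- data.table::rbindlist(lapply(names(sets), function(s) {
    parts <- data.table::tstrsplit(sets[[s]], ":")
    data.table::data.table(accession = parts[[1]],
                           position = as.integer(parts[[2]]),
                           state = "me1", strategy_label = s)
  }))
  ov <- strategy_overlap(det)
  want <- oracle_upset(sets)
  got <- setNames(ov$intersections$count, ov$intersections$combo)
  expect_mapequal(as.list(got), want)
  expect_equal(ov$n_sites, length(unique(unlist(sets))))
  # partition property: intersection counts sum to the unique-site total
  expect_equal(sum(ov$intersections$count), ov$n_sites)
  n_unique <- sum(unlist(want[!grepl("&", names(want))]))
  expect_equal(ov$unique_fraction, 100 * n_unique / ov$n_sites)
})

test_that("disjoint and identical strategy sets hit the trivial overlaps", {
  mk <- function(acc, strat) data.table::data.table(
    accession = acc, position = 1L, state = "me2", strategy_label = strat)
  disj <- rbind(mk(paste0("A", 1:3), "s1"), mk(paste0("B", 1:4), "s2"))
  ov <- strategy_overlap(disj)
  expect_equal(ov$unique_fraction, 100)
  expect_false("s1&s2" %in% ov$intersections$combo)
  ident <- rbind(mk(paste0("A", 1:3), "s1"), mk(paste0("A", 1:3), "s2"))
  ov2 <- strategy_overlap(ident)
  expect_equal(ov2$unique_fraction, 0)
  expect_equal(ov2$intersections$combo, "s1&s2")
})

test_that("novelty accounting against a reference catalog", {
  sites <- data.table::data.table(accession = "P1", position = 1:10,
                                  state = "me2")
  ref0 <- data.table::data.table(accession = character(),
                                 position = integer(),
                                 ptm_type = character())
  expect_equal(annotate_novelty(sites, ref0)$novel_percent, 100)
  ref_all <- data.table::data.table(accession = "P1", position = 1:10,
                                    ptm_type = "me2")
  expect_equal(annotate_novelty(sites, ref_all)$novel_percent, 0)
  ref4 <- ref_all[1:4]
  nov <- annotate_novelty(sites, ref4)
  expect_equal(nov$novel_percent, 60)
  # state-aware key: same position, different state stays novel
  ref_wrong_state <- data.table::data.table(accession = "P1",
                                            position = 1:10,
                                            ptm_type = "me1")
  expect_equal(annotate_novelty(sites, ref_wrong_state)$novel_percent, 100)
  expect_equal(annotate_novelty(sites, ref_wrong_state,
                                collapse_state = TRUE)$novel_percent, 0)
  # novelty and known fractions sum to 100 per state
  ps <- nov$per_state
  expect_equal(ps$n_novel + (ps$n - ps$n_novel), ps$n)
})

test_that("merging with the reference follows inclusion-exclusion", {
  ours <- data.table::data.table(accession = "P1", position = c(1L, 2L, 3L),
                                 state = "me1")
  ref <- data.table::data.table(accession = "P1", position = c(3L, 4L),
                                ptm_type = "me1")
  m <- merge_methylome(ours, ref)
  expect_equal(m$n_sites, 4L)  # 3 + 2 - 1 shared
  expect_equal(m$catalog$provenance,
               c("this-study", "this-study", "both", "reference"))
  # disjoint -> m + n; identical -> m with provenance both
  ref_d <- data.table::data.table(accession = "P2", position = 1:2,
                                  ptm_type = "me1")
  expect_equal(merge_methylome(ours, ref_d)$n_sites, 5L)
  ref_i <- data.table::data.table(accession = "P1", position = 1:3,
                                  ptm_type = "me1")
  mi <- merge_methylome(ours, ref_i)
  expect_equal(mi$n_sites, 3L)
  expect_true(all(mi$catalog$provenance == "both"))
  expect_equal(mi$n_proteins, 1L)
})

test_that("per-protein stats: histogram fraction and Pearson r-squared", {
  # every protein exactly one site -> 1-3 fraction 100%
  s1 <- data.table::data.table(accession = paste0("P", 1:5), position = 4L,
                               state = "me1")
  r1 <- make_records(list(sequence = "AAAKAA", accession = "P1",
                          mods = list(c(4, "me1", 1))))
  expect_equal(per_protein_stats(s1, r1)$fraction_1_3, 100)
  # hand-built 5-protein table: r^2 against the closed-form oracle
  events <- c(1, 2, 3, 5, 8)
  lysK <- c(2, 2, 4, 6, 7)
  sites <- data.table::rbindlist(lapply(1:5, function(i)
    data.table::data.table(accession = paste0("P", i),
                           position = seq_len(events[i]), state = "me1")))
  recs <- do.call(make_records, lapply(1:5, function(i)
    list(sequence = paste(rep("K", lysK[i]), collapse = ""),
         accession = paste0("P", i), mods = list(c(1, "me1", 1)))))
  st <- per_protein_stats(sites, recs)
  expect_equal(st$r_squared, oracle_pearson(events, lysK)^2)
  # counts proportional to lysines -> r^2 = 1
  recs2 <- do.call(make_records, lapply(1:5, function(i)
    list(sequence = paste(rep("K", events[i] * 2), collapse = ""),
         accession = paste0("P", i), mods = list(c(1, "me1", 1)))))
  expect_equal(per_protein_stats(sites, recs2)$r_squared, 1)
  # fewer than 3 proteins -> flagged insufficient
  expect_true(per_protein_stats(s1[1:2], r1)$insufficient)
})

test_that("round-trip: perfect-capture PSM simulation reproduces the catalog", {
  prot <- gen_proteome(40, 250, seed = 51)
  sim <- sim_methylome(prot, seed = 52)
  strat <- data.table::data.table(strategy_label = "full",
                                  run_label = "r1", target_state = NA,
                                  capture = 1, background_psms = 0L)
  psms <- sim_psm_table(sim$sites, prot, strategies = strat,
                        phospho_rate = 0, decoy_rate = 0,
                        localization = "perfect", seed = 53)
  called <- call_sites(filter_peptides(psms), proteome = prot)
  expect_true(data.table::fsetequal(
    data.table::as.data.table(called)[, .(accession, position, state)],
    sim$sites[, .(accession, position, state)]))
  expect_equal(nrow(attr(called, "mapping_errors")), 0L)
})

test_that("site tables round-trip through TSV", {
  sites <- data.table::data.table(accession = c("P1", "P2"),
                                  position = c(3L, 9L),
                                  state = c("me1", "me3"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sites(sites, path)
  expect_equal(as.data.frame(read_sites(path)), as.data.frame(sites))
})
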