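saturated_profile <- function(state = "me2") {
  lib <- kopl_library(state)
  build_profile(uniform_scan(lib), lib)
}

test_that("pan metric hits its bounds and the half-filled midpoint", {
  prof <- saturated_profile()
  expect_equal(pan_metric(prof)$score, 100)
  # half the cells at 1, half at ~0 -> score 50 (57/57 split of 114)
  lib <- kopl_library("me2")
  scan <- uniform_scan(lib, value = 1e-9)
  hot <- lib$set_id[1:57]
  scan[scan$feature_id %in% hot, "raw_signal"] <- 1000
  prof2 <- build_profile(scan, lib)
  expect_equal(pan_metric(prof2)$score, 50, tolerance = 1e-6)
  # all-zero on-target cells against a bright off-target feature -> 0
  scan0 <- uniform_scan(lib, value = 0)
  off <- data.table::data.table(antibody_id = "Ab", feature_id = "ctrl",
                                replicate = 1:3, raw_signal = 100)
  expect_equal(pan_metric(build_profile(rbind(scan0, off), lib))$score, 0)
})

test_that("pan metric is monotone in any single cell", {
  lib <- kopl_library("me2")
  set.seed(11)
  scan <- uniform_scan(lib, value = 100)
  scan$raw_signal <- runif(nrow(scan), 50, 400)
  # keep one feature clearly the max so raising another cell cannot
  # change the normalization denominator
  scan[scan$feature_id == lib$set_id[1], "raw_signal"] <- 1000
  base <- pan_metric(build_profile(scan, lib))$score
  for (sid in sample(lib$set_id[-1], 5)) {
    bumped <- data.table::copy(scan)
    bumped[bumped$feature_id == sid, "raw_signal"] <-
      bumped[bumped$feature_id == sid, raw_signal] * 1.5
    expect_gte(pan_metric(build_profile(bumped, lib))$score, base)
  }
})

test_that("PSSM is the identity mapping of the profile, cysteine missing", {
  truth <- truth_antibody("AbX", "me2", seed = 5)
  scan <- sim_kopl_array(truth, noise_cv = 0, seed = 6)
  prof <- build_profile(scan, kopl_library("me2"))
  pssm <- build_pssm(prof)
  expect_equal(pssm$scores[AA_KOPL, ], prof$matrix)
  expect_true(all(is.na(pssm$scores["C", ])))
  # uniform profile -> uniform PSSM
  u <- saturated_profile()
  expect_true(all(build_pssm(u)$scores[AA_KOPL, ] == 1))
})

test_that("score_7mer sums single-position lookups", {
  p <- as_pssm(matrix(0.8, 1, 1, dimnames = list("F", "P-1")))
  expect_equal(score_7mer(p, "AAFKAAA"), 0.8)
  expect_equal(score_7mer(p, "AAAKAAA"), 0)
  u <- as_pssm(matrix(0.3, length(AA_KOPL), 6,
                      dimnames = list(AA_KOPL, offset_label(KOPL_OFFSETS))))
  expect_equal(score_7mer(u, "AAAKAAA"), 6 * 0.3)
  expect_equal(score_7mer(u, "XXAKAAA"), 4 * 0.3)  # padding scores 0
  expect_equal(score_7mer(u, "CCAKAAA"), 4 * 0.3)  # cysteine missing -> 0
  expect_error(score_7mer(u, "AAAKAA"), "7 residues")
  expect_error(score_7mer(u, "AAARAAA"), "lysine")
})

test_that("score_7mer matches the brute-force oracle on random windows", {
  set.seed(33)
  truth <- truth_antibody("AbO", "me1", seed = 34)
  pssm <- build_pssm(build_profile(
    sim_kopl_array(truth, seed = 35), kopl_library("me1")))
  windows <- vapply(1:500, function(i) {
    res <- sample(c(AA_STANDARD, "X"), 6, replace = TRUE)
    paste(c(res[1:3], "K", res[4:6]), collapse = "")
  }, character(1))
  got <- vapply(windows, function(w) score_7mer(pssm, w), numeric(1))
  want <- vapply(windows, function(w) oracle_score_7mer(pssm$scores, w),
                 numeric(1))
  expect_equal(unname(got), unname(want))
})

test_that("rank_proteome emits one record per lysine, sorted with stable ties", {
  pssm <- as_pssm(matrix(0.5, 1, 1, dimnames = list("D", "P+1")))
  prot <- c(A1 = "MKDKKAM", B2 = "KDKR", C3 = "MAMA")
  ranked <- rank_proteome(pssm, prot)
  n_k <- sum(lengths(regmatches(prot, gregexpr("K", prot))))
  expect_equal(nrow(ranked), n_k)
  expect_equal(ranked$rank, seq_len(nrow(ranked)))
  expect_true(all(diff(ranked$score) <= 0))
  # K followed by D scores 0.5, others 0; ties by (accession, position)
  top <- ranked[ranked$score == 0.5, ]
  expect_equal(top$accession, c("A1", "B2"))
  expect_equal(top$position, c(2L, 1L))
  expect_error(rank_proteome(pssm, character(0)), "empty|named")
})

test_that("a PSSM favoring (P+1, D) enriches D at P+1 in the top decile", {
  set.seed(77)
  prot <- gen_proteome(n_proteins = 80, mean_length = 250, seed = 78)
  pssm <- as_pssm(matrix(1, 1, 1, dimnames = list("D", "P+1")))
  ranked <- rank_proteome(pssm, prot)
  dec <- ranked[ranked$rank <= nrow(ranked) / 10, ]
  f_top <- mean(substr(dec$window, 5, 5) == "D")
  f_all <- mean(substr(ranked$window, 5, 5) == "D")
  expect_gt(f_top, f_all)
})

test_that("mean PSSM score by group averages site windows per strategy", {
  pssm <- as_pssm(matrix(0.5, 1, 1, dimnames = list("D", "P+1")))
  prot <- c(P1 = "AAAKDAAAKAAA")
  sites <- data.table::data.table(
    accession = "P1", position = c(4L, 9L, 4L),
    strategy_label = c("s1", "s1", "s2"))
  out <- mean_pssm_score_by_group(sites, prot, pssm)
  expect_equal(out$mean_score[out$strategy_label == "s1"], 0.25)
  expect_equal(out$mean_score[out$strategy_label == "s2"], 0.5)
  # identical groups -> identical means; singleton group -> its own score
  expect_equal(out$n, c(2L, 1L))
})

test_that("pan_vs_intensity reproduces the closed-form Pearson r", {
  dt <- data.frame(score = c(10, 30, 55, 80),
                   max_signal = c(1000, 2500, 2400, 6000))
  res <- pan_vs_intensity(dt)
  expect_equal(res$r, oracle_pearson(dt$max_signal, dt$score))
  expect_equal(res$r_squared, res$r^2)
  expect_equal(res$n, 4L)
  # perfectly proportional -> r = 1
  prop <- data.frame(score = 1:5, max_signal = (1:5) * 7)
  expect_equal(pan_vs_intensity(prop)$r, 1)
  # degenerate and undersized panels
  expect_true(pan_vs_intensity(
    data.frame(score = c(1, 1, 1), max_signal = 1:3))$degenerate)
  expect_error(pan_vs_intensity(dt[1:2, ]), "at least 3")
})

test_that("PSSM TSV round-trips", {
  truth <- truth_antibody("AbT", "me3", seed = 9)
  pssm <- build_pssm(build_profile(sim_kopl_array(truth, seed = 10),
                                   kopl_library("me3")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pssm(pssm, path)
  back <- read_pssm(path)
  expect_equal(back$scores, pssm$scores)
})
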