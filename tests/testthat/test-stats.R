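test_that("group summaries reproduce the hand-checked reference values", {
  pm <- group_summary(c(30, 28, 30, 25))
  expect_equal(pm$mean, 28.25)
  expect_equal(round(pm$sd, 2), 2.36)
  expect_equal(pm$mode, 30L)

  cme <- group_summary(c(17, 5, 7, 15, 10))
  expect_equal(cme$mean, 10.8)
  expect_equal(round(cme$sd, 2), 5.12)

  single <- group_summary(20L)
  expect_equal(single$mean, 20)
  expect_true(is.na(single$sd))
  expect_equal(single$n, 1L)

  # mode ties break towards the smallest length
  expect_equal(group_summary(c(10, 10, 12, 12))$mode, 10L)

  expect_error(group_summary(integer(0)), "empty")
  expect_error(group_summary(c(10.5, 12)), "integer")
})

test_that("length distributions are exact integer histograms", {
  d <- length_distribution(c(20, 21, 20, 23, 20))
  expect_equal(unname(d$counts[c("20", "21", "23")]), c(3L, 1L, 1L))
  expect_equal(sum(d$prob), 1)
  expect_equal(d$mode, 20L)
  expect_equal(d$n, 5L)
  set.seed(11)
  x <- sample(15:25, 40, replace = TRUE)
  d <- length_distribution(x)
  for (v in names(d$counts)) {
    expect_equal(unname(d$counts[v]), sum(x == as.integer(v)))
  }
})

test_that("welch_ttest matches the closed-form oracle and is antisymmetric", {
  set.seed(22)
  for (rep in 1:20) {
    x <- sample(10:30, sample(4:12, 1), replace = TRUE)
    y <- sample(10:30, sample(4:12, 1), replace = TRUE)
    if (var(x) == 0 || var(y) == 0) next
    got <- welch_ttest(x, y)
    orc <- oracle_welch(x, y)
    expect_equal(got$t, orc$t, tolerance = 1e-10)
    expect_equal(got$df, orc$df, tolerance = 1e-10)
    expect_equal(got$p, orc$p, tolerance = 1e-10)
    swapped <- welch_ttest(y, x)
    expect_equal(swapped$t, -got$t, tolerance = 1e-10)
    expect_equal(swapped$p, got$p, tolerance = 1e-10)
  }
  # degenerate constants
  deg <- welch_ttest(c(20, 20, 20), c(20, 20))
  expect_equal(c(deg$t, deg$p), c(0, 1))
  expect_equal(deg$flag, "degenerate")
  expect_error(welch_ttest(c(20, 20), c(21, 21)), "constant")
  expect_error(welch_ttest(5, c(1, 2)), "two observations")
})

test_that("zero-support trimming keeps the common lengths and renormalises", {
  tr <- trim_zero_support(c(10L, 11L, 12L), c(11L, 12L, 13L))
  expect_equal(tr$support, c(11L, 12L))
  expect_equal(unname(tr$p1), c(0.5, 0.5))
  expect_equal(unname(tr$p2), c(0.5, 0.5))
  expect_equal(sum(tr$p1), 1)
  expect_equal(sum(tr$p2), 1)
  expect_error(trim_zero_support(c(10L, 11L), c(20L, 21L)),
               "non-overlapping")
})

test_that("kldm reproduces hand-computed divergences and key properties", {
  # p = (.5,.5) vs q = (.9,.1) on a shared two-point support:
  # .5*log(.5/.9) + .5*log(.5/.1) = log(5/3) (by hand)
  x <- c(10L, 10L, 11L, 11L)           # (.5, .5)
  y <- c(rep(10L, 9), 11L)             # (.9, .1)
  expect_equal(kldm(x, y), log(5 / 3), tolerance = 1e-12)
  expect_equal(kldm(y, x), 0.9 * log(0.9 / 0.5) + 0.1 * log(0.1 / 0.5),
               tolerance = 1e-12)
  # asymmetry and the symmetric average
  expect_false(isTRUE(all.equal(kldm(x, y), kldm(y, x))))
  expect_equal(kldm_symmetric(x, y), (kldm(x, y) + kldm(y, x)) / 2,
               tolerance = 1e-12)
  expect_equal(kldm_symmetric(x, y), kldm_symmetric(y, x), tolerance = 1e-12)
  # identical distributions diverge by exactly zero
  expect_equal(kldm(x, x), 0)
  # base-2 logarithm rescales by log(2)
  expect_equal(kldm(x, y, log_base = 2), log(5 / 3) / log(2),
               tolerance = 1e-12)
  # trimming happens before the divergence: extra non-shared lengths change
  # the renormalised weights, matching the raw oracle
  set.seed(33)
  for (rep in 1:20) {
    a <- sample(15:22, 30, replace = TRUE)
    b <- sample(18:25, 30, replace = TRUE)
    expect_equal(kldm(a, b), oracle_kldm_raw(a, b), tolerance = 1e-12)
    expect_gte(kldm(a, b), -1e-12)
  }
})

test_that("rms_pm_difference computes both variants against a direct loop", {
  pm <- data.frame(species = c("s1", "s1", "s2"), length = c(30, 28, 25))
  org <- data.frame(species = c("s1", "s2", "s2"), length = c(20, 21, 19))
  diffs <- c(20 - 29, 21 - 25, 19 - 25)
  expect_equal(rms_pm_difference(org, pm), sqrt(mean(diffs^2)))
  expect_equal(rms_pm_difference(org, pm, variant = "sum"),
               sqrt(sum(diffs^2)))
  bad <- data.frame(species = "s3", length = 20)
  expect_error(rms_pm_difference(bad, pm), "s3")
})

test_that("compare_groups assembles summaries, Welch test, and KLDM", {
  viral <- viral_tmd_lengths()
  pm <- viral$tmd_length[viral$group == "PM"]
  cme <- viral$tmd_length[viral$group == "CME"]
  cmp <- compare_groups(pm, cme, labels = c("PM", "CME"))
  expect_equal(cmp$groups$PM$mean, 28.25)
  expect_equal(cmp$groups$CME$mean, 10.8)
  expect_equal(cmp$t_stat, welch_ttest(pm, cme)$t)
  expect_lt(cmp$p_value, 0.01)
  # PM {25,28,30} and CME {5,7,10,15,17} share no lengths
  expect_true(is.na(cmp$kldm_sym))
  expect_match(cmp$flag, "non-overlapping")
  expect_length(cmp$trimmed_support, 0L)

  # overlapping groups get finite divergences
  cmp2 <- compare_groups(c(19, 20, 20, 21), c(20, 20, 21, 22),
                         labels = c("a", "b"))
  expect_equal(cmp2$kldm_sym, (cmp2$kldm_xy + cmp2$kldm_yx) / 2)
  expect_gte(cmp2$kldm_xy, 0)
  expect_output(print(cmp2), "Welch t")
})

test_that("hydropathy profiles of one record reproduce its own profile", {
  ges <- get_scale("GES")
  sim <- generate_group(1, 20, 0, seed = 41, group = "one")
  tab <- detect_tmds(sim$records)
  prof <- mean_hydropathy_profile(tab, window = 1)
  direct <- windowed_profile(tab$oriented_context[1], ges, 1)$score
  expect_equal(prof$mean_score, direct, tolerance = 1e-12)
  expect_true(all(prof$coverage == 1L))
})

test_that("profiles of identical records equal the single-record profile", {
  recs <- protein_records(paste0("r", 1:4),
                          rep(paste0(strrep("D", 10), strrep("L", 20),
                                     strrep("D", 10)), 4),
                          topology = "N_CYTO")
  tab <- detect_tmds(recs)
  prof <- mean_hydropathy_profile(tab)
  one <- mean_hydropathy_profile(tab[1, , drop = FALSE])
  expect_equal(prof$mean_score, one$mean_score, tolerance = 1e-12)
  expect_true(all(prof$coverage == 4L))
})

test_that("heterogeneous profiles equal the coverage-weighted loop oracle", {
  ges <- get_scale("GES")
  sim <- generate_group(12, 20, 3, seed = 42, group = "het")
  tab <- detect_tmds(sim$records)
  prof <- mean_hydropathy_profile(tab, window = 1)
  seqs <- tab$oriented_context
  maxp <- max(nchar(seqs))
  for (p in c(1L, 5L, maxp)) {
    covering <- seqs[nchar(seqs) >= p]
    vals <- vapply(covering, function(s) ges$values[[substr(s, p, p)]], 0)
    expect_equal(prof$mean_score[p], mean(vals), tolerance = 1e-12)
    expect_equal(prof$coverage[p], length(covering))
  }
})

test_that("the profile mode length reads the dominant planted length", {
  # 22-residue homogeneous set: crossing exactly at 22
  recs <- protein_records(paste0("h", 1:3),
                          rep(paste0(strrep("D", 10), strrep("L", 22),
                                     strrep("D", 10)), 3),
                          topology = "N_CYTO")
  prof <- mean_hydropathy_profile(detect_tmds(recs))
  expect_equal(profile_mode_length(prof), 22L)

  # dominant length 20 with symmetric outliers at 15 and 25:
  # the mode reading tracks the dominant sub-population, not the mean
  mk <- function(L, k) paste0(strrep("D", 12), strrep("L", L), strrep("D", 12))
  seqs <- c(rep(mk(20), 12), rep(mk(15), 2), rep(mk(25), 2))
  recs <- protein_records(sprintf("m%02d", seq_along(seqs)), seqs,
                          topology = "N_CYTO")
  prof <- mean_hydropathy_profile(detect_tmds(recs))
  expect_equal(profile_mode_length(prof), 20L)

  # an all-negative profile has no crossing
  flat <- structure(data.frame(position = 1:5, mean_score = rep(-1, 5),
                               coverage = 1L),
                    class = c("tmd_profile", "data.frame"))
  expect_equal(profile_mode_length(flat), 0L)
})

test_that("abundance profiles are per-position frequencies summing to one", {
  sim <- generate_group(8, 18, 2, seed = 43, group = "ab")
  tab <- detect_tmds(sim$records)
  ab <- abundance_profile(tab)
  expect_equal(dim(ab$freq), c(max(nchar(tab$oriented_sequence)), 21L))
  expect_equal(unname(rowSums(ab$freq)), rep(1, nrow(ab$freq)),
               tolerance = 1e-12)
  expect_true(all(ab$hydrophobic >= 0 & ab$hydrophobic <= 1))
  # planted cores use a purely hydrophobic alphabet
  expect_true(all(ab$hydrophobic[seq_len(min(nchar(tab$oriented_sequence)))]
                  == 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(ab, path)
  out <- utils::read.delim(path, check.names = FALSE)
  expect_equal(nrow(out), nrow(ab$freq))
  expect_true(all(c("position", "hydrophobic", "coverage") %in% names(out)))
})
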