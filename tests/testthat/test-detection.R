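ges <- get_scale("GES")

test_that("rough_scan finds the most hydrophobic window deterministically", {
  s <- paste0(strrep("D", 10), strrep("L", 18), strrep("D", 10))
  core <- rough_scan(s, ges)
  expect_equal(core$core_start, 11L)
  expect_equal(core$core_end, 28L)
  # single possible window
  core18 <- rough_scan(strrep("A", 18), ges)
  expect_equal(c(core18$core_start, core18$core_end), c(1L, 18L))
  expect_error(rough_scan("LLL", ges), "shorter")
  # seeded random sequences vs exhaustive argmax
  set.seed(202)
  for (rep in 1:25) {
    s <- random_seq(80)
    scores <- unname(ges$values[strsplit(s, "")[[1]]])
    expect_equal(rough_scan(s, ges)$core_start,
                 oracle_best_window(scores, 18L))
  }
})

test_that("attach_flanks extends up to 8 residues, truncating at the ends", {
  f <- attach_flanks(list(core_start = 11L, core_end = 28L), strrep("A", 38))
  expect_equal(c(f$cand_start, f$cand_end, f$flank_left, f$flank_right),
               c(3L, 36L, 8L, 8L))
  f <- attach_flanks(list(core_start = 1L, core_end = 18L), strrep("A", 30))
  expect_equal(c(f$cand_start, f$cand_end, f$flank_left, f$flank_right),
               c(1L, 26L, 0L, 8L))
  f <- attach_flanks(list(core_start = 11L, core_end = 28L), strrep("A", 30))
  expect_equal(c(f$cand_start, f$cand_end, f$flank_left, f$flank_right),
               c(3L, 30L, 8L, 2L))
})

test_that("edge refinement applies the chop, expansion and burial rules", {
  # charged flanks are never added; hydrophobic core kept whole
  s <- paste0(strrep("D", 8), strrep("L", 18), strrep("D", 8))
  span <- refine_edges(attach_flanks(rough_scan(s, ges), s), s, ges)
  expect_equal(c(span$start, span$end, span$length), c(9L, 26L, 18L))

  # terminal hydrophilic at the core edge is chopped
  cand <- list(core_start = 9L, core_end = 26L, cand_start = 1L,
               cand_end = 30L, flank_left = 8L, flank_right = 4L)
  s <- paste0(strrep("D", 8), strrep("L", 17), "D", strrep("D", 4))
  span <- refine_edges(cand, s, ges)
  expect_equal(span$length, 17L)
  expect_equal(c(span$start, span$end), c(9L, 25L))

  # hydrophobic flank residues are taken up by expansion
  s <- paste0("DDDDDLLL", strrep("L", 18), strrep("D", 8))
  cand <- list(core_start = 9L, core_end = 26L, cand_start = 1L,
               cand_end = 34L, flank_left = 8L, flank_right = 8L)
  span <- refine_edges(cand, s, ges)
  expect_equal(span$length, 21L)
  expect_equal(span$start, 6L)

  # candidate without a single hydrophobic residue -> no TMD, not an error
  s <- strrep("D", 30)
  span <- refine_edges(attach_flanks(rough_scan(s, ges), s), s, ges)
  expect_true(span$no_tmd)
  expect_true(is.na(span$length))
})

test_that("the bundled edge-case suite refines to its expected spans", {
  ec <- edge_case_suite()
  tab <- detect_tmds(ec$records)
  got <- as.data.frame(tab)[match(ec$expected$id, tab$id),
                            c("start", "end", "length")]
  expect_equal(got$start, ec$expected$exp_start)
  expect_equal(got$end, ec$expected$exp_end)
  expect_equal(got$length, ec$expected$exp_length)
})

test_that("orientation anchors position 1 at the cytosolic end", {
  s <- paste0(strrep("D", 10), "LIV", strrep("D", 10))
  span <- list(start = 11L, end = 13L, length = 3L, no_tmd = FALSE)
  expect_equal(orient_span(span, s, "N_CYTO")$oriented_sequence, "LIV")
  expect_equal(orient_span(span, s, "C_CYTO")$oriented_sequence, "VIL")
  # context runs from the cytosolic end towards the exoplasmic side
  expect_equal(substr(orient_span(span, s, "C_CYTO")$oriented_context, 1, 3),
               "VIL")
  expect_error(orient_span(span, s, "UNKNOWN"), "UNKNOWN")
})

test_that("detect composes the stages and recovers planted spans exactly", {
  rec <- protein_records("p", strrep("L", 18), topology = "N_CYTO")
  tab <- detect_tmds(rec)
  expect_equal(c(tab$start, tab$end, tab$length), c(1L, 18L, 18L))

  p <- plant_tmd(23, 12, seed = 9)
  d <- detect_tmd(p$sequence, "N_CYTO")
  expect_equal(c(d$start, d$end, d$length),
               c(p$truth$true_start, p$truth$true_end, 23L))

  # determinism: identical inputs give identical spans
  d2 <- detect_tmd(p$sequence, "N_CYTO")
  expect_identical(d, d2)

  # unknown topology: strict error naming the id, lenient skip with warning
  recs <- protein_records(c("a", "b"), c(p$sequence, p$sequence),
                          topology = c("N_CYTO", "UNKNOWN"))
  expect_error(detect_tmds(recs), "b")
  expect_warning(tab <- detect_tmds(recs, lenient = TRUE), "1 record")
  expect_equal(tab$flags, c("", "unknown_topology"))
})

test_that("refined spans honour the bounds and terminal-residue contracts", {
  sim <- generate_group(60, length_mean = 20, length_sd = 5, seed = 314,
                        group = "prop")
  tab <- detect_tmds(sim$records)
  expect_true(all(tab$flags == ""))
  expect_true(all(tab$length >= 1 & tab$length <= 34))
  expect_true(all(tab$length <= 18 + tab$flank_left + tab$flank_right))
  cand_len <- tab$cand_end - tab$cand_start + 1L
  expect_true(all(cand_len >= 18 & cand_len <= 34))
  # 26-residue minimum candidate whenever >= 8 residues exist on a side
  expect_true(all(cand_len[tab$flank_left == 8 | tab$flank_right == 8] >= 26))

  # every terminal residue is hydrophobic (or buried-uncharged-hydrophilic)
  first <- substr(tab$oriented_sequence, 1, 1)
  last <- substr(tab$oriented_sequence, nchar(tab$oriented_sequence),
                 nchar(tab$oriented_sequence))
  expect_true(all(is_hydrophobic(ges, first)))
  expect_true(all(is_hydrophobic(ges, last)))

  # fixed point: refining the refined span with no flank budget is a no-op
  for (i in seq_len(10)) {
    s <- sim$records$sequence[i]
    cand0 <- list(core_start = tab$start[i], core_end = tab$end[i],
                  cand_start = tab$start[i], cand_end = tab$end[i],
                  flank_left = 0L, flank_right = 0L)
    again <- refine_edges(cand0, s, ges)
    expect_equal(c(again$start, again$end), c(tab$start[i], tab$end[i]))
  }
})

test_that("planted spans up to the candidate reach are recovered exactly", {
  # lengths <= 26 are always within reach of the 18-window plus one 8-flank
  set.seed(55)
  for (L in seq(10L, 26L, by = 2L)) {
    for (rep in 1:5) {
      p <- plant_tmd(L, 12, seed = 1000L * L + rep)
      d <- detect_tmd(p$sequence, "N_CYTO")
      expect_equal(c(d$start, d$end), c(p$truth$true_start, p$truth$true_end))
    }
  }
})

test_that("TMD tables round-trip through the canonical TSV format", {
  sim <- generate_group(6, 22, 2, seed = 8, group = "io")
  tab <- detect_tmds(sim$records)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tmd_table(tab, path)
  header <- readLines(path, n = 1L)
  expect_equal(header, paste(c("id", "group", "start", "end", "length",
                               "oriented_sequence", "scale", "flags"),
                             collapse = "\t"))
  back <- read_tmd_table(path)
  expect_equal(back$id, tab$id)
  expect_equal(back$length, tab$length)
  expect_equal(back$oriented_sequence, tab$oriented_sequence)
})
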