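test_that("nxx follows the cumulative-sum rule", {
  expect_equal(nxx(c(1, 2, 3, 4, 1000)), 1000)
  expect_equal(nxx(c(500)), 500)
  expect_equal(nxx(rep(7, 13)), 7)
  expect_error(nxx(numeric(0)), "undefined")
  # property: agrees with a candidate-scan oracle on random sets
  set.seed(9)
  for (rep in 1:50) {
    lens <- sample(1:10000, sample(1:40, 1), replace = TRUE)
    frac <- runif(1, 0.1, 0.9)
    total <- sum(lens)
    cands <- sort(unique(lens), decreasing = TRUE)
    oracle <- max(cands[vapply(cands, function(L)
      sum(lens[lens >= L]) >= frac * total, TRUE)])
    expect_equal(nxx(lens, frac), oracle)
  }
})

test_that("assembly_stats reproduces a hand-built layout", {
  lay <- two_contig_layout(600000, 400000, gap = 100)
  st <- assembly_stats(lay)
  expect_equal(st$n_scaffolds, 1)
  expect_equal(st$total_scaffold_length, 1000100)
  expect_equal(st$n_gaps, 1)
  expect_equal(st$gap_size, 100)
  expect_equal(st$contigs_in_scaffolds, 2)
  expect_equal(st$scaffold_n50, 1000100)
  expect_equal(st$total_assembly_length, 1000100)
  expect_equal(st$remaining_contigs, 0)
})

test_that("assembly_stats conserves totals and matches an AGP recount", {
  cfg <- small_config(seed = 3)
  ds <- simulate_dataset(cfg, reads = FALSE)
  lay <- ds$truth$observed_layout
  st <- assembly_stats(lay)
  # independent recount via the written AGP file
  f <- tempfile(fileext = ".agp")
  write_agp(lay, f)
  lines <- readLines(f)
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t")
  obj <- vapply(fields, `[`, "", 1)
  typ <- vapply(fields, `[`, "", 5)
  ends <- as.numeric(vapply(fields, `[`, "", 3))
  scaf_len <- tapply(ends, obj, max)
  expect_equal(st$total_scaffold_length + st$remaining_total_length,
               st$total_assembly_length)
  expect_equal(sort(as.numeric(scaf_len)),
               sort(c(as.numeric(scaffold_lengths(lay)), lay$unplaced$length)))
  expect_equal(st$n_gaps, sum(typ %in% c("N", "U")))
  expect_equal(st$gap_size,
               sum(as.numeric(vapply(fields, `[`, "", 6)[typ %in% c("N", "U")])))
})

test_that("degenerate layout with only unplaced contigs reports NA scaffold fields", {
  lay <- scaffold_layout(
    tibble::tibble(scaffold = character(0), part = integer(0),
                   start = numeric(0), end = numeric(0), type = character(0),
                   comp_id = character(0), comp_beg = numeric(0),
                   comp_end = numeric(0), orientation = character(0),
                   gap_length = numeric(0), gap_source = character(0)),
    tibble::tibble(comp_id = c("a", "b", "c"), length = c(100, 250, 75)))
  st <- assembly_stats(lay)
  expect_equal(st$n_scaffolds, 0)
  expect_true(is.na(st$scaffold_n50))
  expect_equal(st$remaining_contigs, 3)
  expect_equal(st$remaining_total_length, 425)
  expect_equal(st$remaining_n50, 250)
})

test_that("percentage_summary reproduces published worked examples", {
  expect_equal(percentage_summary(50, 62, "nearest"), 81)
  expect_equal(percentage_summary(12, 62, "nearest"), 19)
  expect_equal(percentage_summary(21, 48, "floor"), 43)
  expect_equal(percentage_summary(24, 29, "floor"), 82)
  expect_equal(percentage_summary(21, 29, "floor"), 72)
  expect_equal(percentage_summary(5, 6, "floor"), 83)
  expect_error(percentage_summary(1, 0), "denominator")
  # floor <= nearest <= floor + 1, both in [0, 100]
  set.seed(5)
  for (rep in 1:50) {
    d <- sample(1:200, 1); n <- sample(0:d, 1)
    fl <- percentage_summary(n, d, "floor")
    ne <- percentage_summary(n, d, "nearest")
    expect_gte(fl, 0); expect_lte(ne, 100)
    expect_gte(ne, fl); expect_lte(ne, fl + 1)
  }
})

test_that("error_rate_by_contig_length bins and percentages match a recount", {
  cfg <- small_config(seed = 11)
  ds <- simulate_dataset(cfg, reads = FALSE)
  lay <- ds$truth$observed_layout
  w <- lay$components[lay$components$type == "W", ]
  lens <- stats::setNames(w$comp_end - w$comp_beg, w$comp_id)
  set.seed(1)
  involved <- sample(names(lens), 4)
  tab <- error_rate_by_contig_length(lay, involved, bin_width = 50000)
  expect_equal(sum(tab$n_contigs), length(lens))
  expect_equal(sum(tab$n_involved), 4)
  for (i in seq_len(nrow(tab))) {
    ids <- names(lens)[lens >= tab$bin_start[i] & lens < tab$bin_end[i]]
    expect_equal(tab$n_contigs[i], length(ids))
    expect_equal(tab$n_involved[i], sum(ids %in% involved))
    if (length(ids) > 0)
      expect_equal(tab$percentage[i],
                   floor(100 * sum(ids %in% involved) / length(ids)))
    else expect_true(is.na(tab$percentage[i]))
  }
  # five involved in a bin of six -> 83
  lay6 <- scaffold_layout(
    tibble::tibble(scaffold = "s", part = 1:11,
                   start = c(0, cumsum(rep(c(60000, 100), 5))[1:10]),
                   end = cumsum(rep(c(60000, 100), 6))[1:11],
                   type = rep(c("W", "N"), 6)[1:11],
                   comp_id = ifelse(rep(c(TRUE, FALSE), 6)[1:11],
                                    paste0("k", 1:11), NA),
                   comp_beg = ifelse(rep(c(TRUE, FALSE), 6)[1:11], 0, NA),
                   comp_end = ifelse(rep(c(TRUE, FALSE), 6)[1:11], 60000, NA),
                   orientation = ifelse(rep(c(TRUE, FALSE), 6)[1:11], "+", NA),
                   gap_length = ifelse(rep(c(TRUE, FALSE), 6)[1:11], NA, 100),
                   gap_source = ifelse(rep(c(TRUE, FALSE), 6)[1:11], NA, "HIC")))
  tab6 <- error_rate_by_contig_length(lay6, paste0("k", c(1, 3, 5, 7, 9)),
                                      bin_width = 50000)
  b <- tab6[tab6$bin_start == 50000, ]
  expect_equal(b$n_contigs, 6)
  expect_equal(b$percentage, 83)
})

test_that("compare_runs reports deltas and fold changes", {
  lay <- two_contig_layout()
  st <- assembly_stats(lay)
  cmp0 <- compare_runs(st, st)
  expect_true(all(cmp0$delta == 0, na.rm = TRUE))
  expect_true(all(cmp0$fold[!is.na(cmp0$fold)] == 1))
  # an order-of-magnitude N50 drop shows as fold ~ 0.094
  before <- st; after <- st
  before$scaffold_n50 <- 38440066
  after$scaffold_n50 <- 3604007
  cmp <- compare_runs(before, after)
  fold <- cmp$fold[cmp$field == "scaffold_n50"]
  expect_equal(round(fold, 3), 0.094)
})
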