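bp_row <- function(scaffold, position, channel, query = "q1", side = "right") {
  tibble::tibble(scaffold = scaffold, position = position, channel = channel,
                 query_id = query, side = side, score = 50)
}

test_that("breakpoints cluster by single linkage within the merge window", {
  bp <- rbind(bp_row("s1", 100000, "BSPQI"), bp_row("s1", 110000, "BSSSI"))
  cf <- merge_channels(bp, merge_window = 50000)
  expect_equal(nrow(cf), 1)
  expect_equal(cf$channels, "BSPQI,BSSSI")
  expect_true(cf$dual_channel)
  expect_equal(cf$position, 105000)
  # far apart: two conflicts
  bp2 <- rbind(bp_row("s1", 100000, "BSPQI"), bp_row("s1", 500000, "BSPQI"))
  expect_equal(nrow(merge_channels(bp2, 50000)), 2)
  # different scaffolds never merge
  bp3 <- rbind(bp_row("s1", 100000, "BSPQI"), bp_row("s2", 100000, "BSSSI"))
  expect_equal(nrow(merge_channels(bp3, 50000)), 2)
  # min_channels = 2 drops single-channel clusters
  cf3 <- merge_channels(bp3, 50000, min_channels = 2)
  expect_equal(nrow(cf3), 0)
})

test_that("cluster count equals brute-force single linkage on random sets", {
  set.seed(19)
  for (rep in 1:30) {
    n <- sample(2:40, 1)
    pos <- sort(sample(1:3e6, n))
    w <- sample(c(10000, 50000, 200000), 1)
    bp <- do.call(rbind, lapply(pos, function(p)
      bp_row("s1", p, sample(c("BSPQI", "BSSSI"), 1))))
    got <- nrow(merge_channels(bp, w))
    # brute force: grow clusters while any pair within w links them
    adj <- abs(outer(pos, pos, "-")) <= w
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(got, igraph::components(g)$no)
  }
})

test_that("implied gap size is exact in the zero-noise limit", {
  # scaffold: contig (600 kb) + declared 100 bp gap + contig (400 kb);
  # true physical gap is 20 kb. Labels every 10 kb on each contig.
  true_gap <- 20000
  lab1 <- seq(10000, 590000, by = 10000)
  lab2 <- seq(10000, 390000, by = 10000)
  ref <- label_map("s1", 1000100, "E", c(lab1, 600100 + lab2))
  qry <- label_map("q", 1020000, "E", c(lab1, 600000 + true_gap + lab2))
  gaps <- tibble::tibble(scaffold = "s1", gap_index = 1L, start = 600000,
                         end = 600100, declared_length = 100, source = "HIC")
  p <- align_params(min_score = 10)
  aln <- align_maps(qry, ref, p, ref_gaps = gaps)
  expect_length(aln, 1)
  implied <- estimate_gap_size(aln[[1]], gaps[1, ], qry, ref)
  expect_equal(implied, true_gap)
  # declared equal to truth: implied equals declared
  qry2 <- label_map("q2", 1000200, "E", c(lab1, 600100 + lab2))
  aln2 <- align_maps(qry2, ref, p, ref_gaps = gaps)
  expect_equal(estimate_gap_size(aln2[[1]], gaps[1, ], qry2, ref), 100)
})

test_that("classification separates structural, gap-size and internal conflicts", {
  gaps <- tibble::tibble(scaffold = "s1", gap_index = 1L, start = 600000,
                         end = 600100, declared_length = 100, source = "HIC")
  # conflict 10 kb from the gap, no spanning alignment -> structural
  cf <- tibble::tibble(scaffold = "s1", position = 590000, channels = "BSPQI",
                       n_channels = 1L, n_breakpoints = 1L, dual_channel = FALSE)
  out <- classify_conflicts(cf, gaps, list(), list(), list(),
                            near_distance = 50000)
  expect_equal(out$classification, "NEAR_GAP_STRUCTURAL")
  expect_equal(out$nearest_gap_distance, 10000)
  # conflict 300 kb from any gap -> internal
  cf2 <- cf; cf2$position <- 300000
  out2 <- classify_conflicts(cf2, gaps, list(), list(), list())
  expect_equal(out2$classification, "INTERNAL")
  # spanning alignments with implied 20 kb vs declared 100 -> gap size only
  true_gap <- 20000
  lab1 <- seq(550000, 595000, by = 9000)
  lab2 <- seq(5000, 50000, by = 9000)
  ref <- label_map("s1", 1000100, "E", c(lab1, 600100 + lab2))
  qry <- label_map("qA", 1020100, "E", c(lab1, 600000 + true_gap + lab2))
  qryB <- label_map("qB", 1020100, "E", c(lab1, 600000 + true_gap + lab2))
  p <- align_params(min_score = 10, min_matched_labels = 6)
  aln <- c(align_maps(qry, ref, p, ref_gaps = gaps),
           align_maps(qryB, ref, p, ref_gaps = gaps))
  expect_length(aln, 2)
  cf3 <- cf; cf3$position <- 598000
  out3 <- classify_conflicts(cf3, gaps, aln,
                             list(`qA|E` = qry, `qB|E` = qryB),
                             list(`s1|E` = ref),
                             near_distance = 50000, gap_tol = 10000)
  expect_equal(out3$classification, "GAP_SIZE_ONLY")
  expect_equal(out3$implied_gap, 20000)
})

test_that("cutting splits scaffolds at gaps and conserves contig bases", {
  lay <- two_contig_layout(600000, 400000, gap = 100)
  # no conflicts: identity
  no_cf <- tibble::tibble(scaffold = character(0), position = numeric(0),
                          classification = character(0))
  expect_equal(cut_at_conflicts(lay, no_cf)$components, lay$components)
  # one structural conflict near the gap: two single-contig scaffolds
  cf <- tibble::tibble(scaffold = "s1", position = 590000,
                       classification = "NEAR_GAP_STRUCTURAL")
  cut <- cut_at_conflicts(lay, cf)
  expect_equal(length(unique(cut$components$scaffold)), 2)
  expect_equal(sum(cut$components$type != "W"), 0)
  expect_equal(placed_contig_bases(cut), placed_contig_bases(lay))
  st_before <- assembly_stats(lay); st_after <- assembly_stats(cut)
  expect_lte(st_after$scaffold_n50, st_before$scaffold_n50)
  expect_gte(st_after$n_scaffolds, st_before$n_scaffolds)
  # an INTERNAL conflict splits the containing contig
  cf2 <- tibble::tibble(scaffold = "s1", position = 300000,
                        classification = "INTERNAL")
  cut2 <- cut_at_conflicts(lay, cf2, classes_to_cut = "INTERNAL")
  expect_equal(length(unique(cut2$components$scaffold)), 2)
  expect_equal(placed_contig_bases(cut2), placed_contig_bases(lay))
  w <- cut2$components[cut2$components$type == "W", ]
  expect_setequal(w$comp_id, c("c1.1", "c1.2", "c2"))
  # conflict coordinate outside any scaffold errors
  cf3 <- tibble::tibble(scaffold = "s1", position = 99e6,
                        classification = "NEAR_GAP_STRUCTURAL")
  expect_error(cut_at_conflicts(lay, cf3), "outside")
})

test_that("cutting a minus-strand contig keeps component coordinates consistent", {
  comp <- two_contig_layout()$components
  comp$orientation[1] <- "-"
  lay <- scaffold_layout(comp)
  cf <- tibble::tibble(scaffold = "s1", position = 200000,
                       classification = "INTERNAL")
  cut <- cut_at_conflicts(lay, cf, classes_to_cut = "INTERNAL")
  w <- cut$components[cut$components$type == "W", ]
  expect_equal(placed_contig_bases(cut), placed_contig_bases(lay))
  # pieces of c1 tile its original extent
  c1 <- w[startsWith(w$comp_id, "c1"), ]
  expect_setequal(c(c1$comp_beg, c1$comp_end), c(0, 400000, 400000, 600000))
})
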