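test_that("genome generation is seed-deterministic and well composed", {
  cfg <- small_config(seed = 1)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1), as.character(g2))
  expect_length(g1, 2)
  expect_equal(sum(Biostrings::width(g1)), 1e6, tolerance = 0.01)
  # base frequencies ~ uniform: binomial SD at n = 1e6 is ~0.0004, so 0.01
  # is a >3-sigma bound with huge margin
  freq <- colSums(Biostrings::alphabetFrequency(g1)[, c("A", "C", "G", "T")])
  expect_true(all(abs(freq / sum(freq) - 0.25) < 0.01))
  expect_error(sim_config(genome_length = 1e5, n_contigs = 10,
                          min_contig_length = 5e4),
               "min_contig_length")
})

test_that("fragmentation partitions chromosomes into contigs plus true gaps", {
  cfg <- small_config(seed = 2)
  g <- generate_genome(cfg)
  tr <- fragment_and_scaffold(g, cfg)
  tc <- tr$true_layout$components
  # contigs + true gaps tile each chromosome exactly
  for (chr in names(g)) {
    expect_equal(max(tc$end[tc$scaffold == chr]), length(g[[chr]]))
  }
  # contig sequences match their recorded coordinates
  w <- tc[tc$type == "W", ]
  for (i in sample(nrow(w), 4)) {
    expect_equal(as.character(tr$contigs[[w$comp_id[i]]]),
                 as.character(Biostrings::subseq(g[[w$scaffold[i]]],
                                                 w$start[i] + 1, w$end[i])))
  }
  # no misjoins: observed layout identical up to scaffold ids and gap sizes
  oc <- tr$observed_layout$components
  expect_equal(oc$comp_id[oc$type == "W"], tc$comp_id[tc$type == "W"])
  expect_equal(oc$orientation[oc$type == "W"], tc$orientation[tc$type == "W"])
  expect_true(all(oc$gap_length[oc$type != "W"] == cfg$hic_gap_fill))
  expect_true(all(oc$gap_source[oc$type != "W"] == "HIC"))
  expect_equal(nrow(tr$misjoin_records), 0)
  # conservation of contig bases between layouts
  expect_equal(placed_contig_bases(tr$true_layout),
               placed_contig_bases(tr$observed_layout))
})

test_that("requested misjoins are applied once each at distinct junctions", {
  cfg <- sim_config(seed = 7, genome_length = 5e6, n_contigs = 40,
                    misjoins = c(TRANSLOCATION = 4, INVERSION = 2, FUSION = 2))
  g <- generate_genome(cfg)
  tr <- fragment_and_scaffold(g, cfg)
  mj <- tr$misjoin_records
  expect_equal(nrow(mj), 8)
  expect_equal(sort(table(mj$type), decreasing = TRUE),
               sort(c(TRANSLOCATION = 4L, INVERSION = 2L, FUSION = 2L),
                    decreasing = TRUE), ignore_attr = TRUE)
  # all recorded junctions distinct
  expect_equal(nrow(unique(mj[, c("scaffold", "junction_index")])), 8)
  # every coordinate lies at a gap boundary of the observed layout
  gaps <- gap_records(tr$observed_layout, source = "HIC")
  expect_true(all(mj$position %in% gaps$start))
  # contig multiset conserved
  tc <- tr$true_layout$components
  oc <- tr$observed_layout$components
  expect_setequal(oc$comp_id[oc$type == "W"], tc$comp_id[tc$type == "W"])
  # recorded junctions are genuinely disrupted
  jt <- junction_truth(tr)
  key <- paste(jt$scaffold, jt$start)
  expect_true(all(!jt$intact[match(paste(mj$scaffold, mj$position), key)]))
})

test_that("a single inversion flips exactly one placement's orientation", {
  cfg <- small_config(seed = 5, misjoins = c(INVERSION = 1))
  g <- generate_genome(cfg)
  tr <- fragment_and_scaffold(g, cfg)
  tc <- tr$true_layout$components
  oc <- tr$observed_layout$components
  tw <- tc[tc$type == "W", ]; ow <- oc[oc$type == "W", ]
  expect_equal(ow$comp_id, tw$comp_id)   # order unchanged
  flipped <- ow$comp_id[ow$orientation != tw$orientation[match(ow$comp_id, tw$comp_id)]]
  expect_length(flipped, 1)
  expect_equal(tr$misjoin_records$right_comp, flipped)
})

test_that("too many requested misjoins raise a configuration error", {
  expect_error(sim_config(genome_length = 1e6, n_chromosomes = 2,
                          n_contigs = 10, min_contig_length = 6e4,
                          misjoins = c(TRANSLOCATION = 8)),
               "misjoin")
})

test_that("zero-noise label maps equal the in-silico digest", {
  cfg <- small_config(seed = 6, sizing_sd_coeff = 0, label_miss_rate = 0,
                      false_label_rate = 0)
  g <- generate_genome(cfg)
  e <- cfg$enzymes[[1]]
  m <- simulate_label_map(g[[1]], e, cfg, seed = 1)
  truth <- in_silico_digest(g[1], list(e), 1000)[[1]]
  expect_equal(m$positions, truth$positions)
  # full dropout: empty map
  cfg2 <- small_config(seed = 6, label_miss_rate = 1, false_label_rate = 0)
  m2 <- simulate_label_map(g[[1]], cfg2$enzymes[[1]], cfg2, seed = 1)
  expect_length(m2$positions, 0)
})

test_that("label retention matches the binomial dropout model", {
  cfg <- small_config(seed = 8, label_miss_rate = 0.1, false_label_rate = 0,
                      sizing_sd_coeff = 0)
  g <- generate_genome(cfg)
  e <- cfg$enzymes[[2]]
  n_true <- length(in_silico_digest(g[1], list(e), 1000)[[1]]$positions)
  kept <- vapply(1:200, function(s)
    length(simulate_label_map(g[[1]], e, cfg, seed = s)$positions), 0L)
  rate <- mean(kept) / n_true
  # binomial SE of the mean retained fraction over 200 maps
  se <- sqrt(0.1 * 0.9 / (n_true * 200))
  expect_lt(abs(rate - 0.9), max(3 * se, 0.02))
})

test_that("sizing noise perturbs intervals at the sqrt-length scale", {
  cfg <- small_config(seed = 12, label_miss_rate = 0, false_label_rate = 0)
  g <- generate_genome(cfg)
  e <- cfg$enzymes[[1]]
  truth <- in_silico_digest(g[1], list(e), 1000)[[1]]$positions
  devs <- unlist(lapply(1:50, function(s) {
    m <- simulate_label_map(g[[1]], e, cfg, seed = 1000 + s)
    (diff(m$positions) - diff(truth)) / (cfg$sizing_sd_coeff * sqrt(diff(truth) / 1000))
  }))
  # standardized interval errors ~ N(0,1)
  expect_lt(abs(mean(devs)), 0.05)
  expect_lt(abs(sd(devs) - 1), 0.1)
})

test_that("read alignments split at misjoins and span intact junctions", {
  cfg <- sim_config(seed = 9, genome_length = 2e6, n_chromosomes = 2,
                    n_contigs = 16, min_contig_length = 7e4,
                    misjoins = c(TRANSLOCATION = 2))
  ds <- simulate_dataset(cfg)
  jt <- junction_truth(ds$truth)
  reads <- ds$reads
  anchor <- cfg$min_anchor_read
  for (k in seq_len(nrow(jt))) {
    spans <- reads$tname == jt$scaffold[k] &
      reads$tstart <= jt$start[k] - anchor &
      reads$tend >= jt$end[k] + anchor
    if (!jt$intact[k]) {
      expect_equal(sum(spans), 0, info = paste("misjoined junction", k))
    }
  }
  # intact junctions collect many spanning reads at 30x with 15 kb reads
  intact_counts <- vapply(which(jt$intact), function(k)
    sum(reads$tname == jt$scaffold[k] &
          reads$tstart <= jt$start[k] - anchor &
          reads$tend >= jt$end[k] + anchor), 0L)
  expect_true(all(intact_counts >= 5))
  # a read fully inside one contig appears as exactly one record
  one_rec <- table(reads$qname)
  expect_gt(sum(one_rec == 1), 0.5 * length(one_rec))
  # record coordinates are valid
  expect_true(all(reads$tstart >= 0 & reads$tend <= reads$tlen))
  expect_true(all(reads$qstart >= 0 & reads$qend <= reads$qlen))
})

test_that("the full dataset writer emits byte-identical files for one seed", {
  cfg <- small_config(seed = 33, misjoins = c(INVERSION = 1))
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_true(all(c("genome.fasta", "contigs.fasta", "scaffolds.fasta",
                    "true_layout.agp", "observed_layout.agp",
                    "query_maps.cmap", "reads.paf", "misjoins.bed") %in%
                    list.files(d1)))
})
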