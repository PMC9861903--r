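# Shared fixture builders. All randomness is seeded locally so tests are
# order-independent.

small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, genome_length = 1e6, n_chromosomes = 2,
             n_contigs = 10, min_contig_length = 6e4, ...)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force motif scan: forward + reverse complement, 0-based starts
brute_force_sites <- function(seq, motif) {
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(motif, "")[[1]]), collapse = ""))
  hits <- integer(0)
  n <- nchar(seq)
  k <- nchar(motif)
  for (i in seq_len(n - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (w == motif || w == rc) hits <- c(hits, i - 1)
  }
  sort(unique(hits))
}

# exhaustive best monotone chain score, independent of the DP implementation:
# plain recursion over all extensions within the lookback bound
exhaustive_best_chain <- function(qpos, rpos, params) {
  nq <- length(qpos); nr <- length(rpos)
  lb <- params$lookback
  best_from <- function(i, j, run_max, s) {
    best <- s
    for (a in seq_len(min(lb, nq - i))) {
      for (b in seq_len(min(lb, nr - j))) {
        pen <- params$penalty_weight *
          interval_penalty(qpos[i + a] - qpos[i], rpos[j + b] - rpos[j],
                           params$sigma)
        step <- params$match_bonus - pen -
          (b - 1) * params$miss_penalty - (a - 1) * params$false_penalty
        s2 <- s + step
        if (max(run_max, s2) - s2 > params$max_drop) next
        best <- max(best, best_from(i + a, j + b, max(run_max, s2), s2))
      }
    }
    best
  }
  best <- 0
  for (i in seq_len(nq)) for (j in seq_len(nr)) {
    best <- max(best, best_from(i, j, 0, 0))
  }
  best
}

# two-contig scaffold with one gap, built directly (no simulator)
two_contig_layout <- function(len1 = 600000, len2 = 400000, gap = 100,
                              source = "HIC") {
  comp <- tibble::tibble(
    scaffold = "s1",
    part = 1:3,
    start = c(0, len1, len1 + gap),
    end = c(len1, len1 + gap, len1 + gap + len2),
    type = c("W", "N", "W"),
    comp_id = c("c1", NA, "c2"),
    comp_beg = c(0, NA, 0),
    comp_end = c(len1, NA, len2),
    orientation = c("+", NA, "+"),
    gap_length = c(NA, gap, NA),
    gap_source = c(NA, source, NA))
  scaffold_layout(comp)
}
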