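test_that("interval penalty follows the scaled squared-error form", {
  expect_equal(interval_penalty(5000, 5000, 123), 0)
  # (6000-5000)^2 / (400^2 * 5000/1000) = 1e6 / 8e5 = 1.25
  expect_equal(interval_penalty(6000, 5000, 400), 1.25)
  # symmetric in the sign of the difference
  expect_equal(interval_penalty(4000, 5000, 400), interval_penalty(6000, 5000, 400))
  # short reference intervals are floored at 1 kb
  expect_equal(interval_penalty(700, 500, 400), 200^2 / (400^2 * 1))
  # zero sigma forbids any mismatch
  expect_equal(interval_penalty(5000, 5000, 0), 0)
  expect_equal(interval_penalty(5001, 5000, 0), Inf)
})

test_that("self-alignment recovers every label with the full match score", {
  pos <- c(0, cumsum(rep(c(8000, 9500, 7000), 5)))[-1]
  m <- label_map("m", max(pos) + 1000, "E", pos)
  p <- align_params(min_matched_labels = 5, min_score = 10)
  aln <- align_maps(m, m, p)
  expect_length(aln, 1)
  a <- aln[[1]]
  expect_equal(nrow(a$pairs), length(pos))
  expect_equal(a$score, (length(pos) - 1) * p$match_bonus)
  expect_equal(a$orientation, "+")
  expect_equal(c(a$query_left, a$query_right, a$ref_left, a$ref_right),
               c(0L, 0L, 0L, 0L))
})

test_that("a query label absent from the reference costs one skip penalty", {
  pos <- c(0, cumsum(rep(8000, 11)))[-1]
  m <- label_map("q", max(pos) + 1000, "E", pos)
  ref <- label_map("r", max(pos) + 1000, "E", pos[-6])
  p <- align_params(min_matched_labels = 5, min_score = 10)
  aln <- align_maps(m, ref, p)
  expect_length(aln, 1)
  # the skipped query label costs one false_penalty (query has one extra)
  expect_equal(aln[[1]]$score,
               (length(pos) - 2) * p$match_bonus - p$false_penalty)
  expect_equal(nrow(aln[[1]]$pairs), length(pos) - 1)
})

test_that("DP optimum equals exhaustive chain enumeration on small maps", {
  # unconstrained X-drop so the DP equals the classic local-alignment optimum
  p <- align_params(lookback = 5L, min_matched_labels = 2L, min_score = 0.5,
                    max_drop = 1e9)
  set.seed(123)
  for (rep in 1:40) {
    nq <- sample(4:6, 1); nr <- sample(4:6, 1)
    qpos <- sort(sample(1000:60000, nq))
    rpos <- sort(sample(1000:60000, nr))
    q <- label_map("q", 70000, "E", qpos)
    r <- label_map("r", 70000, "E", rpos)
    aln <- align_maps(q, r, p)
    got <- if (length(aln)) max(vapply(aln, `[[`, 0, "score")) else 0
    oracle <- max(exhaustive_best_chain(qpos, rpos, p),
                  exhaustive_best_chain(rev(70000 - qpos), rpos, p))
    if (oracle >= p$min_score) {
      expect_equal(got, oracle, tolerance = 1e-9, info = paste("rep", rep))
    } else {
      expect_length(aln, 0)
    }
  }
})

test_that("reversed query aligns with flipped orientation and equal score", {
  set.seed(4)
  pos <- sort(sample(1000:200000, 25))
  m <- label_map("q", 210000, "E", pos)
  rev_m <- label_map("qr", 210000, "E", sort(210000 - pos))
  ref <- label_map("r", 210000, "E", pos)
  p <- align_params(min_matched_labels = 5, min_score = 10)
  fwd <- align_maps(m, ref, p)
  bwd <- align_maps(rev_m, ref, p)
  expect_equal(fwd[[1]]$orientation, "+")
  expect_equal(bwd[[1]]$orientation, "-")
  expect_equal(fwd[[1]]$score, bwd[[1]]$score)
  expect_equal(nrow(fwd[[1]]$pairs), nrow(bwd[[1]]$pairs))
})

test_that("a query extending past a reference junction yields one breakpoint", {
  set.seed(8)
  # reference = maps of chromosome A then B concatenated; query = A's map
  # extending 20 labels past the junction into its true continuation
  ivA <- sample(2000:20000, 30, replace = TRUE)
  ivB <- sample(2000:20000, 30, replace = TRUE)
  posA <- cumsum(ivA)
  junction <- max(posA) + 5000
  posB <- junction + cumsum(ivB)
  ref <- label_map("scaf", max(posB) + 5000, "E", c(posA, posB))
  ivC <- sample(2000:20000, 20, replace = TRUE)
  qpos <- c(posA, max(posA) + cumsum(ivC))
  q <- label_map("q", max(qpos) + 5000, "E", qpos)
  p <- align_params(min_matched_labels = 5, min_score = 10)
  aln <- align_maps(q, ref, p)
  bp <- detect_breakpoints(aln, list(scaf = ref), p,
                           query_maps = list(q = q))
  expect_equal(nrow(bp), 1)
  expect_equal(bp$side, "right")
  # breakpoint at the last matched label, close to the junction
  expect_lte(abs(bp$position - max(posA)), 30000)
  # query map ending exactly at its last matched label emits nothing
  q2 <- label_map("q2", max(posA) + 3000, "E", posA)
  aln2 <- align_maps(q2, ref, p)
  bp2 <- detect_breakpoints(aln2, list(scaf = ref), p,
                            query_maps = list(q2 = q2))
  expect_equal(nrow(bp2), 0)
})

test_that("trailing_k larger than the remaining labels suppresses breakpoints", {
  set.seed(15)
  iv <- sample(6000:11000, 40, replace = TRUE)
  pos <- cumsum(iv)
  ref <- label_map("r", max(pos) + 5000, "E", pos)
  # query = first 30 labels plus 3 trailing unalignable labels
  qpos <- c(pos[1:30], pos[30] + c(40000, 47000, 52000))
  q <- label_map("q", max(qpos) + 60000, "E", qpos)
  p <- align_params(min_matched_labels = 5, min_score = 10, trailing_k = 5L)
  aln <- align_maps(q, ref, p)
  bp <- detect_breakpoints(aln, list(r = ref), p, query_maps = list(q = q),
                           end_guard = 0)
  expect_equal(nrow(bp), 0)   # only 3 < trailing_k labels remain on the query
})
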