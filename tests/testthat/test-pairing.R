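test_that("midpoints use the floor of the half-width from the start", {
  expect_equal(hit_midpoint(100L, 112L), 106L)  # length 12 -> offset 6
  expect_equal(hit_midpoint(0L, 1L), 0L)
  expect_equal(hit_midpoint(10L, 15L), 12L)     # odd length floors
})

test_that("pair distance is the absolute midpoint difference", {
  a <- list(seq_id = "s1", start = 100L, end = 112L)  # mid 106
  b <- list(seq_id = "s1", start = 115L, end = 127L)  # mid 121
  expect_equal(pair_distance(a, b), 15L)
  expect_equal(pair_distance(b, a), 15L)
  expect_equal(pair_distance(a, a), 0L)
  expect_error(pair_distance(a, list(seq_id = "s2", start = 0L, end = 2L)),
               "different sequences")
})

test_that("pairs obey the distance window", {
  in_range <- enumerate_pairs(make_hits(c("s1", "s1"), c("A", "B"),
                                        c(5, 15), c(15, 25)),
                              d_min = 5, d_max = 20)
  expect_equal(in_range$pooled$F, 1L)
  expect_equal(in_range$instances$distance, 10L)
  too_close <- enumerate_pairs(make_hits(c("s1", "s1"), c("A", "B"),
                                         c(5, 7), c(15, 17), strand = "+"),
                               d_min = 5, d_max = 20)
  expect_equal(nrow(too_close$pooled), 0L)
})

test_that("different-type overlaps are tolerated up to max_overlap", {
  # intervals [0,12) and [8,20): overlap 4, midpoint distance 8
  ok <- enumerate_pairs(make_hits(c("s1", "s1"), c("A", "B"),
                                  c(0, 8), c(12, 20)),
                        d_min = 5, d_max = 20, max_overlap = 4)
  expect_equal(nrow(ok$pooled), 1L)
  # overlap 5 is one too many
  bad <- enumerate_pairs(make_hits(c("s1", "s1"), c("A", "B"),
                                   c(0, 7), c(12, 19)),
                         d_min = 5, d_max = 20, max_overlap = 4)
  expect_equal(nrow(bad$pooled), 0L)
})

test_that("homotypic clusters are counted by greedy disjoint matching", {
  # four same-type sites at midpoints 10, 20, 30, 40: two pairs
  hits <- make_hits(rep("s1", 4), rep("A", 4),
                    start = c(8, 18, 28, 38), end = c(12, 22, 32, 42))
  counts <- enumerate_pairs(hits, d_min = 5, d_max = 20)
  expect_equal(counts$pooled$F, 2L)
  expect_equal(sort(counts$instances$distance), c(10L, 10L))
  expect_equal(counts$instances$start_a, c(8L, 28L))
})

test_that("a site can serve once per pair type but across several types", {
  # B at mid 20 can pair with A (mid 10) and with C (mid 30)
  hits <- make_hits(rep("s1", 3), c("A", "B", "C"),
                    start = c(8, 18, 28), end = c(12, 22, 32))
  counts <- enumerate_pairs(hits, d_min = 5, d_max = 20)
  expect_equal(nrow(counts$pooled), 3L)  # A-B, A-C (distance 20), B-C
  expect_true(all(counts$pooled$F == 1L))
})

test_that("counting is invariant to the order of the input hits", {
  set.seed(8)
  hits <- make_hits(
    sample(c("s1", "s2"), 40, replace = TRUE),
    sample(c("A", "B", "C"), 40, replace = TRUE),
    start = (st <- sample(seq(0, 480, by = 3), 40)),
    end = st + 10L
  )
  a <- enumerate_pairs(hits)
  b <- enumerate_pairs(hits[sample(nrow(hits)), ])
  expect_equal(a$pooled, b$pooled)
  expect_equal(a$per_sequence, b$per_sequence)
})

test_that("counted instances satisfy the constraints and use disjoint sites", {
  set.seed(13)
  hits <- make_hits(
    rep("s1", 50), sample(c("A", "B"), 50, replace = TRUE),
    start = (st <- sample(seq(0, 900, by = 2), 50)), end = st + 8L
  )
  hits <- suppressMessages(resolve_same_type_overlaps(
    hits, make_promoters(c(s1 = strrep("A", 1000)))))
  counts <- enumerate_pairs(hits, d_min = 5, d_max = 20, max_overlap = 4)
  inst <- counts$instances
  expect_true(all(inst$distance >= 5 & inst$distance <= 20))
  ov <- pmax(0, pmin(inst$end_a, inst$end_b) - pmax(inst$start_a, inst$start_b))
  expect_true(all(ov <= 4))
  expect_true(all(ov[inst$type_a == inst$type_b] == 0))
  # per pair type no site occurs in two counted instances
  for (pt in split(inst, paste(inst$type_a, inst$type_b))) {
    sites <- c(paste(pt$start_a, pt$end_a), paste(pt$start_b, pt$end_b))
    expect_false(anyDuplicated(sites) > 0)
  }
})

test_that("per-sequence totals and pooled counts are consistent", {
  counts <- micro_counts()
  expect_equal(sum(counts$n_s$n_pairs), sum(counts$pooled$F))
  expect_equal(counts$n_s$n_pairs[counts$n_s$seq_id == "s1"], 3L)
})
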