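test_that("pooled pair and slot-based marginal probabilities are correct", {
  counts <- make_pair_counts(tibble::tibble(
    seq_id = c("s1", "s1"), type_a = c("A", "A"),
    type_b = c("B", "C"), count = c(3L, 1L)))
  probs <- pair_probabilities(counts)
  expect_equal(probs$total, 4)
  expect_equal(probs$joint$p_joint[probs$joint$type_b == "B"], 0.75)
  m <- setNames(probs$marginal$p, probs$marginal$type)
  expect_equal(m[["A"]], 0.5)
  expect_equal(m[["B"]], 3 / 8)
  expect_equal(m[["C"]], 1 / 8)
  expect_equal(sum(m), 1)
})

test_that("homotypic pairs occupy both slots in the marginals", {
  counts <- make_pair_counts(tibble::tibble(
    seq_id = "s1", type_a = "A", type_b = "A", count = 1L))
  probs <- pair_probabilities(counts)
  expect_equal(probs$joint$p_joint, 1)
  expect_equal(probs$marginal$p, 1)
})

test_that("pair PMI matches hand-derived values", {
  counts <- make_pair_counts(tibble::tibble(
    seq_id = c("s1", "s1"), type_a = c("A", "A"),
    type_b = c("B", "C"), count = c(3L, 1L)))
  pmi <- pair_pmi(pair_probabilities(counts))
  expect_equal(pmi$pmi[pmi$type_b == "B"], 2)  # log2(.75/(.5*.375))
  expect_equal(pmi$pmi[pmi$type_b == "C"], 2)  # log2(.25/(.5*.125))
  # a single heterotypic pair type is forced to PMI 2 by normalization
  single <- make_pair_counts(tibble::tibble(
    seq_id = "s1", type_a = "A", type_b = "B", count = 1L))
  expect_equal(pair_pmi(pair_probabilities(single))$pmi, 2)
})

test_that("sequence weights are pair-count shares summing to one", {
  counts <- micro_counts()
  w <- sequence_weights(counts)
  expect_equal(w$w[w$seq_id == "s1"], 0.75)
  expect_equal(w$w[w$seq_id == "s2"], 0.25)
  expect_equal(sum(w$w), 1)
})

test_that("weighted cumulative PMI accumulates weights of carrying sequences", {
  counts <- micro_counts()
  probs <- pair_probabilities(counts)
  scored <- cumulative_weighted_pmi(counts, pair_pmi(probs),
                                    sequence_weights(counts))
  expect_equal(scored$pmi_pc[scored$type_b == "B"], 1.5)    # (0.75+0.25)*0.75*2
  expect_equal(scored$pmi_pc[scored$type_b == "C"], 0.375)  # 0.75*0.25*2
})

test_that("APC reproduces the worked micro example exactly", {
  scores <- score_pairs(micro_counts())
  get <- function(a, b, col) scores[[col]][scores$type_a == a & scores$type_b == b]
  expect_equal(get("A", "B", "apc"), 1.125)        # 0.9375*0.75/0.625
  expect_equal(get("A", "C", "apc"), 0.28125)
  expect_equal(get("B", "C", "apc"), 0.225)
  expect_equal(get("A", "B", "pmi_pc_apc"), 0.375)
  expect_equal(get("A", "C", "pmi_pc_apc"), 0.09375)
  expect_equal(get("B", "C", "pmi_pc_apc"), -0.225)
})

test_that("z-scores standardize over the pair-slot universe", {
  scores <- score_pairs(micro_counts())
  v <- c(0.375, 0.09375, -0.225)
  expect_equal(scores$zscore[scores$type_b == "B"],
               (0.375 - mean(v)) / sd(v), tolerance = 1e-12)
  expect_false(any(scores$significant))
})

test_that("two participating types force corrected scores to zero", {
  counts <- make_pair_counts(tibble::tibble(
    seq_id = c("s1", "s2"), type_a = "A", type_b = "B", count = c(2L, 1L)))
  probs <- pair_probabilities(counts)
  corrected <- apc_correct(cumulative_weighted_pmi(
    counts, pair_pmi(probs), sequence_weights(counts)))
  expect_equal(corrected$apc, corrected$pmi_pc)
  expect_equal(corrected$pmi_pc_apc, 0)
  # standardization needs at least two pair slots
  expect_error(pair_zscores(corrected), "at least 2 pair slots")
})

test_that("uniform pair structure yields zero corrected scores everywhere", {
  # every heterotypic pair of 4 types once in the same sequence
  cmb <- utils::combn(LETTERS[1:4], 2)
  counts <- make_pair_counts(tibble::tibble(
    seq_id = "s1", type_a = cmb[1, ], type_b = cmb[2, ], count = 1L))
  scores <- suppressMessages(score_pairs(counts))
  expect_equal(scores$pmi_pc_apc, rep(0, 6), tolerance = 1e-12)
  expect_false(any(scores$significant))
})

test_that("every per-pair quantity is symmetric in the pair order", {
  # scoring canonicalizes pairs; feeding swapped labels gives the same table
  per1 <- tibble::tibble(seq_id = c("s1", "s1", "s2"),
                         type_a = c("A", "A", "B"),
                         type_b = c("B", "C", "C"), count = c(2L, 1L, 3L))
  s1 <- score_pairs(make_pair_counts(per1))
  # relabel A<->C: canonical pairs change names but values must map over
  per2 <- per1
  per2$type_a <- chartr("AC", "CA", per1$type_a)
  per2$type_b <- chartr("AC", "CA", per1$type_b)
  swap <- tibble::tibble(type_a = pmin(per2$type_a, per2$type_b),
                         type_b = pmax(per2$type_a, per2$type_b),
                         seq_id = per2$seq_id, count = per2$count)
  s2 <- score_pairs(make_pair_counts(swap))
  relabel <- function(x) {
    a <- chartr("AC", "CA", x$type_a); b <- chartr("AC", "CA", x$type_b)
    x$type_a <- pmin(a, b); x$type_b <- pmax(a, b)
    dplyr::arrange(as.data.frame(x), type_a, type_b)
  }
  plain <- dplyr::arrange(as.data.frame(tidy(s1)), type_a, type_b)
  expect_equal(plain, relabel(tidy(s2)), tolerance = 1e-12)
})

test_that("shifting corrected scores leaves z-scores unchanged", {
  scores <- score_pairs(micro_counts())
  shifted <- dplyr::mutate(scores, pmi_pc_apc = pmi_pc_apc + 5)
  rez <- pair_zscores(shifted)
  expect_equal(sort(rez$zscore), sort(scores$zscore), tolerance = 1e-12)
})

test_that("degenerate inputs raise the documented errors", {
  empty <- make_pair_counts(tibble::tibble(
    seq_id = character(), type_a = character(),
    type_b = character(), count = integer()))
  expect_error(pair_probabilities(empty), "no pairs")
  expect_error(sequence_weights(empty), "no pairs")
  solo <- make_pair_counts(tibble::tibble(
    seq_id = "s1", type_a = "A", type_b = "A", count = 2L))
  expect_error(score_pairs(solo), "at least 2 TFBS types")
})

test_that("scoring agrees with the brute-force oracle on random instances", {
  for (seed in 1:30) {
    per_seq <- random_pair_table(seed)
    got <- as.data.frame(tidy(score_pairs(make_pair_counts(per_seq))))
    want <- oracle_pair_scores(per_seq)
    j <- merge(got, want, by = c("type_a", "type_b"), suffixes = c("", ".o"))
    expect_equal(nrow(j), nrow(want))
    expect_equal(j$F, j$F.o)
    expect_equal(j$p_joint, j$p_joint.o, tolerance = 1e-9)
    obs <- j$F > 0
    expect_equal(j$pmi[obs], j$pmi.o[obs], tolerance = 1e-9)
    expect_equal(j$pmi_pc, j$pmi_pc.o, tolerance = 1e-9)
    expect_equal(j$apc, j$apc.o, tolerance = 1e-9)
    expect_equal(j$pmi_pc_apc, j$pmi_pc_apc.o, tolerance = 1e-9)
    expect_equal(j$zscore, j$zscore.o, tolerance = 1e-9)
  }
})

test_that("joint probabilities and weights conserve mass", {
  per_seq <- random_pair_table(77)
  counts <- make_pair_counts(per_seq)
  probs <- pair_probabilities(counts)
  expect_equal(sum(probs$joint$p_joint), 1, tolerance = 1e-12)
  expect_equal(sum(probs$marginal$p), 1, tolerance = 1e-12)
  expect_equal(sum(sequence_weights(counts)$w), 1, tolerance = 1e-12)
})
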