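test_that("the simulator is deterministic under a fixed seed", {
  cfg <- spikein_config(n_sequences = 10, seed = 4)
  a <- simulate_spikein(cfg)
  b <- simulate_spikein(cfg)
  expect_identical(a$promoters, b$promoters)
  expect_identical(a$truth, b$truth)
  expect_identical(a$decoy_truth, b$decoy_truth)
  c <- simulate_spikein(spikein_config(n_sequences = 10, seed = 5))
  expect_false(identical(a$promoters$seq, c$promoters$seq))
})

test_that("background base composition matches the requested GC content", {
  cfg <- spikein_config(n_sequences = 100, seq_length = 1000,
                        gc_content = 0.5, seed = 2)
  bg <- generate_background(cfg)
  pooled <- paste(bg$seq, collapse = "")
  gc <- sum(strsplit(pooled, "")[[1]] %in% c("G", "C")) / nchar(pooled)
  expect_lt(abs(gc - 0.5), 0.01)
  expect_true(all(bg$tss_offset == 1000L))
  expect_equal(nrow(generate_background(spikein_config(n_sequences = 0))), 0L)
})

test_that("planted pairs respect the copy-number and gap ranges", {
  cfg <- spikein_config(n_sequences = 30, seed = 9)
  sim <- simulate_spikein(cfg)
  per_seq <- table(sim$truth$seq_id)
  expect_true(all(per_seq >= 2 & per_seq <= 12))
  expect_equal(length(per_seq), 30L)
  expect_true(all(sim$truth$gap >= 5 & sim$truth$gap <= 20))
  expect_true(all(sim$truth$start_b - sim$truth$end_a == sim$truth$gap))
})

test_that("the truth table reconstructs every planted motif exactly", {
  cfg <- spikein_config(n_sequences = 15, seed = 21)
  sim <- simulate_spikein(cfg)
  seqs <- setNames(sim$promoters$seq, sim$promoters$seq_id)
  a <- cfg$pair_motifs[[1]]; b <- cfg$pair_motifs[[2]]
  got_a <- substr(seqs[sim$truth$seq_id], sim$truth$start_a + 1, sim$truth$end_a)
  got_b <- substr(seqs[sim$truth$seq_id], sim$truth$start_b + 1, sim$truth$end_b)
  expect_true(all(got_a == a))
  expect_true(all(got_b == b))
  got_d <- substr(seqs[sim$decoy_truth$seq_id],
                  sim$decoy_truth$start + 1, sim$decoy_truth$end)
  expect_equal(unname(got_d),
               unname(cfg$decoy_motifs[sim$decoy_truth$matrix_id]))
})

test_that("planted insertions never overlap each other", {
  cfg <- spikein_config(n_sequences = 20, seed = 33)
  sim <- simulate_spikein(cfg)
  ivs <- rbind(
    data.frame(seq_id = sim$truth$seq_id, s = sim$truth$start_a,
               e = sim$truth$end_a),
    data.frame(seq_id = sim$truth$seq_id, s = sim$truth$start_b,
               e = sim$truth$end_b),
    data.frame(seq_id = sim$decoy_truth$seq_id, s = sim$decoy_truth$start,
               e = sim$decoy_truth$end)
  )
  for (g in split(ivs, ivs$seq_id)) {
    g <- g[order(g$s), ]
    expect_true(all(g$s[-1] >= g$e[-nrow(g)]))
  }
})

test_that("sequence length is preserved by planting", {
  cfg <- spikein_config(n_sequences = 10, seq_length = 800, seed = 12)
  sim <- simulate_spikein(cfg)
  expect_true(all(nchar(sim$promoters$seq) == 800L))
})

test_that("decoy planting honours the rate profile and a zero rate", {
  cfg0 <- spikein_config(n_sequences = 10, decoy_rate = 0, seed = 6)
  bg <- generate_background(cfg0)
  out <- plant_decoys(bg, cfg0)
  expect_identical(out$promoters$seq, bg$seq)
  expect_equal(nrow(out$truth), 0L)
  rates <- decoy_rates(spikein_config())
  expect_equal(mean(rates), 3)
  expect_gt(max(rates) / min(rates), 10)  # heavy-tailed abundance profile
  flat <- decoy_rates(spikein_config(decoy_spread = 0))
  expect_true(all(flat == 3))
})

test_that("decoy types are positionally uncoupled", {
  # correlation of per-sequence counts of two decoy types across seeds
  counts <- sapply(1:40, function(seed) {
    cfg <- spikein_config(n_sequences = 5, pair_motifs = NULL,
                          decoy_motifs = c(X = "TGACGTCA", Y = "GGGACTTTCC"),
                          decoy_rate = 3, decoy_spread = 0, seed = seed)
    sim <- simulate_spikein(cfg)
    table(factor(sim$decoy_truth$matrix_id, levels = c("X", "Y")),
          factor(sim$decoy_truth$seq_id, levels = sim$promoters$seq_id))
  })
  # each column flattens a 2 x 5 table column-major: odd rows X, even rows Y
  x <- as.vector(counts[seq(1, nrow(counts), 2), ])
  y <- as.vector(counts[seq(2, nrow(counts), 2), ])
  r <- cor(x, y)
  expect_lt(abs(r), 2.5 / sqrt(length(x)))  # within ~2.5 SE of zero
})
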