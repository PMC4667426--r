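# Independent straight-from-the-formulas oracles, written long-hand with
# base R loops so they share no code with the package implementation.

# Sequence-by-type PMI from a raw frequency matrix.
oracle_seq_pmi <- function(f) {
  total <- sum(f)
  stopifnot(total > 0)
  rows <- list()
  for (i in seq_len(nrow(f))) {
    for (j in seq_len(ncol(f))) {
      if (f[i, j] > 0) {
        p_st <- f[i, j] / total
        p_s <- sum(f[i, ]) / total
        p_t <- sum(f[, j]) / total
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = rownames(f)[i], matrix_id = colnames(f)[j],
          pmi = log2(p_st / (p_s * p_t)),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Full pair-scoring cascade from a per-sequence pair count data frame
# (seq_id, type_a <= type_b, count).  Returns one data.frame over the
# pair-slot universe with every per-pair quantity.
oracle_pair_scores <- function(per_seq, z_threshold = 3) {
  agg <- aggregate(count ~ type_a + type_b, data = per_seq, FUN = sum)
  total <- sum(agg$count)
  types <- sort(unique(c(agg$type_a, agg$type_b)))
  n <- length(types)
  stopifnot(n >= 2)

  F_of <- function(a, b) {
    lo <- min(a, b); hi <- max(a, b)
    r <- agg[agg$type_a == lo & agg$type_b == hi, "count"]
    if (length(r)) r else 0
  }
  p_joint <- function(a, b) F_of(a, b) / total
  marg <- sapply(types, function(a) {
    tot <- 0
    for (k in seq_len(nrow(agg))) {
      if (agg$type_a[k] == a) tot <- tot + agg$count[k]
      if (agg$type_b[k] == a) tot <- tot + agg$count[k]
    }
    tot / (2 * total)  # homotypic rows hit both branches: 2 F(a,a)
  })
  pmi <- function(a, b) log2(p_joint(a, b) / (marg[[a]] * marg[[b]]))

  n_s <- tapply(per_seq$count, per_seq$seq_id, sum)
  w <- n_s / sum(n_s)
  pmi_pc <- function(a, b) {
    if (F_of(a, b) == 0) return(0)
    lo <- min(a, b); hi <- max(a, b)
    in_s <- unique(per_seq$seq_id[per_seq$type_a == lo &
                                    per_seq$type_b == hi & per_seq$count > 0])
    sum(w[in_s]) * p_joint(a, b) * pmi(a, b)
  }

  mean_pc <- sapply(types, function(a) {
    others <- setdiff(types, a)
    sum(sapply(others, function(x) pmi_pc(a, x))) / (n - 1)
  })
  hetero <- utils::combn(types, 2)
  overall <- mean(apply(hetero, 2, function(p) pmi_pc(p[1], p[2])))

  slots <- data.frame(type_a = hetero[1, ], type_b = hetero[2, ],
                      stringsAsFactors = FALSE)
  homo <- agg[agg$type_a == agg$type_b, c("type_a", "type_b")]
  slots <- rbind(slots, homo)
  slots$F <- mapply(F_of, slots$type_a, slots$type_b)
  slots$p_joint <- slots$F / total
  slots$pmi <- ifelse(slots$F > 0,
                      mapply(pmi, slots$type_a, slots$type_b), NA_real_)
  slots$pmi_pc <- mapply(pmi_pc, slots$type_a, slots$type_b)
  slots$apc <- if (overall == 0) 0 else
    mean_pc[slots$type_a] * mean_pc[slots$type_b] / overall
  slots$pmi_pc_apc <- slots$pmi_pc - slots$apc
  mu <- mean(slots$pmi_pc_apc)
  s <- sd(slots$pmi_pc_apc)
  slots$zscore <- if (is.na(s) || s == 0) 0 else (slots$pmi_pc_apc - mu) / s
  slots$significant <- if (is.na(s) || s == 0) FALSE else
    slots$zscore >= z_threshold
  attr(slots, "marginal") <- marg
  attr(slots, "weights") <- w
  slots
}

# Deterministic random small instance for oracle-equivalence sweeps:
# m <= 5 sequences, n <= 6 types, <= 30 pair instances, at least two
# participating types.
random_pair_table <- function(seed) {
  set.seed(seed)
  repeat {
    m <- sample(1:5, 1)
    n <- sample(2:6, 1)
    types <- LETTERS[seq_len(n)]
    inst <- sample(2:30, 1)
    a <- sample(types, inst, replace = TRUE)
    b <- sample(types, inst, replace = TRUE)
    df <- data.frame(
      seq_id = sample(paste0("s", seq_len(m)), inst, replace = TRUE),
      type_a = pmin(a, b), type_b = pmax(a, b),
      count = 1L, stringsAsFactors = FALSE)
    df <- aggregate(count ~ seq_id + type_a + type_b, df, sum)
    if (length(unique(c(df$type_a, df$type_b))) >= 2) return(df)
  }
}

random_tsm_matrix <- function(seed) {
  set.seed(seed)
  repeat {
    m <- sample(1:5, 1)
    n <- sample(1:6, 1)
    f <- matrix(sample(0:9, m * n, replace = TRUE), m, n,
                dimnames = list(paste0("s", seq_len(m)),
                                LETTERS[seq_len(n)]))
    if (sum(f) > 0) return(f)
  }
}
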