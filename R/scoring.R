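#' Pooled pair and marginal type probabilities
#'
#' With `F(a,b)` the pooled count of (unordered) pair `a-b` and
#' `T = sum(F)`, the joint probability is `p(a,b) = F(a,b) / T`.  Every
#' counted pair occupies two type slots, so the marginal of type `a` is
#' its slot share, `p(a) = C(a) / (2T)` with
#' `C(a) = sum_{b != a} F(a,b) + 2 F(a,a)`; marginals then sum to one and
#' the definition reduces to standard bigram PMI.
#'
#' @param counts A `tf_pair_counts` object.
#' @return List with `joint` (tibble `type_a`, `type_b`, `F`, `p_joint`)
#'   and `marginal` (tibble `type`, `C`, `p`), plus the total `T`.
#' @export
pair_probabilities <- function(counts) {
  pooled <- counts$pooled
  total <- sum(pooled$F)
  if (total == 0) abort("no pairs: every sequence has zero counted pair instances")
  joint <- pooled %>% mutate(p_joint = .data$F / total)
  slot <- c(
    setNames(pooled$F * ifelse(pooled$type_a == pooled$type_b, 2L, 1L), pooled$type_a),
    setNames(ifelse(pooled$type_a == pooled$type_b, 0L, pooled$F), pooled$type_b)
  )
  C <- tapply(slot, names(slot), sum)
  marginal <- tibble(type = names(C), C = as.double(C),
                     p = as.double(C) / (2 * total)) %>%
    arrange(.data$type)
  list(joint = joint, marginal = marginal, total = total)
}

#' Pointwise mutual information of pooled pairs
#'
#' `PMI(a;b) = log2( p(a,b) / (p(a) p(b)) )` for every observed pair
#' (`F > 0`); unobserved pairs carry no PMI.
#'
#' @param probs Output of [pair_probabilities()].
#' @return The joint tibble with a `pmi` column added.
#' @export
pair_pmi <- function(probs) {
  m <- setNames(probs$marginal$p, probs$marginal$type)
  probs$joint %>%
    mutate(pmi = unname(log2(.data$p_joint / (m[.data$type_a] * m[.data$type_b]))))
}

#' Per-sequence weights from pair totals
#'
#' `w_s = N_s / sum(N_s)`: each sequence's share of all counted pair
#' instances.  Sequences without pairs get weight 0.
#'
#' @param counts A `tf_pair_counts` object.
#' @return Tibble `seq_id`, `n_pairs`, `w`.
#' @export
sequence_weights <- function(counts) {
  tot <- sum(counts$n_s$n_pairs)
  if (tot == 0) abort("no pairs: all per-sequence totals are zero")
  counts$n_s %>% mutate(w = .data$n_pairs / tot)
}

#' Weighted cumulative PMI of each pair
#'
#' The raw PMI is damped by the pair's global joint probability (to tame
#' low-count pairs) and accumulated over the sequences that actually
#' contain the pair, each contributing its weight:
#' `PMI_pc(a,b) = [sum over sequences s containing a-b of w_s] * p(a,b) * PMI(a;b)`.
#' The joint probability and PMI are the pooled (global) quantities.
#'
#' @param counts A `tf_pair_counts`.
#' @param pmi Joint tibble from [pair_pmi()].
#' @param weights Tibble from [sequence_weights()].
#' @return The joint tibble with `w_sum` and `pmi_pc` columns added.
#' @export
cumulative_weighted_pmi <- function(counts, pmi, weights) {
  w <- setNames(weights$w, weights$seq_id)
  wsum <- counts$per_sequence %>%
    group_by(.data$type_a, .data$type_b) %>%
    summarise(w_sum = sum(w[.data$seq_id]), .groups = "drop")
  pmi %>%
    left_join(wsum, by = c("type_a", "type_b")) %>%
    mutate(w_sum = ifelse(is.na(.data$w_sum), 0, .data$w_sum),
           pmi_pc = .data$w_sum * .data$p_joint * .data$pmi)
}

# Full pair-slot universe over the participating types: all n(n-1)/2
# heterotypic unordered type pairs (unobserved ones carry pmi_pc = 0)
# plus any observed homotypic pairs.
pair_slot_universe <- function(scored) {
  types <- sort(unique(c(scored$type_a, scored$type_b)))
  n <- length(types)
  hetero <- if (n >= 2) {
    idx <- utils::combn(n, 2)
    tibble(type_a = types[idx[1, ]], type_b = types[idx[2, ]])
  } else {
    tibble(type_a = character(), type_b = character())
  }
  homo_obs <- scored %>%
    filter(.data$type_a == .data$type_b) %>%
    select("type_a", "type_b")
  slots <- bind_rows(hetero, homo_obs) %>%
    left_join(scored, by = c("type_a", "type_b")) %>%
    mutate(
      F = ifelse(is.na(.data$F), 0L, .data$F),
      p_joint = ifelse(is.na(.data$p_joint), 0, .data$p_joint),
      w_sum = ifelse(is.na(.data$w_sum), 0, .data$w_sum),
      pmi_pc = ifelse(is.na(.data$pmi_pc), 0, .data$pmi_pc)
    )
  list(slots = slots, types = types)
}

#' Average product correction of the weighted cumulative PMI
#'
#' False-positive site predictions inflate the scores of every pair a
#' promiscuous type participates in.  The average product correction
#' estimates that shared background as
#' `APC(a,b) = mean_pc(a) * mean_pc(b) / overall_mean`, where
#' `mean_pc(a)` averages `PMI_pc(a, x)` over the other `n - 1`
#' participating types (self excluded, unobserved pairs contributing 0)
#' and `overall_mean` averages `PMI_pc` over all `n(n-1)/2` heterotypic
#' type-pair slots.  Homotypic pairs use their single type's mean
#' squared.  The corrected score is
#' `PMI_pc_APC(a,b) = PMI_pc(a,b) - APC(a,b)`; a rank-one (uniform)
#' `PMI_pc` structure is cancelled exactly.
#'
#' @param scored Joint tibble from [cumulative_weighted_pmi()].
#' @return Tibble over the full pair-slot universe (observed pairs plus
#'   unobserved heterotypic slots of the participating types) with `apc`
#'   and `pmi_pc_apc` columns; per-type means in attribute `type_means`,
#'   overall mean in attribute `overall_mean`.
#' @export
apc_correct <- function(scored) {
  u <- pair_slot_universe(scored)
  n <- length(u$types)
  if (n < 2) abort("APC needs at least 2 TFBS types participating in pairs")
  hetero <- filter(u$slots, .data$type_a != .data$type_b)
  contrib <- c(setNames(hetero$pmi_pc, hetero$type_a),
               setNames(hetero$pmi_pc, hetero$type_b))
  sums <- tapply(contrib, names(contrib), sum)
  means <- setNames(as.double(sums[u$types]) / (n - 1), u$types)
  means[is.na(means)] <- 0
  overall <- mean(hetero$pmi_pc)
  out <- u$slots %>%
    mutate(
      apc = if (overall == 0) 0 else unname(means[.data$type_a] * means[.data$type_b] / overall),
      pmi_pc_apc = .data$pmi_pc - .data$apc
    )
  if (overall == 0) {
    inform("apc_correct: overall mean PMI_pc is 0; APC set to 0 (degenerate)")
  }
  attr(out, "type_means") <- means
  attr(out, "overall_mean") <- overall
  out
}

#' Z-scores and significance of corrected pair scores
#'
#' Corrected scores are standardized over the full pair-slot universe of
#' the participating types (the same population the APC means are taken
#' over): `z = (v - mean) / sd` with the sample standard deviation.  A
#' pair is significant when `z >= z_threshold` (default 3).  When all
#' corrected scores are equal (`sd = 0`) no pair is significant.
#'
#' @param corrected Tibble from [apc_correct()].
#' @param z_threshold Significance threshold on the z-score (default 3).
#' @return The tibble with `zscore` and `significant` columns, sorted by
#'   descending z-score.
#' @export
pair_zscores <- function(corrected, z_threshold = 3) {
  if (nrow(corrected) < 2) abort("z-scores need at least 2 pair slots")
  mu <- mean(corrected$pmi_pc_apc)
  s <- sd(corrected$pmi_pc_apc)
  if (is.na(s) || s == 0) {
    inform("pair_zscores: zero variance in corrected scores; no pair significant")
    out <- corrected %>% mutate(zscore = 0, significant = FALSE)
  } else {
    out <- corrected %>%
      mutate(zscore = (.data$pmi_pc_apc - mu) / s,
             significant = .data$zscore >= z_threshold)
  }
  arrange(out, dplyr::desc(.data$zscore), .data$type_a, .data$type_b)
}

#' Score all TFBS pairs of a pair-count table
#'
#' Runs the whole scoring cascade — probabilities, PMI, sequence weights,
#' weighted cumulative PMI, APC correction, z-scores — and returns one
#' table with every per-pair quantity.
#'
#' @param counts A `tf_pair_counts` from [enumerate_pairs()].
#' @param z_threshold Z-score significance threshold (default 3).
#' @return A `tf_pair_scores` tibble: `type_a`, `type_b`, `F`, `p_joint`,
#'   `pmi`, `w_sum`, `pmi_pc`, `apc`, `pmi_pc_apc`, `zscore`,
#'   `significant`, sorted by descending z-score.  Attributes carry the
#'   sequence weights, per-type means, overall mean and threshold.
#' @export
score_pairs <- function(counts, z_threshold = 3) {
  probs <- pair_probabilities(counts)
  pmi <- pair_pmi(probs)
  weights <- sequence_weights(counts)
  scored <- cumulative_weighted_pmi(counts, pmi, weights)
  corrected <- apc_correct(scored)
  out <- pair_zscores(corrected, z_threshold = z_threshold)
  attr(out, "weights") <- weights
  attr(out, "z_threshold") <- z_threshold
  class(out) <- c("tf_pair_scores", class(out))
  out
}
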