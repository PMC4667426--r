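#' Sequence-by-TFBS pointwise mutual information
#'
#' Phase 2 asks, for every sequence `s` and TFBS type `t`: does `t` occur
#' in `s` more often than expected from the overall abundance of `t` and
#' the overall site load of `s`?  With `T` the total count of the
#' (filtered) TFBS-sequence matrix, `p(s,t) = f_st / T`,
#' `p(s) = rowsum_s / T`, `p(t) = colsum_t / T`, the score is
#' `PMI(s;t) = log2( p(s,t) / (p(s) p(t)) )`.  Cells with `f_st = 0` have
#' no finite PMI and are excluded.
#'
#' @param tsm A filtered `tf_tsm` with total count > 0.
#' @return Tibble with one row per non-zero cell: `seq_id`, `matrix_id`,
#'   `f`, `pmi`.  Marginals are attached as attributes `p_seq`, `p_type`.
#' @export
sequence_tfbs_pmi <- function(tsm) {
  stopifnot(inherits(tsm, "tf_tsm"))
  f <- tsm$f
  total <- sum(f)
  if (total == 0) abort("empty matrix: total TFBS count is zero")
  rs <- rowSums(f)
  cs <- colSums(f)
  nz <- which(f > 0, arr.ind = TRUE)
  fv <- as.vector(f[nz])
  out <- tibble(
    seq_id = rownames(f)[nz[, 1]],
    matrix_id = colnames(f)[nz[, 2]],
    f = as.integer(fv),
    pmi = as.vector(log2((fv / total) /
                           ((rs[nz[, 1]] / total) * (cs[nz[, 2]] / total))))
  ) %>%
    arrange(.data$seq_id, .data$matrix_id)
  attr(out, "p_seq") <- rs / total
  attr(out, "p_type") <- cs / total
  out
}

#' Select the important TFBS types of each sequence
#'
#' A strictly positive PMI means the type occurs in that sequence more
#' often than by chance; only those (sequence, type) assignments are kept
#' for pair construction.  PMI exactly 0 (independence) is not important.
#'
#' @param pmi_table Output of [sequence_tfbs_pmi()].
#' @return The subset of rows with `pmi > 0`.
#' @export
select_important <- function(pmi_table) {
  filter(pmi_table, .data$pmi > 0)
}

#' Restrict hits to the important (sequence, type) assignments
#'
#' Keeps exactly the hits whose (sequence, type) combination survived
#' [select_important()].  Hits of types removed by the Phase-1 matrix
#' filters are absent from the importance table and are dropped here too.
#'
#' @param hits Hits tibble.
#' @param important Tibble with columns `seq_id`, `matrix_id` (typically
#'   from [select_important()]).
#' @return Filtered hits tibble.
#' @export
restrict_hits <- function(hits, important) {
  semi_join(hits, important, by = c("seq_id", "matrix_id"))
}
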