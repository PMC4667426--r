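# Shared fixtures: small promoter/hit sets built in code.

make_promoters <- function(seqs, tss_offset = NULL) {
  tb <- tibble::tibble(
    seq_id = names(seqs),
    seq = toupper(unname(seqs)),
    length = nchar(seqs),
    tss_offset = if (is.null(tss_offset)) nchar(seqs) else tss_offset,
    chrom = NA_character_, g_start = NA_integer_, g_end = NA_integer_
  )
  tb
}

make_hits <- function(seq_id, matrix_id, start, end,
                      strand = "+", score = 1) {
  tibble::tibble(seq_id = seq_id, matrix_id = matrix_id,
                 start = as.integer(start), end = as.integer(end),
                 strand = strand, score = score)
}

# Build a tf_pair_counts object directly from a per-sequence pair count
# table (seq_id, type_a, type_b, count), bypassing hit-level enumeration.
make_pair_counts <- function(per_seq, seq_ids = NULL) {
  stopifnot(all(per_seq$type_a <= per_seq$type_b))
  if (is.null(seq_ids)) seq_ids <- sort(unique(per_seq$seq_id))
  per_sequence <- dplyr::summarise(
    dplyr::group_by(per_seq, seq_id, type_a, type_b),
    count = sum(count), .groups = "drop")
  n_s <- dplyr::summarise(dplyr::group_by(per_sequence, seq_id),
                          n_pairs = sum(count), .groups = "drop")
  n_s <- dplyr::mutate(
    dplyr::left_join(tibble::tibble(seq_id = seq_ids), n_s, by = "seq_id"),
    n_pairs = ifelse(is.na(n_pairs), 0L, n_pairs))
  pooled <- dplyr::arrange(
    dplyr::summarise(dplyr::group_by(per_sequence, type_a, type_b),
                     F = sum(count), .groups = "drop"),
    type_a, type_b)
  structure(list(
    instances = per_sequence[rep(seq_len(nrow(per_sequence)),
                                 per_sequence$count), ],
    per_sequence = per_sequence, n_s = n_s, pooled = pooled,
    params = list(d_min = NA, d_max = NA, max_overlap = NA)
  ), class = "tf_pair_counts")
}

new_tsm_for_test <- function(f) tfpairs:::new_tsm(f)

# The cross-module worked example: s1 carries (A,B) twice and (A,C) once,
# s2 carries (A,B) once.
micro_counts <- function() {
  make_pair_counts(tibble::tibble(
    seq_id = c("s1", "s1", "s2"),
    type_a = c("A", "A", "A"),
    type_b = c("B", "C", "B"),
    count = c(2L, 1L, 1L)
  ))
}

# Hit-level realisation of the same example (10 bp sites, no overlaps,
# pair distances inside [5, 20]).
micro_hits <- function() {
  make_hits(
    seq_id = c(rep("s1", 6), "s2", "s2"),
    matrix_id = c("A", "B", "A", "B", "A", "C", "A", "B"),
    start = c(5, 15, 35, 45, 65, 75, 5, 15),
    end = c(15, 25, 45, 55, 75, 85, 15, 25)
  )
}

micro_promoters <- function() {
  make_promoters(c(s1 = strrep("A", 100), s2 = strrep("A", 100)))
}

write_fasta_tmp <- function(seqs) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

run_spikein <- function(seed, cfg_args = list(), ...) {
  cfg <- do.call(spikein_config, c(list(seed = seed), cfg_args))
  sim <- simulate_spikein(cfg)
  hits <- scan_consensus(sim$promoters, spikein_motifs(cfg))
  res <- suppressMessages(tf_pair_analysis(sim$promoters, hits = hits, ...))
  list(cfg = cfg, sim = sim, res = res)
}

planted_row <- function(res, cfg) {
  nm <- sort(names(cfg$pair_motifs))
  dplyr::filter(tidy(res), type_a == nm[1], type_b == nm[2])
}
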