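#' Run the full TFBS pair-discovery pipeline
#'
#' Orchestrates all six phases on a promoter set: (optional) promoter
#' de-duplication; binding sites taken from a supplied hit table or
#' produced by the built-in scanner; TFBS-sequence matrix construction
#' and its two column filters; per-sequence importance selection by
#' positive PMI; resolution of same-type overlapping sites towards the
#' TSS; distance-constrained pair enumeration; and weighted cumulative
#' PMI scoring with APC correction and z-score significance calls.
#'
#' @param promoters Promoter tibble from [read_promoters()] (or the
#'   simulator).
#' @param hits Optional precomputed hits tibble; if missing, `pwms` or
#'   `motifs` must be given.
#' @param pwms Optional PWM tibble for [scan_pwm()].
#' @param motifs Optional named consensus vector for [scan_consensus()].
#' @param d_min,d_max,max_overlap Pairing constraints in bp (defaults 5,
#'   20, 4).
#' @param z_threshold Significance threshold on the pair z-score
#'   (default 3).
#' @param min_score Scanner threshold for `pwms` (default 0.85).
#' @param dedup Apply [deduplicate_promoters()] first (default FALSE;
#'   needs genomic intervals).
#' @param over_filter,sparse_filter Toggle the Phase-1 column filters
#'   (defaults TRUE).
#' @param importance Toggle the positive-PMI importance selection
#'   (default TRUE).
#' @param overlap_filter Toggle the same-type overlap resolution
#'   (default TRUE).
#' @return A `tf_pair_result` list: `scores` (a `tf_pair_scores` tibble),
#'   `tsm_raw`, `tsm` (filtered), `importance`, `counts`, `hits` (the
#'   restricted hit set used for pairing), `log` (per-stage record
#'   counts) and `params`.
#' @export
tf_pair_analysis <- function(promoters, hits = NULL, pwms = NULL,
                             motifs = NULL,
                             d_min = 5, d_max = 20, max_overlap = 4,
                             z_threshold = 3, min_score = 0.85,
                             dedup = FALSE,
                             over_filter = TRUE, sparse_filter = TRUE,
                             importance = TRUE, overlap_filter = TRUE) {
  if (!nrow(promoters)) abort("no sequences")
  if (d_min > d_max) abort("d_min must not exceed d_max")
  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1L]] <<- tibble(
      stage = stage, n_in = as.integer(n_in),
      n_removed = as.integer(n_in - n_out), n_out = as.integer(n_out))
  }
  if (dedup) {
    n0 <- nrow(promoters)
    promoters <- deduplicate_promoters(promoters)
    note("deduplicate_promoters", n0, nrow(promoters))
    if (!nrow(promoters)) abort("no sequences after promoter de-duplication")
  }
  if (is.null(hits)) {
    if (!is.null(motifs)) {
      hits <- scan_consensus(promoters, motifs)
    } else if (!is.null(pwms)) {
      hits <- scan_pwm(promoters, pwms, min_score = min_score)
    } else {
      abort("supply hits, pwms or motifs")
    }
  }
  if (!nrow(hits)) abort("no hits")
  note("hits", nrow(hits), nrow(hits))

  tsm_raw <- build_tsm(hits, promoters)
  tsm <- tsm_raw
  if (over_filter) {
    n0 <- ncol(tsm$f)
    tsm <- filter_overrepresented(tsm)
    note("filter_overrepresented", n0, ncol(tsm$f))
  }
  if (sparse_filter) {
    n0 <- ncol(tsm$f)
    tsm <- filter_sparse(tsm)
    note("filter_sparse", n0, ncol(tsm$f))
  }
  if (!ncol(tsm$f)) abort("no surviving TFBS columns after matrix filtering")

  if (importance) {
    imp <- select_important(sequence_tfbs_pmi(tsm))
  } else {
    imp <- tidy(tsm) %>% filter(.data$f > 0) %>% mutate(pmi = NA_real_)
  }
  n0 <- nrow(hits)
  hits_used <- restrict_hits(hits, imp)
  note("restrict_hits", n0, nrow(hits_used))

  if (overlap_filter) {
    n0 <- nrow(hits_used)
    hits_used <- resolve_same_type_overlaps(hits_used, promoters)
    note("resolve_same_type_overlaps", n0, nrow(hits_used))
  }

  counts <- enumerate_pairs(hits_used, promoters, d_min = d_min,
                            d_max = d_max, max_overlap = max_overlap)
  note("enumerate_pairs", nrow(hits_used), nrow(counts$instances))
  if (nrow(counts$pooled) < 1) abort("no pairs under the distance constraints")

  scores <- score_pairs(counts, z_threshold = z_threshold)
  if (nrow(scores) < 2) abort("fewer than 2 pair slots; cannot standardize")

  structure(list(
    scores = scores, tsm_raw = tsm_raw, tsm = tsm, importance = imp,
    counts = counts, hits = hits_used, log = bind_rows(log),
    params = list(d_min = d_min, d_max = d_max, max_overlap = max_overlap,
                  z_threshold = z_threshold, min_score = min_score,
                  over_filter = over_filter, sparse_filter = sparse_filter,
                  importance = importance, overlap_filter = overlap_filter,
                  n_sequences = nrow(promoters))
  ), class = "tf_pair_result")
}

#' @export
print.tf_pair_result <- function(x, ...) {
  g <- glance(x)
  cat("<tf_pair_result> ", g$n_sequences, " sequences, ", g$n_types,
      " TFBS types, ", g$n_pair_instances, " pair instances, ",
      g$n_pairs_observed, " observed pair types, ", g$n_significant,
      " significant (z >= ", x$params$z_threshold, ")\n", sep = "")
  invisible(x)
}

#' Tidy pair scores
#'
#' @param x A `tf_pair_scores` or `tf_pair_result`.
#' @param ... Unused.
#' @return The per-pair score tibble.
#' @export
tidy.tf_pair_scores <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "tf_pair_scores")
  attr(out, "weights") <- NULL
  attr(out, "type_means") <- NULL
  attr(out, "overall_mean") <- NULL
  attr(out, "z_threshold") <- NULL
  out
}

#' @rdname tidy.tf_pair_scores
#' @export
tidy.tf_pair_result <- function(x, ...) tidy(x$scores)

#' One-row pipeline summary
#'
#' @param x A `tf_pair_result`.
#' @param ... Unused.
#' @return One-row tibble with sequence, hit, type, pair and significance
#'   counts.
#' @export
glance.tf_pair_result <- function(x, ...) {
  tibble(
    n_sequences = x$params$n_sequences,
    n_hits_used = nrow(x$hits),
    n_types = ncol(x$tsm$f),
    n_pair_instances = nrow(x$counts$instances),
    n_pairs_observed = sum(x$scores$F > 0),
    n_significant = sum(x$scores$significant),
    sigma_colsums = x$tsm$sigma,
    z_threshold = x$params$z_threshold
  )
}

#' Significant-pair network edge list
#'
#' @param scores A `tf_pair_scores` or `tf_pair_result`.
#' @return Tibble `type_a`, `type_b`, `zscore` for significant pairs.
#' @export
network_edges <- function(scores) {
  if (inherits(scores, "tf_pair_result")) scores <- scores$scores
  scores %>%
    filter(.data$significant) %>%
    select("type_a", "type_b", "zscore") %>%
    as_tibble()
}

#' Node degrees of the significant-pair network
#'
#' The most connected TFBS types — the hubs — often correspond to broadly
#' collaborating factors.
#'
#' @param scores A `tf_pair_scores` or `tf_pair_result`.
#' @return Tibble `type`, `degree`, sorted by decreasing degree.  A
#'   homotypic significant pair contributes a self-loop (degree 1).
#' @export
node_degrees <- function(scores) {
  e <- network_edges(scores)
  if (!nrow(e)) return(tibble(type = character(), degree = integer()))
  tibble(type = c(e$type_a, e$type_b[e$type_a != e$type_b])) %>%
    count(.data$type, name = "degree") %>%
    arrange(dplyr::desc(.data$degree), .data$type)
}

#' Write all pipeline result tables
#'
#' Emits `pairs.tsv` (all scored pair slots, descending z-score),
#' `significant_pairs.tsv`, `network_edges.tsv`, `node_degrees.tsv` and
#' `run.log` (per-stage record counts and effective parameters) into a
#' directory.
#'
#' @param result A `tf_pair_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pair_results <- function(result, dir) {
  stopifnot(inherits(result, "tf_pair_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tidy(result$scores), file.path(dir, "pairs.tsv"))
  readr::write_tsv(filter(tidy(result$scores), .data$significant),
                   file.path(dir, "significant_pairs.tsv"))
  readr::write_tsv(network_edges(result), file.path(dir, "network_edges.tsv"))
  readr::write_tsv(node_degrees(result), file.path(dir, "node_degrees.tsv"))
  par_lines <- paste0(names(result$params), " = ",
                      vapply(result$params, function(p) paste(format(p), collapse = ","), character(1)))
  log_lines <- with(result$log, paste0(stage, ": in=", n_in,
                                       " removed=", n_removed, " out=", n_out))
  writeLines(c("# parameters", par_lines, "# stages", log_lines),
             file.path(dir, "run.log"))
  invisible(dir)
}
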