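#' Midpoint of a binding-site interval
#'
#' Defined as `start + floor(width / 2)` in 0-based sequence coordinates,
#' i.e. the floor-midpoint offset applied from the site's start.
#'
#' @param start,end 0-based half-open interval bounds (vectorized).
#' @return Integer midpoint position(s).
#' @export
hit_midpoint <- function(start, end) {
  stopifnot(all(start < end))
  as.integer(start + (end - start) %/% 2L)
}

#' Distance between two binding sites
#'
#' Absolute difference of the midpoints of two hits on the same sequence.
#'
#' @param hit_a,hit_b Single-row hits (lists or one-row tibbles with
#'   `seq_id`, `start`, `end`).
#' @return Integer distance in bp.
#' @export
pair_distance <- function(hit_a, hit_b) {
  if (!identical(hit_a$seq_id, hit_b$seq_id)) {
    abort("pair_distance: hits lie on different sequences")
  }
  abs(hit_midpoint(hit_a$start, hit_a$end) - hit_midpoint(hit_b$start, hit_b$end))
}

#' Enumerate distance-constrained TFBS pairs
#'
#' Two sites form a candidate pair when they lie on the same sequence,
#' their midpoint distance falls in `[d_min, d_max]`, and their intervals
#' overlap by at most `max_overlap` bases for different types (same-type
#' candidates must not overlap at all; the same-type overlap filter
#' guarantees that upstream).  Dense homotypic clusters would otherwise be
#' over-counted, so per sequence and per (unordered) pair type a greedy
#' 5'-to-3' disjoint matching is applied: scanning candidates ordered by
#' the left hit's midpoint then the right hit's midpoint, a candidate is
#' counted only if neither of its sites has already been counted *for that
#' pair type*; a site may still be counted once for every other pair type.
#'
#' @param hits Hits tibble (ideally after [restrict_hits()] and
#'   [resolve_same_type_overlaps()]).
#' @param promoters Optional promoter tibble fixing the sequence universe
#'   for per-sequence totals `N_s` (sequences without pairs get 0);
#'   defaults to the sequences present in `hits`.
#' @param d_min,d_max Midpoint distance constraints in bp (defaults 5
#'   and 20; 50 or 100 widen the search to long-range partners).
#' @param max_overlap Maximum tolerated interval overlap between sites of
#'   different types, in bp (default 4).
#' @return A `tf_pair_counts` object: counted pair `instances`,
#'   `per_sequence` counts, per-sequence totals `n_s`, and `pooled` counts
#'   `F(a,b)` over the whole set.  Pair types are canonicalized with
#'   `type_a <= type_b`.
#' @export
enumerate_pairs <- function(hits, promoters = NULL, d_min = 5, d_max = 20,
                            max_overlap = 4) {
  stopifnot(d_min >= 0, d_max >= d_min, max_overlap >= 0)
  seq_ids <- if (is.null(promoters)) sort(unique(hits$seq_id)) else promoters$seq_id
  inst <- if (nrow(hits)) {
    h <- mutate(hits, mid = hit_midpoint(.data$start, .data$end))
    by_seq <- split(seq_len(nrow(h)), h$seq_id)
    bind_rows(lapply(names(by_seq), function(sid) {
      out <- pairs_in_sequence(h[by_seq[[sid]], ], d_min, d_max, max_overlap)
      if (nrow(out)) mutate(out, seq_id = sid, .before = 1) else NULL
    }))
  } else {
    NULL
  }
  if (is.null(inst) || !nrow(inst)) {
    inst <- tibble(seq_id = character(), type_a = character(),
                   type_b = character(), start_a = integer(), end_a = integer(),
                   start_b = integer(), end_b = integer(), distance = integer())
  }
  per_sequence <- inst %>%
    count(.data$seq_id, .data$type_a, .data$type_b, name = "count")
  n_s <- per_sequence %>%
    group_by(.data$seq_id) %>%
    summarise(n_pairs = sum(.data$count), .groups = "drop")
  n_s <- tibble(seq_id = seq_ids) %>%
    left_join(n_s, by = "seq_id") %>%
    mutate(n_pairs = ifelse(is.na(.data$n_pairs), 0L, .data$n_pairs))
  pooled <- per_sequence %>%
    group_by(.data$type_a, .data$type_b) %>%
    summarise(F = sum(.data$count), .groups = "drop") %>%
    arrange(.data$type_a, .data$type_b)
  structure(
    list(instances = inst, per_sequence = per_sequence, n_s = n_s,
         pooled = pooled,
         params = list(d_min = d_min, d_max = d_max, max_overlap = max_overlap)),
    class = "tf_pair_counts"
  )
}

#' @export
print.tf_pair_counts <- function(x, ...) {
  cat("<tf_pair_counts> ", nrow(x$instances), " pair instances, ",
      nrow(x$pooled), " pair types over ",
      sum(x$n_s$n_pairs > 0), "/", nrow(x$n_s), " sequences ",
      "(d in [", x$params$d_min, ", ", x$params$d_max, "], overlap <= ",
      x$params$max_overlap, ")\n", sep = "")
  invisible(x)
}

# All counted pair instances of one sequence.  g carries start/end/strand/
# matrix_id/mid; hit order is canonicalized internally so results do not
# depend on input row order.
pairs_in_sequence <- function(g, d_min, d_max, max_overlap) {
  n <- nrow(g)
  empty <- tibble(type_a = character(), type_b = character(),
                  start_a = integer(), end_a = integer(),
                  start_b = integer(), end_b = integer(), distance = integer())
  if (n < 2) return(empty)
  g <- g[order(g$mid, g$start, g$matrix_id, g$strand != "+"), ]
  mid <- g$mid
  ci <- integer(0); cj <- integer(0)
  for (i in seq_len(n - 1L)) {
    js <- seq(i + 1L, n)
    js <- js[mid[js] - mid[i] <= d_max & mid[js] - mid[i] >= d_min]
    if (!length(js)) next
    ov <- pmax(0L, pmin(g$end[i], g$end[js]) - pmax(g$start[i], g$start[js]))
    same <- g$matrix_id[js] == g$matrix_id[i]
    js <- js[ifelse(same, ov == 0L, ov <= max_overlap)]
    if (length(js)) {
      ci <- c(ci, rep.int(i, length(js)))
      cj <- c(cj, js)
    }
  }
  if (!length(ci)) return(empty)
  # canonical pair type and deterministic scan order
  ta <- pmin(g$matrix_id[ci], g$matrix_id[cj])
  tb <- pmax(g$matrix_id[ci], g$matrix_id[cj])
  ord <- order(mid[ci], mid[cj], g$start[ci], g$start[cj])
  ci <- ci[ord]; cj <- cj[ord]; ta <- ta[ord]; tb <- tb[ord]
  key <- paste(ta, tb, sep = "\r")
  used <- new.env(parent = emptyenv())
  keep <- logical(length(ci))
  for (k in seq_along(ci)) {
    ku <- key[k]
    u <- used[[ku]]
    if (is.null(u)) u <- integer(0)
    if (!(ci[k] %in% u) && !(cj[k] %in% u)) {
      keep[k] <- TRUE
      used[[ku]] <- c(u, ci[k], cj[k])
    }
  }
  ci <- ci[keep]; cj <- cj[keep]
  tibble(
    type_a = ta[keep], type_b = tb[keep],
    start_a = g$start[ci], end_a = g$end[ci],
    start_b = g$start[cj], end_b = g$end[cj],
    distance = abs(mid[cj] - mid[ci])
  )
}
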