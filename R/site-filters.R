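#' Resolve same-type overlapping binding sites towards the TSS
#'
#' Predicted sites of the *same* motif frequently overlap — palindromic
#' motifs match both strands over the same bases, and long matrices
#' overhang the true binding footprint — which would over-count that type
#' in pair construction.  Within each (sequence, type) group this filter
#' builds overlap clusters (transitive closure of half-open interval
#' overlap) and keeps exactly one site per cluster: the one whose midpoint
#' lies closest to the TSS, functional sites tending to sit near it.
#' Ties break towards the smaller start, then the `+` strand.  Overlaps
#' between *different* types are left untouched (a slight overlap between
#' partners is tolerated at the pairing stage).
#'
#' @param hits Hits tibble.
#' @param promoters Promoter tibble supplying `tss_offset` per sequence.
#' @return Hits tibble with at most one site per same-type overlap cluster.
#' @export
resolve_same_type_overlaps <- function(hits, promoters) {
  if (!nrow(hits)) return(hits)
  tss <- setNames(promoters$tss_offset, promoters$seq_id)
  unknown <- setdiff(hits$seq_id, names(tss))
  if (length(unknown)) {
    abort(paste0("hits reference sequence id(s) without records: ",
                 paste(unknown, collapse = ", ")))
  }
  groups <- split(seq_len(nrow(hits)),
                  paste(hits$seq_id, hits$matrix_id, sep = "\r"))
  keep <- lapply(groups, function(ii) {
    if (length(ii) < 2) return(ii)
    ii[keep_nearest_tss(hits$start[ii], hits$end[ii], hits$strand[ii],
                        tss[[hits$seq_id[ii[1]]]])]
  })
  hits[sort(unlist(keep, use.names = FALSE)), ]
}

# One (sequence, type) group: cluster by interval overlap, keep the hit
# whose midpoint is nearest the TSS (tie: smaller start, then "+").
# Returns the within-group indices of the survivors.
keep_nearest_tss <- function(start, end, strand, tss_offset) {
  ord <- order(start, end)
  s <- start[ord]; e <- end[ord]
  # transitive overlap clusters on sorted half-open intervals
  cummax_end <- cummax(e)
  cl <- cumsum(c(TRUE, s[-1] >= cummax_end[-length(s)]))
  mid <- s + (e - s) %/% 2L
  dist <- abs(mid - tss_offset)
  pick <- vapply(split(seq_along(ord), cl), function(idx) {
    o <- order(dist[idx], s[idx], strand[ord][idx] != "+")
    idx[o[1]]
  }, integer(1))
  ord[pick]
}
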