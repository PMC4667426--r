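#' Scan promoters with position weight matrices
#'
#' A simple log-odds scanner for users without an external TFBS predictor:
#' both strands of every sequence are scored against each count matrix and
#' windows at or above `min_score` are reported.  Per-position
#' probabilities use a pseudocount of 1% of the column total (spread
#' across the four bases); the log2 odds against the background base
#' frequencies of the scanned sequence set are summed over the window and
#' rescaled so that the best achievable window scores 1 and the worst 0:
#' `score = (S - S_min) / (S_max - S_min)`.  Windows containing `N` never
#' produce hits.  Reverse-strand matches are reported in forward-strand
#' coordinates with `strand = "-"`.  Any monotone scorer would serve here:
#' downstream analysis consumes only hit positions, and externally
#' predicted sites can be supplied via [read_hits()] instead.
#'
#' @param promoters Promoter tibble from [read_promoters()].
#' @param pwms PWM tibble from [read_transfac_matrices()] or
#'   [consensus_pwms()].
#' @param min_score Minimum normalized score in `[0, 1]` (default 0.85).
#' @return Hits tibble (`seq_id`, `matrix_id`, `start`, `end`, `strand`,
#'   `score`), sorted by sequence, matrix, start.
#' @export
scan_pwm <- function(promoters, pwms, min_score = 0.85) {
  stopifnot(min_score >= 0, min_score <= 1)
  bg <- background_frequencies(promoters$seq)
  out <- purrr::map(seq_len(nrow(pwms)), function(k) {
    lut <- pwm_logodds(pwms$counts[[k]], bg)
    purrr::map(seq_len(nrow(promoters)), function(i) {
      scan_one(promoters$seq[i], promoters$seq_id[i], pwms$matrix_id[k],
               lut, min_score)
    })
  })
  res <- bind_rows(purrr::flatten(out))
  if (!nrow(res)) {
    return(tibble(seq_id = character(), matrix_id = character(),
                  start = integer(), end = integer(),
                  strand = character(), score = double()))
  }
  arrange(res, .data$seq_id, .data$matrix_id, .data$start, .data$strand)
}

# Base composition of a character vector of sequences (N ignored),
# symmetrized over strands (A with T, C with G) since both strands are
# scanned, and floored at 1e-6 to keep log odds finite.
background_frequencies <- function(seqs) {
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(seqs))[, .DNA_BASES, drop = FALSE])
  if (sum(counts) == 0) return(setNames(rep(0.25, 4), .DNA_BASES))
  at <- (counts[["A"]] + counts[["T"]]) / 2
  cg <- (counts[["C"]] + counts[["G"]]) / 2
  counts <- c(A = at, C = cg, G = cg, T = at)
  pmax(counts / sum(counts), 1e-6)
}

# 4 x L matrix of log2((c + pc/4)/(C + pc) / bg) plus normalization bounds.
pwm_logodds <- function(counts, bg) {
  C <- colSums(counts)
  if (any(C <= 0)) abort("PWM column with all-zero counts")
  pc <- 0.01 * C
  p <- sweep(counts, 2, pc / 4, "+")
  p <- sweep(p, 2, C + pc, "/")
  l <- log2(p / bg)
  list(l = l, s_min = sum(apply(l, 2, min)), s_max = sum(apply(l, 2, max)))
}

# window scores of one strand; returns numeric vector (NA where N present)
window_scores <- function(codes, l) {
  L <- ncol(l)
  nw <- length(codes) - L + 1L
  if (nw < 1L) return(numeric(0))
  s <- numeric(nw)
  for (j in seq_len(L)) {
    s <- s + unname(l[, j][codes[j:(j + nw - 1L)]])
  }
  s
}

scan_one <- function(seq, seq_id, matrix_id, lut, min_score) {
  L <- ncol(lut$l)
  n <- nchar(seq)
  if (n < L) return(NULL)
  denom <- lut$s_max - lut$s_min
  if (denom <= 0) denom <- 1  # degenerate constant matrix: every window maximal
  norm <- function(s) (s - lut$s_min) / denom
  fwd_codes <- match(strsplit(seq, "")[[1]], .DNA_BASES)
  rev_codes <- match(strsplit(.rev_comp(seq), "")[[1]], .DNA_BASES)
  sf <- norm(window_scores(fwd_codes, lut$l))
  sr <- norm(window_scores(rev_codes, lut$l))
  keep_f <- which(!is.na(sf) & sf >= min_score)
  keep_r <- which(!is.na(sr) & sr >= min_score)
  rows <- list()
  if (length(keep_f)) {
    rows$f <- tibble(seq_id = seq_id, matrix_id = matrix_id,
                     start = keep_f - 1L, end = keep_f - 1L + L,
                     strand = "+", score = sf[keep_f])
  }
  if (length(keep_r)) {
    # position p (1-based) on the reverse complement covers forward
    # interval [n - p + 1 - L, n - p + 1)
    st <- n - keep_r + 1L - L
    rows$r <- tibble(seq_id = seq_id, matrix_id = matrix_id,
                     start = st, end = st + L,
                     strand = "-", score = sr[keep_r])
  }
  if (!length(rows)) NULL else bind_rows(rows)
}

#' Scan promoters for exact consensus matches
#'
#' Exact string matching of each motif and its reverse complement against
#' every sequence; the score of every reported hit is 1.  Used by the
#' spike-in validation, where the planted motifs are known exactly.
#'
#' @param promoters Promoter tibble.
#' @param motifs Named character vector of consensus strings (names become
#'   `matrix_id`s).
#' @return Hits tibble in forward-strand 0-based half-open coordinates.
#'   For palindromic motifs both strand copies of the same interval are
#'   reported; the same-type overlap filter resolves them downstream.
#' @export
scan_consensus <- function(promoters, motifs) {
  stopifnot(!is.null(names(motifs)), all(nzchar(names(motifs))))
  subject <- Biostrings::DNAStringSet(setNames(promoters$seq, promoters$seq_id))
  widths <- setNames(nchar(promoters$seq), promoters$seq_id)
  res <- purrr::imap(motifs, function(m, id) {
    m <- toupper(m)
    fwd <- Biostrings::vmatchPattern(m, subject)
    rev <- Biostrings::vmatchPattern(.rev_comp(m), subject)
    f_tbl <- match_table(fwd, id, "+")
    r_tbl <- match_table(rev, id, "-")
    bind_rows(f_tbl, r_tbl)
  })
  res <- bind_rows(res)
  if (!nrow(res)) {
    return(tibble(seq_id = character(), matrix_id = character(),
                  start = integer(), end = integer(),
                  strand = character(), score = double()))
  }
  arrange(res, .data$seq_id, .data$matrix_id, .data$start, .data$strand)
}

match_table <- function(mindex, matrix_id, strand) {
  df <- as.data.frame(mindex)
  if (!nrow(df)) return(NULL)
  nm <- names(mindex)[df$group]
  tibble(seq_id = nm, matrix_id = matrix_id,
         start = df$start - 1L, end = df$end,
         strand = strand, score = 1)
}
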