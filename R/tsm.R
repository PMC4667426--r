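#' Build the TFBS-sequence frequency matrix
#'
#' The m x n matrix whose entry `f[i, j]` counts predicted binding sites
#' of motif `j` in sequence `i` — the central Phase-1 object, analogous to
#' a term-sentence matrix in document summarization.  Rows cover every
#' promoter record (sequences without hits get an all-zero row, with a
#' warning); columns are sorted by `matrix_id` for determinism.
#'
#' @param hits Hits tibble.
#' @param promoters Promoter tibble; every hit's `seq_id` must occur here.
#' @return A `tf_tsm` object: the count matrix plus filter bookkeeping.
#' @export
build_tsm <- function(hits, promoters) {
  unknown <- setdiff(hits$seq_id, promoters$seq_id)
  if (length(unknown)) {
    abort(paste0("hits reference sequence id(s) absent from promoters: ",
                 paste(unknown, collapse = ", ")))
  }
  row_ids <- promoters$seq_id
  col_ids <- sort(unique(hits$matrix_id))
  f <- matrix(0L, nrow = length(row_ids), ncol = length(col_ids),
              dimnames = list(row_ids, col_ids))
  if (nrow(hits)) {
    tab <- table(factor(hits$seq_id, levels = row_ids),
                 factor(hits$matrix_id, levels = col_ids))
    f[] <- as.integer(tab)
  }
  zero_rows <- rownames(f)[rowSums(f) == 0]
  if (length(zero_rows) && length(col_ids)) {
    warn(paste0(length(zero_rows), " sequence(s) without any hits: ",
                paste(head(zero_rows, 5), collapse = ", "),
                if (length(zero_rows) > 5) ", ..." else ""))
  }
  new_tsm(f)
}

new_tsm <- function(f, sigma = NA_real_, removed = NULL) {
  if (is.null(removed)) {
    removed <- tibble(filter = character(), matrix_id = character(),
                      value = double(), threshold = double())
  }
  structure(list(f = f, sigma = sigma, removed = removed), class = "tf_tsm")
}

#' @export
print.tf_tsm <- function(x, ...) {
  cat("<tf_tsm> ", nrow(x$f), " sequences x ", ncol(x$f), " TFBS types; ",
      sum(x$f), " sites", sep = "")
  if (!is.na(x$sigma)) cat("; sigma(column sums) = ", signif(x$sigma, 4), sep = "")
  if (nrow(x$removed)) cat("; ", nrow(x$removed), " column(s) filtered", sep = "")
  cat("\n")
  invisible(x)
}

#' Tidy a TFBS-sequence matrix into long form
#'
#' @param x A `tf_tsm`.
#' @param ... Unused.
#' @return Tibble with `seq_id`, `matrix_id`, `f`.
#' @export
tidy.tf_tsm <- function(x, ...) {
  as_tibble(as.table(x$f), .name_repair = "minimal") %>%
    setNames(c("seq_id", "matrix_id", "f")) %>%
    mutate(f = as.integer(.data$f))
}

#' Remove over-represented TFBS columns
#'
#' Highly abundant motifs behave like stop words: they appear everywhere
#' and carry no pairing signal.  Let `sigma` be the *population* standard
#' deviation of the column sums of the input matrix; every column whose
#' sum exceeds `3 * sigma` is removed in a single pass (`sigma` is not
#' recomputed after removals).  When all column sums are equal
#' (`sigma = 0`) the filter is disabled rather than removing everything.
#'
#' @param tsm A `tf_tsm` with at least one column.
#' @return The filtered `tf_tsm`, with `sigma` recorded and removals
#'   appended to the bookkeeping table.
#' @export
filter_overrepresented <- function(tsm) {
  stopifnot(inherits(tsm, "tf_tsm"))
  if (ncol(tsm$f) < 1) abort("TSM has no columns")
  cs <- colSums(tsm$f)
  sigma <- sqrt(mean((cs - mean(cs))^2))
  if (sigma == 0) {
    inform("filter_overrepresented: all column sums equal (sigma = 0); filter disabled")
    tsm$sigma <- sigma
    return(tsm)
  }
  drop <- cs > 3 * sigma
  if (any(drop)) {
    inform(paste0("filter_overrepresented: removed ", sum(drop),
                  " column(s) with sum > ", signif(3 * sigma, 4), ": ",
                  paste(names(cs)[drop], collapse = ", ")))
  }
  removed <- bind_rows(tsm$removed, tibble(
    filter = "overrepresented", matrix_id = names(cs)[drop],
    value = unname(cs[drop]), threshold = 3 * sigma
  ))
  new_tsm(tsm$f[, !drop, drop = FALSE], sigma = sigma, removed = removed)
}

#' Remove sparse TFBS columns
#'
#' Motifs observed in too few sequences are likely noise from false
#' positive predictions.  With `z[j]` the number of zero entries in
#' column `j`, columns with *strictly* more zeros than the mean zero
#' count over the input matrix's columns are removed in a single pass.
#'
#' @param tsm A `tf_tsm` with at least one column.
#' @return The filtered `tf_tsm`.
#' @export
filter_sparse <- function(tsm) {
  stopifnot(inherits(tsm, "tf_tsm"))
  if (ncol(tsm$f) < 1) abort("TSM has no columns")
  z <- colSums(tsm$f == 0)
  zbar <- mean(z)
  drop <- z > zbar
  if (any(drop)) {
    inform(paste0("filter_sparse: removed ", sum(drop),
                  " column(s) with > ", signif(zbar, 4), " zero entries: ",
                  paste(names(z)[drop], collapse = ", ")))
  }
  removed <- bind_rows(tsm$removed, tibble(
    filter = "sparse", matrix_id = names(z)[drop],
    value = as.double(unname(z[drop])), threshold = zbar
  ))
  new_tsm(tsm$f[, !drop, drop = FALSE], sigma = tsm$sigma, removed = removed)
}
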