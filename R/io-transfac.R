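#' Read TRANSFAC-style position count matrices
#'
#' Parses a TRANSFAC-flavoured flat file of motif count matrices.  Each
#' block starts with an `ID` line, has a `PO` (or `P0`) header naming the
#' base columns, one numbered row of A/C/G/T counts per motif position,
#' and ends at `//` or at the next `ID`.  Counts are preserved exactly.
#'
#' @param path Path to the matrix flat file.
#' @return A tibble with one row per matrix: `matrix_id`, `length`,
#'   `consensus` (IUPAC-free majority-base string, ties broken A<C<G<T) and
#'   a list-column `counts` holding the 4 x L count matrix (rows A,C,G,T).
#' @export
read_transfac_matrices <- function(path) {
  if (!file.exists(path)) abort(paste0("matrix file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  # split into blocks on ID lines
  id_at <- grep("^ID\\s+", lines)
  if (!length(id_at)) {
    if (all(!nzchar(trimws(lines)))) return(tibble(
      matrix_id = character(), length = integer(),
      consensus = character(), counts = list()
    ))
    abort(paste0("no ID lines found in ", path))
  }
  ends <- c(id_at[-1] - 1L, length(lines))
  pwms <- purrr::map2(id_at, ends, function(from, to) {
    block <- lines[from:to]
    matrix_id <- trimws(sub("^ID\\s+", "", block[1]))
    po <- grep("^P[O0]\\b", block)
    if (!length(po)) {
      abort(paste0("matrix block '", matrix_id, "' lacks a PO header"))
    }
    header <- strsplit(trimws(sub("^P[O0]", "", block[po[1]])), "\\s+")[[1]]
    base_cols <- match(.DNA_BASES, toupper(header))
    if (anyNA(base_cols)) {
      abort(paste0("matrix block '", matrix_id, "' PO header lacks A/C/G/T columns"))
    }
    body <- block[seq(po[1] + 1L, length(block))]
    body <- body[!grepl("^(//|XX)", body) & nzchar(trimws(body))]
    rows <- grep("^\\s*\\d+", body, value = TRUE)
    if (!length(rows)) {
      abort(paste0("matrix block '", matrix_id, "' has no position rows"))
    }
    vals <- purrr::map(rows, function(r) {
      f <- strsplit(trimws(r), "\\s+")[[1]][-1]  # drop the position index
      v <- suppressWarnings(as.numeric(f[base_cols]))
      if (anyNA(v)) {
        abort(paste0("non-numeric count in matrix '", matrix_id, "' row: ", r))
      }
      v
    })
    counts <- t(do.call(rbind, vals))  # 4 x L
    rownames(counts) <- .DNA_BASES
    if (any(colSums(counts) <= 0)) {
      abort(paste0("matrix '", matrix_id, "' has an all-zero column"))
    }
    if (ncol(counts) < 1) abort(paste0("matrix '", matrix_id, "' is empty"))
    list(matrix_id = matrix_id, counts = counts)
  })
  tibble(
    matrix_id = purrr::map_chr(pwms, "matrix_id"),
    length = purrr::map_int(pwms, ~ ncol(.x$counts)),
    consensus = purrr::map_chr(pwms, ~ pwm_consensus(.x$counts)),
    counts = purrr::map(pwms, "counts")
  )
}

#' Majority-base consensus of a count matrix
#'
#' @param counts 4 x L count matrix with rows A,C,G,T.
#' @return Consensus string; per-column ties resolve in A<C<G<T order.
#' @export
pwm_consensus <- function(counts) {
  paste0(.DNA_BASES[apply(counts, 2, which.max)], collapse = "")
}

#' Build a PWM table from consensus strings
#'
#' Convenience constructor producing the same tibble layout as
#' [read_transfac_matrices()] from named consensus sequences (count 1 for
#' the consensus base, 0 otherwise).
#'
#' @param motifs Named character vector of consensus strings.
#' @return PWM tibble (`matrix_id`, `length`, `consensus`, `counts`).
#' @export
consensus_pwms <- function(motifs) {
  stopifnot(length(motifs) > 0, !is.null(names(motifs)), all(nzchar(names(motifs))))
  tibble(
    matrix_id = names(motifs),
    length = nchar(motifs),
    consensus = toupper(unname(motifs)),
    counts = purrr::map(toupper(motifs), function(m) {
      bases <- strsplit(m, "")[[1]]
      stopifnot(all(bases %in% .DNA_BASES))
      cm <- matrix(0, 4, length(bases), dimnames = list(.DNA_BASES, NULL))
      cm[cbind(match(bases, .DNA_BASES), seq_along(bases))] <- 1
      cm
    })
  )
}
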