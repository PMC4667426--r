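#' Read a TFBS hit table
#'
#' Reads predicted binding sites from a tab-separated table with columns
#' `sequence_id`, `matrix_id`, `start`, `end`, `strand`, `score`.
#' Coordinates are 0-based half-open on the forward strand of the stored
#' sequence (the convention is restated in a `#` comment line by
#' [write_hits()]; comment lines are skipped on input).  Hit tables let the
#' pipeline consume sites from any external scanner.
#'
#' @param path Path to the hit TSV.
#' @param promoters Optional promoter tibble; if given, hits naming unknown
#'   sequences trigger a warning.
#' @return A hits tibble: `seq_id`, `matrix_id`, `start`, `end`, `strand`,
#'   `score`.
#' @export
read_hits <- function(path, promoters = NULL) {
  if (!file.exists(path)) abort(paste0("hit table not found: ", path))
  tbl <- readr::read_tsv(
    path, comment = "#",
    col_types = readr::cols(
      sequence_id = readr::col_character(),
      matrix_id = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      strand = readr::col_character(),
      score = readr::col_double()
    )
  )
  need <- c("sequence_id", "matrix_id", "start", "end", "strand", "score")
  if (!all(need %in% names(tbl))) {
    abort(paste0("hit table must have columns: ", paste(need, collapse = ", ")))
  }
  bad_iv <- which(tbl$start >= tbl$end)
  if (length(bad_iv)) {
    abort(paste0("start >= end in hit table row(s): ",
                 paste(head(bad_iv, 5), collapse = ", ")))
  }
  bad_strand <- which(!tbl$strand %in% c("+", "-"))
  if (length(bad_strand)) {
    abort(paste0("strand outside {+,-} in row(s): ",
                 paste(head(bad_strand, 5), collapse = ", ")))
  }
  hits <- tbl %>% rename(seq_id = "sequence_id")
  if (!is.null(promoters)) {
    unknown <- setdiff(hits$seq_id, promoters$seq_id)
    if (length(unknown)) {
      warn(paste0("hits reference unknown sequence id(s): ",
                  paste(unknown, collapse = ", ")))
    }
  }
  hits
}

#' Write a TFBS hit table
#'
#' Inverse of [read_hits()]; emits the documented TSV with a coordinate
#' convention comment line, so `read_hits(write_hits(h))` round-trips.
#'
#' @param hits Hits tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# coordinates: 0-based half-open, forward strand", con)
  out <- hits %>%
    select(sequence_id = "seq_id", "matrix_id", "start", "end", "strand", "score")
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(lapply(out, format_plain), sep = "\t")), con)
  }
  invisible(path)
}

# format numbers without scientific notation / trailing spaces
format_plain <- function(x) {
  if (is.double(x)) format(x, trim = TRUE, scientific = FALSE) else as.character(x)
}
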