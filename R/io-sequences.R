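#' Read promoter sequences from a FASTA file
#'
#' Reads a promoter set into the tibble format used throughout the package:
#' one row per sequence with its DNA string and the 0-based offset of the
#' transcription start site (TSS) within the sequence.  By default the TSS
#' is placed at the 3' end of each sequence (`tss_offset = nchar(seq)`),
#' matching the common "N bp upstream of the TSS" promoter window.  For
#' windows that extend downstream of the TSS (e.g. 500 bp upstream plus
#' 100 bp downstream), give `downstream` so that
#' `tss_offset = nchar(seq) - downstream`, or supply exact per-sequence
#' offsets via `tss`.
#'
#' @param path Path to a FASTA file.
#' @param tss Optional per-sequence TSS offsets: either a data frame with
#'   columns `seq_id` and `tss_offset`, or a path to a tab-separated file
#'   with those columns.  Offsets are 0-based positions within the sequence.
#' @param downstream Optional single integer: number of bases of the window
#'   that lie downstream of the TSS.  Ignored for sequences covered by `tss`.
#' @return A tibble with columns `seq_id`, `seq`, `length`, `tss_offset`,
#'   and (all `NA` until filled by [attach_intervals()]) `chrom`, `g_start`,
#'   `g_end`.
#' @seealso [deduplicate_promoters()], [scan_pwm()], [scan_consensus()]
#' @export
read_promoters <- function(path, tss = NULL, downstream = NULL) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path),
      error = function(e) abort(paste0("malformed FASTA in ", path, ": ",
                                       conditionMessage(e)))
    ),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        abort(paste0("sequence(s) with characters outside {A,C,G,T,N} in ",
                     path))
      }
      invokeRestart("muffleWarning")
    }
  )
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence ids in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0("sequence(s) with characters outside {A,C,G,T,N}: ",
                 paste(ids[bad], collapse = ", ")))
  }
  out <- tibble(
    seq_id = unname(ids),
    seq = unname(seqs),
    length = unname(nchar(seqs)),
    tss_offset = unname(nchar(seqs)),
    chrom = NA_character_,
    g_start = NA_integer_,
    g_end = NA_integer_
  )
  if (!is.null(downstream)) {
    stopifnot(length(downstream) == 1L, downstream >= 0)
    out$tss_offset <- pmax(0L, out$length - as.integer(downstream))
  }
  if (!is.null(tss)) {
    tss_tbl <- if (is.character(tss)) {
      readr::read_tsv(tss, col_types = readr::cols(
        seq_id = readr::col_character(),
        tss_offset = readr::col_integer()
      ))
    } else {
      as_tibble(tss)
    }
    unknown <- setdiff(tss_tbl$seq_id, out$seq_id)
    if (length(unknown)) {
      warn(paste0("TSS sidecar names unknown sequence(s): ",
                  paste(unknown, collapse = ", ")))
    }
    idx <- match(out$seq_id, tss_tbl$seq_id)
    hit <- !is.na(idx)
    out$tss_offset[hit] <- as.integer(tss_tbl$tss_offset[idx[hit]])
  }
  if (any(out$tss_offset < 0 | out$tss_offset > out$length)) {
    abort("tss_offset outside [0, sequence length]")
  }
  out
}

#' Attach genomic intervals to promoter records
#'
#' Joins a BED-like interval table (`seq_id`, `chrom`, `g_start`, `g_end`;
#' 0-based half-open) onto a promoter tibble, for use by
#' [deduplicate_promoters()].
#'
#' @param promoters Promoter tibble from [read_promoters()].
#' @param intervals Data frame or TSV path with columns `seq_id`, `chrom`,
#'   `g_start`, `g_end`.
#' @return The promoter tibble with interval columns filled in.
#' @export
attach_intervals <- function(promoters, intervals) {
  tbl <- if (is.character(intervals)) {
    readr::read_tsv(intervals, col_types = readr::cols(
      seq_id = readr::col_character(),
      chrom = readr::col_character(),
      g_start = readr::col_integer(),
      g_end = readr::col_integer()
    ))
  } else {
    as_tibble(intervals)
  }
  idx <- match(promoters$seq_id, tbl$seq_id)
  hit <- !is.na(idx)
  promoters$chrom[hit] <- tbl$chrom[idx[hit]]
  promoters$g_start[hit] <- as.integer(tbl$g_start[idx[hit]])
  promoters$g_end[hit] <- as.integer(tbl$g_end[idx[hit]])
  promoters
}

#' Drop promoters whose genomic windows overlap
#'
#' Multiple annotated TSSs of the same gene produce highly correlated
#' promoter windows, which over-counts the binding sites they contain.
#' This filter keeps only sequences whose genomic interval overlaps no
#' other record's interval; *both* members of an overlapping pair are
#' removed.  Intervals are 0-based half-open, so touching windows
#' (`[0,1000)` and `[1000,2000)`) do not overlap.  Records without an
#' interval pass through with a warning.
#'
#' @param promoters Promoter tibble with `chrom`, `g_start`, `g_end` filled
#'   (see [attach_intervals()]).
#' @return The subset of `promoters` with pairwise non-overlapping windows.
#' @export
deduplicate_promoters <- function(promoters) {
  has_iv <- !is.na(promoters$chrom) & !is.na(promoters$g_start) & !is.na(promoters$g_end)
  if (any(!has_iv)) {
    warn(paste0(sum(!has_iv), " promoter(s) lack genomic intervals; passed through unfiltered"))
  }
  iv <- promoters[has_iv, ]
  if (nrow(iv) > 1) {
    keep <- vapply(seq_len(nrow(iv)), function(i) {
      same <- iv$chrom == iv$chrom[i] &
        iv$g_start < iv$g_end[i] & iv$g_end > iv$g_start[i]
      sum(same) == 1L  # overlaps only itself
    }, logical(1))
    dropped <- iv$seq_id[!keep]
    if (length(dropped)) {
      inform(paste0("deduplicate_promoters: dropped ", length(dropped),
                    " overlapping promoter(s)"))
    }
    iv <- iv[keep, ]
  }
  bind_rows(iv, promoters[!has_iv, ]) %>%
    arrange(match(.data$seq_id, promoters$seq_id))
}

#' Write promoter sequences to FASTA
#'
#' @param promoters Promoter tibble.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(promoters, path) {
  set <- Biostrings::DNAStringSet(setNames(promoters$seq, promoters$seq_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
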