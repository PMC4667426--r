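#' Configuration for the spike-in validation simulator
#'
#' The simulator emulates the planted-pair positive control: a set of
#' promoter-like background sequences at human-genome-like GC content in
#' which one designated TFBS pair is inserted several times per sequence
#' at tightly constrained spacing, alongside independently placed decoy
#' motifs that supply a realistic (positionally uncoupled) candidate-pair
#' universe.
#'
#' Decoy abundance follows a fixed log-spaced per-type profile whose mean
#' equals `decoy_rate`: real promoter scans yield heavy-tailed per-motif
#' hit counts (a few promiscuous motifs, many rare ones), and the matrix
#' filters are designed around that heterogeneity.  Set
#' `decoy_spread = 0` for a homogeneous rate.
#'
#' @param n_sequences Number of background sequences (default 200).
#' @param seq_length Length of each sequence in bp (default 1000).
#' @param gc_content Background GC fraction (default 0.41, human-like).
#' @param pair_motifs Named character vector of the two planted consensus
#'   motifs.  Defaults to an IRF-like element and a (non-palindromic)
#'   USF-type E-box.  `NULL` disables pair planting (decoy-only null data).
#' @param insertions_per_sequence Integer range `c(min, max)` of planted
#'   pair copies per sequence (default `c(2, 12)`).
#' @param gap_range Integer range of background bp between the two motifs
#'   of a planted copy (default `c(5, 20)`).
#' @param decoy_motifs Named character vector of decoy consensus motifs
#'   (default: 12 built-in motifs of varied length and GC).
#' @param decoy_rate Mean decoy insertions per sequence per motif type
#'   (default 3, Poisson).
#' @param decoy_spread Half-range, in log2 units, of the per-type decoy
#'   abundance profile around `decoy_rate` (default 2.5).
#' @param random_strand Insert motifs in random orientation (default
#'   FALSE: forward strand).
#' @param seed Integer seed making the whole simulation reproducible.
#' @return A `spikein_config` list.
#' @export
spikein_config <- function(n_sequences = 200,
                           seq_length = 1000,
                           gc_content = 0.41,
                           pair_motifs = c(IRF1 = "AAAGTGAAAG",
                                           USF1 = "CACGTGAC"),
                           insertions_per_sequence = c(2L, 12L),
                           gap_range = c(5L, 20L),
                           decoy_motifs = default_decoy_motifs(),
                           decoy_rate = 3,
                           decoy_spread = 2.5,
                           random_strand = FALSE,
                           seed = 1L) {
  stopifnot(n_sequences >= 0, seq_length > 0,
            gc_content > 0, gc_content < 1,
            is.null(pair_motifs) || length(pair_motifs) == 2,
            length(insertions_per_sequence) == 2,
            insertions_per_sequence[1] <= insertions_per_sequence[2],
            length(gap_range) == 2, gap_range[1] <= gap_range[2],
            gap_range[1] >= 0, decoy_rate >= 0, decoy_spread >= 0)
  structure(list(
    n_sequences = as.integer(n_sequences),
    seq_length = as.integer(seq_length),
    gc_content = gc_content,
    pair_motifs = if (is.null(pair_motifs)) NULL else toupper(pair_motifs),
    insertions_per_sequence = as.integer(insertions_per_sequence),
    gap_range = as.integer(gap_range),
    decoy_motifs = toupper(decoy_motifs),
    decoy_rate = decoy_rate,
    decoy_spread = decoy_spread,
    random_strand = isTRUE(random_strand),
    seed = as.integer(seed)
  ), class = "spikein_config")
}

#' Built-in decoy consensus motifs
#'
#' Twelve consensus strings of varied length (6-10 bp) and GC content,
#' loosely modelled on common vertebrate promoter motifs.  They are
#' planted independently of each other and of the pair, so any apparent
#' co-occurrence among them is chance.
#'
#' @return Named character vector of 12 motifs.
#' @export
default_decoy_motifs <- function() {
  c(SP1   = "GGGGCGGGG",
    NFY   = "CCAATCAG",
    TATA  = "TATAAATG",
    CREB  = "TGACGTCA",
    ETS   = "ACAGGAAGT",
    GATA  = "AGATAAGG",
    NFKB  = "GGGACTTTCC",
    OCT   = "ATGCAAAT",
    MEF2  = "CTAAAAATAG",
    HNF4  = "GGGTCAAAGGTCA",
    STAT  = "TTCCCGGAA",
    AP2   = "GCCCCAGGC")
}

#' Generate i.i.d. promoter-like background sequences
#'
#' Bases are drawn independently with `P(G) + P(C) = gc_content` (G and C
#' equiprobable, A and T equiprobable).  The TSS sits at the 3' end of
#' each sequence (`tss_offset = seq_length`), matching an upstream
#' promoter window.  Deterministic under `cfg$seed`.
#'
#' @param cfg A [spikein_config()].
#' @return Promoter tibble with sequences `sim_001`, `sim_002`, ...
#' @export
generate_background <- function(cfg) {
  stopifnot(inherits(cfg, "spikein_config"))
  withr::with_seed(cfg$seed, generate_background_impl(cfg))
}

generate_background_impl <- function(cfg) {
  if (cfg$n_sequences == 0) {
    return(tibble(seq_id = character(), seq = character(), length = integer(),
                  tss_offset = integer(), chrom = NA_character_,
                  g_start = NA_integer_, g_end = NA_integer_))
  }
  p <- c(A = (1 - cfg$gc_content) / 2, C = cfg$gc_content / 2,
         G = cfg$gc_content / 2, T = (1 - cfg$gc_content) / 2)
  seqs <- vapply(seq_len(cfg$n_sequences), function(i) {
    paste0(sample(.DNA_BASES, cfg$seq_length, replace = TRUE, prob = p),
           collapse = "")
  }, character(1))
  tibble(
    seq_id = sprintf("sim_%03d", seq_len(cfg$n_sequences)),
    seq = seqs,
    length = cfg$seq_length,
    tss_offset = cfg$seq_length,
    chrom = NA_character_, g_start = NA_integer_, g_end = NA_integer_
  )
}

# place one block of `len` bp uniformly over the start positions whose
# half-open interval avoids `occupied` (two-column matrix); NULL if no
# feasible start remains
place_block <- function(len, seq_length, occupied) {
  if (seq_length < len) return(NULL)
  if (!nrow(occupied)) {
    s <- sample.int(seq_length - len + 1L, 1L) - 1L
    return(c(s, s + len))
  }
  occ <- occupied[order(occupied[, 1]), , drop = FALSE]
  # merge and walk the free gaps, collecting feasible start ranges
  starts <- integer(0)
  gap_from <- 0
  for (k in seq_len(nrow(occ))) {
    gap_to <- occ[k, 1]           # free gap [gap_from, gap_to)
    if (gap_to - gap_from >= len) {
      starts <- c(starts, gap_from:(gap_to - len))
    }
    gap_from <- max(gap_from, occ[k, 2])
  }
  if (seq_length - gap_from >= len) {
    starts <- c(starts, gap_from:(seq_length - len))
  }
  if (!length(starts)) return(NULL)
  s <- starts[sample.int(length(starts), 1L)]
  c(s, s + len)
}

splice_in <- function(seq, start, what) {
  paste0(substr(seq, 1, start), what,
         substr(seq, start + nchar(what) + 1, nchar(seq)))
}

#' Plant the coupled motif pair into background sequences
#'
#' Per sequence, `k` copies of the pair are inserted, with `k` uniform on
#' `insertions_per_sequence`.  Each copy writes motif A, then `g` bp of
#' the untouched background (`g` uniform on `gap_range`), then motif B,
#' at a uniformly chosen non-overlapping position; sequence length is
#' preserved (the motifs overwrite background).  Every insertion is
#' recorded in the returned truth table.
#'
#' @param promoters Promoter tibble (typically from
#'   [generate_background()]).
#' @param cfg A [spikein_config()] with non-NULL `pair_motifs`.
#' @return List with `promoters` (modified sequences) and `truth`
#'   (tibble `seq_id`, `copy`, `start_a`, `end_a`, `start_b`, `end_b`,
#'   `gap`, `strand`).  Deterministic under `cfg$seed`.
#' @export
plant_pairs <- function(promoters, cfg) {
  stopifnot(inherits(cfg, "spikein_config"), !is.null(cfg$pair_motifs))
  withr::with_seed(cfg$seed + 1L, plant_pairs_impl(promoters, cfg))
}

plant_pairs_impl <- function(promoters, cfg) {
  ma <- cfg$pair_motifs[[1]]
  mb <- cfg$pair_motifs[[2]]
  la <- nchar(ma); lb <- nchar(mb)
  if (la + cfg$gap_range[2] + lb > cfg$seq_length) {
    abort("pair motifs plus maximal gap do not fit in seq_length")
  }
  acc <- list(seq_id = character(), copy = integer(), start_a = integer(),
              end_a = integer(), start_b = integer(), end_b = integer(),
              gap = integer(), strand = character())
  for (i in seq_len(nrow(promoters))) {
    k <- sample(seq(cfg$insertions_per_sequence[1],
                    cfg$insertions_per_sequence[2]), 1L)
    occ <- matrix(numeric(0), ncol = 2)
    s <- promoters$seq[i]
    for (cpy in seq_len(k)) {
      g <- sample(seq(cfg$gap_range[1], cfg$gap_range[2]), 1L)
      block_len <- la + g + lb
      pos <- place_block(block_len, nchar(s), occ)
      if (is.null(pos)) {
        abort(paste0("could not place pair insertion ", cpy, " in sequence ",
                     promoters$seq_id[i], " without overlap"))
      }
      strand <- if (cfg$random_strand && runif(1) < 0.5) "-" else "+"
      block <- if (strand == "+") {
        paste0(ma, substr(s, pos[1] + la + 1, pos[1] + la + g), mb)
      } else {
        .rev_comp(paste0(ma, substr(s, pos[1] + la + 1, pos[1] + la + g), mb))
      }
      s <- splice_in(s, pos[1], block)
      occ <- rbind(occ, pos)
      # on "-" the block is reverse-complemented, so motif B leads
      if (strand == "+") {
        sa <- pos[1]; sb <- pos[1] + la + g
      } else {
        sb <- pos[1]; sa <- pos[1] + lb + g
      }
      acc$seq_id <- c(acc$seq_id, promoters$seq_id[i])
      acc$copy <- c(acc$copy, cpy)
      acc$start_a <- c(acc$start_a, as.integer(sa))
      acc$end_a <- c(acc$end_a, as.integer(sa + la))
      acc$start_b <- c(acc$start_b, as.integer(sb))
      acc$end_b <- c(acc$end_b, as.integer(sb + lb))
      acc$gap <- c(acc$gap, as.integer(g))
      acc$strand <- c(acc$strand, strand)
    }
    promoters$seq[i] <- s
  }
  list(promoters = promoters, truth = as_tibble(acc))
}

#' Plant independent decoy motifs
#'
#' Each decoy type is inserted into each sequence an independent
#' Poisson-distributed number of times (per-type mean from the log-spaced
#' abundance profile, see [spikein_config()]), at uniform non-overlapping
#' positions; there is no positional coupling between types, so decoy
#' pairs arise only by chance.
#'
#' @param promoters Promoter tibble.
#' @param cfg A [spikein_config()].
#' @param avoid Optional truth table from [plant_pairs()] (or any tibble
#'   with `seq_id`, `start_a`/`start_b`, `end_a`/`end_b`) whose intervals
#'   must not be overwritten.
#' @return List with `promoters` and `truth` (tibble `seq_id`,
#'   `matrix_id`, `start`, `end`, `strand`).  Deterministic under
#'   `cfg$seed`.
#' @export
plant_decoys <- function(promoters, cfg, avoid = NULL) {
  stopifnot(inherits(cfg, "spikein_config"))
  withr::with_seed(cfg$seed + 2L, plant_decoys_impl(promoters, cfg, avoid))
}

#' Per-type decoy insertion rates
#'
#' Log-spaced profile over the decoy types, scaled so its mean equals
#' `decoy_rate`.
#'
#' @param cfg A [spikein_config()].
#' @return Named numeric vector of Poisson means, one per decoy type.
#' @export
decoy_rates <- function(cfg) {
  n <- length(cfg$decoy_motifs)
  if (n == 0) return(setNames(numeric(0), character(0)))
  prof <- if (n == 1 || cfg$decoy_spread == 0) {
    rep(1, n)
  } else {
    2^seq(-cfg$decoy_spread, cfg$decoy_spread, length.out = n)
  }
  setNames(cfg$decoy_rate * prof / mean(prof), names(cfg$decoy_motifs))
}

plant_decoys_impl <- function(promoters, cfg, avoid) {
  rates <- decoy_rates(cfg)
  if (!length(rates) || cfg$decoy_rate == 0) {
    return(list(promoters = promoters,
                truth = tibble(seq_id = character(), matrix_id = character(),
                               start = integer(), end = integer(),
                               strand = character())))
  }
  avoid_by_seq <- split_avoid(avoid, promoters$seq_id)
  acc <- list(seq_id = character(), matrix_id = character(),
              start = integer(), end = integer(), strand = character())
  for (i in seq_len(nrow(promoters))) {
    occ0 <- avoid_by_seq[[promoters$seq_id[i]]]
    if (is.null(occ0)) occ0 <- matrix(numeric(0), ncol = 2)
    placed <- NULL
    # the Poisson load is conditioned on physical feasibility: if a draw
    # cannot fit beside the planted pairs, the whole per-sequence decoy
    # set is redrawn (a promoter cannot hold more sites than fit)
    for (attempt in 1:50) {
      placed <- try_place_decoys(promoters$seq[i], occ0, rates,
                                 cfg$decoy_motifs, cfg$random_strand)
      if (!is.null(placed)) break
    }
    if (is.null(placed)) {
      abort(paste0("could not place decoys in sequence ",
                   promoters$seq_id[i], " without overlap"))
    }
    promoters$seq[i] <- placed$seq
    k <- length(placed$start)
    if (k) {
      acc$seq_id <- c(acc$seq_id, rep(promoters$seq_id[i], k))
      acc$matrix_id <- c(acc$matrix_id, placed$matrix_id)
      acc$start <- c(acc$start, placed$start)
      acc$end <- c(acc$end, placed$end)
      acc$strand <- c(acc$strand, placed$strand)
    }
  }
  list(promoters = promoters, truth = as_tibble(acc))
}

# One attempt at drawing and placing a full decoy set for one sequence.
# Counts are Poisson per type; long motifs are placed first so that
# fragmentation never starves them.  NULL when the draw does not fit.
try_place_decoys <- function(s, occ, rates, motifs, random_strand) {
  cnt <- rpois(length(rates), rates)
  todo <- rep(seq_along(rates), cnt)
  todo <- todo[order(-nchar(motifs[todo]), todo)]
  out <- list(matrix_id = character(0), start = integer(0),
              end = integer(0), strand = character(0))
  for (d in todo) {
    m <- motifs[[d]]
    pos <- place_block(nchar(m), nchar(s), occ)
    if (is.null(pos)) return(NULL)
    strand <- if (random_strand && runif(1) < 0.5) "-" else "+"
    s <- splice_in(s, pos[1], if (strand == "+") m else .rev_comp(m))
    occ <- rbind(occ, pos)
    out$matrix_id <- c(out$matrix_id, names(motifs)[d])
    out$start <- c(out$start, as.integer(pos[1]))
    out$end <- c(out$end, as.integer(pos[2]))
    out$strand <- c(out$strand, strand)
  }
  c(list(seq = s), out)
}

split_avoid <- function(avoid, seq_ids) {
  if (is.null(avoid) || !nrow(avoid)) return(list())
  ivs <- if (all(c("start_a", "end_a", "start_b", "end_b") %in% names(avoid))) {
    bind_rows(
      tibble(seq_id = avoid$seq_id, s = avoid$start_a, e = avoid$end_a),
      tibble(seq_id = avoid$seq_id, s = avoid$start_b, e = avoid$end_b)
    )
  } else {
    tibble(seq_id = avoid$seq_id, s = avoid$start, e = avoid$end)
  }
  lapply(split(ivs, ivs$seq_id), function(g) cbind(g$s, g$e))
}

#' Simulate a complete spike-in dataset
#'
#' Background generation, pair planting (unless `cfg$pair_motifs` is
#' NULL) and decoy planting in one reproducible call.
#'
#' @param cfg A [spikein_config()].
#' @return List with `promoters`, `truth` (planted-pair table; empty when
#'   planting is disabled), `decoy_truth`, and `cfg`.
#' @export
simulate_spikein <- function(cfg) {
  stopifnot(inherits(cfg, "spikein_config"))
  promoters <- generate_background(cfg)
  if (!is.null(cfg$pair_motifs) && nrow(promoters)) {
    planted <- plant_pairs(promoters, cfg)
    promoters <- planted$promoters
    truth <- planted$truth
  } else {
    truth <- tibble(seq_id = character(), copy = integer(),
                    start_a = integer(), end_a = integer(),
                    start_b = integer(), end_b = integer(),
                    gap = integer(), strand = character())
  }
  decoys <- plant_decoys(promoters, cfg, avoid = truth)
  list(promoters = decoys$promoters, truth = truth,
       decoy_truth = decoys$truth, cfg = cfg)
}

#' All motifs of a spike-in configuration
#'
#' Named vector combining the planted pair (if any) and the decoys, ready
#' for [scan_consensus()].
#'
#' @param cfg A [spikein_config()].
#' @return Named character vector.
#' @export
spikein_motifs <- function(cfg) {
  c(if (!is.null(cfg$pair_motifs)) cfg$pair_motifs, cfg$decoy_motifs)
}
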