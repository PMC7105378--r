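## Amplicon array parsing: fuzzy direct-repeat detection, spacer extraction
## between repeats, clonality barcodes, and per-colony read-class profiles.

#' Repeat model for array parsing
#'
#' @param repeat_seq direct repeat DNA string.
#' @param max_mismatches substitutions tolerated per repeat copy; must be
#'   less than half the repeat length.
#' @param min_spacer_len,max_spacer_len accepted inter-repeat segment
#'   lengths (defaults 20-45 nt, permissive for a ~30 nt type II spacer).
#' @return object of class `repeat_model`.
#' @export
repeat_model <- function(repeat_seq, max_mismatches = 2L,
                         min_spacer_len = 20L, max_spacer_len = 45L) {
  repeat_seq <- toupper(repeat_seq)
  if (max_mismatches < 0 || max_mismatches >= nchar(repeat_seq) / 2)
    cc_stop("crisprcolony_config_error",
            "max_mismatches must satisfy 0 <= m < repeat length / 2")
  if (min_spacer_len > max_spacer_len)
    cc_stop("crisprcolony_config_error",
            "min_spacer_len must not exceed max_spacer_len")
  structure(list(repeat_seq = repeat_seq,
                 max_mismatches = as.integer(max_mismatches),
                 min_spacer_len = as.integer(min_spacer_len),
                 max_spacer_len = as.integer(max_spacer_len)),
            class = "repeat_model")
}

#' Find direct-repeat copies in a read
#'
#' All non-overlapping occurrences of the repeat with at most
#' `max_mismatches` substitutions, selected greedily left to right (among
#' candidates starting before the current position's end, the leftmost is
#' taken; equal starts are impossible for a fixed-length pattern). Reads are
#' scanned in sequencing orientation only: the amplicon primers fix the
#' orientation, so no reverse-complement pass.
#'
#' @param read DNA string over A/C/G/T/N (N never matches, i.e. counts as a
#'   mismatch).
#' @param model a [repeat_model()].
#' @return data.frame with columns `start` (1-based) and `mismatches`,
#'   leftmost first; zero rows when nothing matches.
#' @export
find_repeats <- function(read, model) {
  w <- nchar(model$repeat_seq)
  empty <- data.frame(start = integer(0), mismatches = integer(0))
  if (nchar(read) < w) return(empty)
  m <- Biostrings::matchPattern(model$repeat_seq, Biostrings::DNAString(read),
                                max.mismatch = model$max_mismatches,
                                with.indels = FALSE, fixed = TRUE)
  starts <- Biostrings::start(m)
  starts <- starts[starts >= 1L & starts + w - 1L <= nchar(read)]
  if (length(starts) == 0L) return(empty)
  mism <- Biostrings::neditStartingAt(Biostrings::DNAString(model$repeat_seq),
                                      Biostrings::DNAString(read),
                                      starting.at = starts,
                                      with.indels = FALSE, fixed = TRUE)
  greedy_nonoverlap(starts, mism, w)
}

## greedy left-to-right non-overlapping selection shared by the per-read
## and batched paths
greedy_nonoverlap <- function(starts, mism, w) {
  ord <- order(starts, mism)
  starts <- starts[ord]; mism <- mism[ord]
  keep <- logical(length(starts))
  next_free <- 1L
  for (i in seq_along(starts)) {
    if (starts[i] >= next_free) {
      keep[i] <- TRUE
      next_free <- starts[i] + w
    }
  }
  data.frame(start = as.integer(starts[keep]),
             mismatches = as.integer(mism[keep]))
}

## batched find_repeats over many reads: one vmatchPattern call, mismatch
## counts recomputed vectorized in R (per-call S4 overhead dominates the
## per-read path at scale)
find_repeats_batch <- function(seqs, model) {
  w <- nchar(model$repeat_seq)
  subj <- Biostrings::DNAStringSet(seqs)
  ml <- Biostrings::vmatchPattern(model$repeat_seq, subj,
                                  max.mismatch = model$max_mismatches,
                                  fixed = TRUE)
  starts_l <- IRanges::start(ml)
  n_hits <- lengths(starts_l)
  read_idx <- rep(seq_along(seqs), n_hits)
  starts <- unlist(starts_l, use.names = FALSE)
  ok <- starts >= 1L & starts + w - 1L <= nchar(seqs)[read_idx]
  read_idx <- read_idx[ok]; starts <- starts[ok]
  if (length(starts) == 0L)
    return(rep(list(data.frame(start = integer(0), mismatches = integer(0))),
               length(seqs)))
  hit_seq <- substring(seqs[read_idx], starts, starts + w - 1L)
  repv <- strsplit(model$repeat_seq, "")[[1]]
  mism <- colSums(matrix(unlist(strsplit(hit_seq, ""), use.names = FALSE),
                         nrow = w) != repv)
  out <- rep(list(data.frame(start = integer(0), mismatches = integer(0))),
             length(seqs))
  for (grp in split(seq_along(starts), read_idx)) {
    i <- read_idx[grp[1L]]
    out[[i]] <- greedy_nonoverlap(starts[grp], mism[grp], w)
  }
  out
}

#' Spacer array from one read
#'
#' @param spacers character vector of spacer sequences, leader-proximal
#'   (most recently acquired) first; the founder spacer is therefore last.
#' @param barcode clonality barcode, or `NA` when not sequenced.
#' @param read_id read identifier.
#' @return object of class `spacer_array` with fields `spacers`, `barcode`,
#'   `read_id`, `n_spacers`.
#' @export
spacer_array <- function(spacers, barcode = NA_character_,
                         read_id = NA_character_) {
  structure(list(spacers = as.character(spacers), barcode = barcode,
                 read_id = read_id, n_spacers = length(spacers)),
            class = "spacer_array")
}

#' @export
print.spacer_array <- function(x, ...) {
  cat(sprintf("<spacer_array> %s: %d spacer(s)%s\n",
              x$read_id, x$n_spacers,
              if (is.na(x$barcode)) "" else paste0(", barcode ", x$barcode)))
  invisible(x)
}

#' Extract the spacer array (and barcode) from one read
#'
#' Spacers are the segments between consecutive repeat copies; a read needs
#' at least two repeats to be parseable, and every inter-repeat segment must
#' fall inside the configured length bounds. When `barcode_spec` is given,
#' the barcode is cut from the fixed-width window upstream of the leader
#' (i.e. `barcode_len` bases ending `leader_len` bases before the first
#' repeat).
#'
#' @param read DNA string.
#' @param model a [repeat_model()].
#' @param barcode_spec `NULL`, or `list(leader_len =, barcode_len =)`.
#' @param read_id identifier attached to the result.
#' @param hits optional precomputed [find_repeats()] table for this read.
#' @return a [spacer_array()]. Signals condition
#'   `crisprcolony_unparseable_read` (< 2 repeats) or
#'   `crisprcolony_malformed_array` (segment outside length bounds).
#' @export
extract_array <- function(read, model, barcode_spec = NULL,
                          read_id = NA_character_, hits = NULL) {
  if (is.null(hits)) hits <- find_repeats(read, model)
  if (nrow(hits) < 2L)
    cc_stop("crisprcolony_unparseable_read",
            "read %s: %d repeat copies found, need >= 2", read_id, nrow(hits))
  w <- nchar(model$repeat_seq)
  seg_start <- hits$start[-nrow(hits)] + w
  seg_end <- hits$start[-1L] - 1L
  lens <- seg_end - seg_start + 1L
  if (any(lens < model$min_spacer_len | lens > model$max_spacer_len))
    cc_stop("crisprcolony_malformed_array",
            "read %s: inter-repeat segment length outside [%d, %d]",
            read_id, model$min_spacer_len, model$max_spacer_len)
  spacers <- substring(read, seg_start, seg_end)
  barcode <- NA_character_
  if (!is.null(barcode_spec)) {
    b_end <- hits$start[1L] - barcode_spec$leader_len - 1L
    b_start <- b_end - barcode_spec$barcode_len + 1L
    if (b_start < 1L)
      cc_stop("crisprcolony_malformed_array",
              "read %s: barcode window extends past the read start", read_id)
    barcode <- substr(read, b_start, b_end)
  }
  spacer_array(spacers, barcode = barcode, read_id = read_id)
}

#' Parse a set of amplicon reads
#'
#' Applies [extract_array()] to every read, counting unparseable and
#' malformed reads instead of failing. Conservation holds by construction:
#' `parseable + unparseable + malformed == total`.
#'
#' @param reads character vector of read sequences (names used as read ids
#'   when present), or a `simulated_reads` data.frame.
#' @param model a [repeat_model()].
#' @param barcode_spec see [extract_array()].
#' @return list with `arrays` (list of [spacer_array()]), `stats` (named
#'   counts: total, parseable, unparseable, malformed) and `table` (per-read
#'   data.frame: read_id, barcode, n_spacers, spacers as a
#'   semicolon-joined string).
#' @export
parse_reads <- function(reads, model, barcode_spec = NULL) {
  if (inherits(reads, "simulated_reads") || is.data.frame(reads)) {
    ids <- reads$read_id
    seqs <- reads$sequence
  } else {
    seqs <- as.character(reads)
    ids <- if (!is.null(names(reads))) names(reads) else
      sprintf("read%05d", seq_along(seqs))
  }
  hit_tables <- find_repeats_batch(seqs, model)
  arrays <- vector("list", length(seqs))
  status <- character(length(seqs))
  for (i in seq_along(seqs)) {
    res <- tryCatch(
      extract_array(seqs[i], model, barcode_spec, read_id = ids[i],
                    hits = hit_tables[[i]]),
      crisprcolony_unparseable_read = function(e) "unparseable",
      crisprcolony_malformed_array = function(e) "malformed"
    )
    if (is.character(res)) {
      status[i] <- res
    } else {
      status[i] <- "parseable"
      arrays[[i]] <- res
    }
  }
  ok <- status == "parseable"
  arrays <- arrays[ok]
  tab <- data.frame(
    read_id = vapply(arrays, `[[`, character(1), "read_id"),
    barcode = vapply(arrays, `[[`, character(1), "barcode"),
    n_spacers = vapply(arrays, `[[`, integer(1), "n_spacers"),
    spacers = vapply(arrays, function(a) paste(a$spacers, collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE
  )
  list(
    arrays = arrays,
    stats = c(total = length(seqs), parseable = sum(ok),
              unparseable = sum(status == "unparseable"),
              malformed = sum(status == "malformed")),
    table = tab
  )
}

#' Per-colony read-class profile and mono/multi call
#'
#' Counts reads by spacer number and classifies the colony: `multi` iff the
#' multi-spacer read fraction strictly exceeds the threshold. The default
#' 2\% threshold is the empirical minimal multi-spacer fraction that yields
#' multiple PCR bands from the amplified array.
#'
#' @param arrays list of [spacer_array()] from one colony.
#' @param threshold multi-spacer fraction cutoff in (0, 1), default 0.02.
#' @param colony_id identifier.
#' @return object of class `colony_profile`: list with `colony_id`,
#'   `read_counts_by_n_spacers` (named integer vector), `multi_fraction`
#'   and `colony_call` ("mono" or "multi").
#' @export
profile_colony <- function(arrays, threshold = 0.02, colony_id = "colony1") {
  stopifnot(threshold > 0, threshold < 1)
  n <- vapply(arrays, `[[`, integer(1), "n_spacers")
  n <- n[n >= 1L]
  if (length(n) == 0L)
    cc_stop("crisprcolony_empty_profile",
            "colony %s: no parseable reads with >= 1 spacer", colony_id)
  counts <- table(factor(pmin(n, 5L), levels = 1:5,
                         labels = c("1", "2", "3", "4", "5+")))
  multi_fraction <- sum(n >= 2L) / length(n)
  structure(list(
    colony_id = colony_id,
    read_counts_by_n_spacers = setNames(as.integer(counts), names(counts)),
    multi_fraction = multi_fraction,
    colony_call = if (multi_fraction > threshold) "multi" else "mono"
  ), class = "colony_profile")
}

#' @export
print.colony_profile <- function(x, ...) {
  cat(sprintf("<colony_profile> %s: %s (multi fraction %.3f)\n",
              x$colony_id, x$colony_call, x$multi_fraction))
  print(x$read_counts_by_n_spacers)
  invisible(x)
}

#' Barcode / founder-spacer concordance
#'
#' Groups arrays by barcode and asks whether each group shares a single
#' founder spacer (the chronologically first acquired spacer, i.e. the
#' leader-distal element of each array). Clonal colonies give concordance 1.
#'
#' @param arrays list of [spacer_array()], each with a barcode and >= 1
#'   spacer.
#' @return list with `concordance` (fraction of barcode groups with exactly
#'   one founder), `n_groups`, `flagged` (barcodes with > 1 founder) and
#'   `contingency` (barcode x founder table).
#' @export
barcode_concordance <- function(arrays) {
  bc <- vapply(arrays, `[[`, character(1), "barcode")
  ns <- vapply(arrays, `[[`, integer(1), "n_spacers")
  if (any(is.na(bc)) || any(ns < 1L))
    cc_stop("crisprcolony_precondition_error",
            "every array must carry a barcode and at least one spacer")
  founder <- vapply(arrays, function(a) a$spacers[a$n_spacers], character(1))
  tab <- table(barcode = bc, founder = founder)
  founders_per_group <- rowSums(tab > 0)
  list(
    concordance = mean(founders_per_group == 1L),
    n_groups = nrow(tab),
    flagged = rownames(tab)[founders_per_group > 1L],
    contingency = tab
  )
}
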