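## Primed-acquisition distance analysis: chronological first-to-second
## spacer target distances, the binned distinct-second-spacer histogram,
## and the local enrichment statistic against a uniform-placement null.
##
## "First" and "second" are chronological (acquisition order). New spacers
## insert at the leader, so the chronologically first (founder) spacer is
## the leader-DISTAL element of the array and the second is the element
## just leader-proximal of it.

#' Extract chronological first/second spacer pairs
#'
#' One pair per read with >= 2 spacers: the two leader-distal-most array
#' elements (positions n and n-1 from the leader). Pairs whose members are
#' unmapped or map ambiguously are dropped and counted. For arrays with
#' more than 2 spacers only the (first, second) chronological pair enters
#' the analysis.
#'
#' @param arrays list of [spacer_array()] (leader-proximal first).
#' @param hits hit table from [map_spacers()] covering the spacer
#'   sequences.
#' @return data.frame with one row per usable pair: `read_id`,
#'   `first_spacer`, `second_spacer`, `first_start`, `second_start`,
#'   `first_strand`, `second_strand`, `signed_distance` (bp,
#'   `start(second) - start(first)`). Attributes `n_candidate` (arrays with
#'   >= 2 spacers) and `n_dropped` record the accounting.
#' @export
extract_pairs <- function(arrays, hits) {
  multi <- Filter(function(a) a$n_spacers >= 2L, arrays)
  n_candidate <- length(multi)
  lookup <- hits[!duplicated(hits$spacer), , drop = FALSE]
  rownames(lookup) <- lookup$spacer
  rows <- lapply(multi, function(a) {
    n <- a$n_spacers
    first <- a$spacers[n]            # leader-distal = acquired first
    second <- a$spacers[n - 1L]
    h1 <- lookup[first, ]; h2 <- lookup[second, ]
    if (is.na(h1$spacer) || is.na(h2$spacer) ||
        !h1$mapped || !h2$mapped || h1$ambiguous || h2$ambiguous)
      return(NULL)
    data.frame(read_id = a$read_id, first_spacer = first,
               second_spacer = second,
               first_start = h1$start, second_start = h2$start,
               first_strand = h1$strand, second_strand = h2$strand,
               signed_distance = h2$start - h1$start,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(0), first_spacer = character(0),
               second_spacer = character(0), first_start = integer(0),
               second_start = integer(0), first_strand = character(0),
               second_strand = character(0), signed_distance = integer(0))
  rownames(out) <- NULL
  attr(out, "n_candidate") <- n_candidate
  attr(out, "n_dropped") <- n_candidate - nrow(out)
  out
}

#' Binned histogram of distinct second-spacer target distances
#'
#' Counts DISTINCT second-spacer sequences per signed distance bin: a
#' sequence recurring in many reads contributes once per bin. The origin
#' (0) is each pair's own first-spacer target, so the histogram is
#' invariant to translating all coordinates.
#'
#' @param pairs data.frame from [extract_pairs()].
#' @param bin_width bin width in bp (default 1000).
#' @return data.frame with `bin_start`, `bin_end` (signed, half-open bins;
#'   the bin containing 0 is `[0, bin_width)`) and `distinct_count`.
#' @export
distance_histogram <- function(pairs, bin_width = 1000L) {
  stopifnot(bin_width > 0)
  d <- pairs[!duplicated(paste(pairs$second_spacer,
                               floor(pairs$signed_distance / bin_width))), ,
             drop = FALSE]
  bin <- floor(d$signed_distance / bin_width)
  counts <- table(bin)
  b <- as.integer(names(counts))
  data.frame(bin_start = b * bin_width,
             bin_end = (b + 1L) * bin_width,
             distinct_count = as.integer(counts))
}

#' Local (priming) enrichment of second-spacer targets
#'
#' Fraction of second-spacer targets within `window` bp of the first
#' target, compared with the expectation under uniform placement along the
#' genome (window truncated at the linear genome ends, averaged over the
#' observed first-target positions). `use = "distinct"` counts distinct
#' second-spacer sequences (figure semantics); `use = "pairs"` counts every
#' pair, which is the right scale for recovering the generator's
#' `local_fraction` (distinct counting saturates once the few hundred valid
#' local protospacers are exhausted).
#'
#' @param pairs data.frame from [extract_pairs()].
#' @param genome_length genome length in bp (for the uniform null).
#' @param window half-width in bp (default 500).
#' @param use counting basis, "pairs" or "distinct" (default "pairs").
#' @param expected_fraction optional override of the uniform-null expected
#'   fraction, e.g. the exact share of valid protospacer sites inside the
#'   window when the site list is known.
#' @return list with `n` (counting units), `observed_fraction`,
#'   `expected_fraction` (uniform null), `ratio`, `p_value` (one-sided
#'   binomial tail), `est_local_fraction` (mixture inversion
#'   `(obs - exp) / (1 - exp)`, clamped to [0, 1]) plus the per-basis
#'   observed fractions `observed_fraction_pairs` and
#'   `observed_fraction_distinct`.
#' @export
local_enrichment <- function(pairs, genome_length, window = 500L,
                             use = c("pairs", "distinct"),
                             expected_fraction = NULL) {
  use <- match.arg(use)
  stopifnot(window > 0)
  if (nrow(pairs) == 0L)
    cc_stop("crisprcolony_empty_report", "no spacer pairs to analyze")
  is_local <- abs(pairs$signed_distance) <= window
  obs_pairs <- mean(is_local)
  dd <- pairs[!duplicated(pairs$second_spacer), , drop = FALSE]
  obs_distinct <- mean(abs(dd$signed_distance) <= window)
  ## uniform null: share of the genome within +/- window of each first
  ## target, truncated at the ends
  covered <- pmin(pairs$first_start + window, genome_length - 1L) -
    pmax(pairs$first_start - window, 0L) + 1L
  expected <- if (is.null(expected_fraction)) mean(covered / genome_length)
              else expected_fraction
  if (use == "pairs") {
    k <- sum(is_local); n <- nrow(pairs); obs <- obs_pairs
  } else {
    k <- sum(abs(dd$signed_distance) <= window); n <- nrow(dd)
    obs <- obs_distinct
  }
  list(
    n = n, observed_fraction = obs, expected_fraction = expected,
    ratio = obs / expected,
    p_value = pbinom(k - 1L, n, expected, lower.tail = FALSE),
    est_local_fraction = min(max((obs - expected) / (1 - expected), 0), 1),
    observed_fraction_pairs = obs_pairs,
    observed_fraction_distinct = obs_distinct
  )
}
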