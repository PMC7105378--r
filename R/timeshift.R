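## Time-shift co-evolution analysis: ordinal resistance scores for hosts
## challenged with phage from past, contemporary and future time points,
## averaged per host per phage time point.

#' Resistance matrix for a time-shift assay
#'
#' @param scores numeric hosts x phages matrix with entries in
#'   \{0, 0.5, 1\} or `NA` (missing), dimnames = host/phage ids; or a long
#'   data.frame with columns `host_id`, `host_timepoint`, `phage_id`,
#'   `phage_timepoint`, `score`.
#' @param hosts data.frame `host_id`, `host_timepoint` (hours; 0 = the
#'   founder). Required with a matrix `scores`, derived from the long form
#'   otherwise.
#' @param phages data.frame `phage_id`, `phage_timepoint` (0 = ancestral
#'   stock isolates).
#' @return object of class `resistance_matrix`.
#' @export
resistance_matrix <- function(scores, hosts = NULL, phages = NULL) {
  if (is.data.frame(scores)) {
    long <- scores
    req <- c("host_id", "host_timepoint", "phage_id", "phage_timepoint",
             "score")
    if (!all(req %in% names(long)))
      cc_stop("crisprcolony_input_error",
              "long input needs columns: %s", paste(req, collapse = ", "))
    hosts <- unique(long[c("host_id", "host_timepoint")])
    phages <- unique(long[c("phage_id", "phage_timepoint")])
    scores <- matrix(NA_real_, nrow(hosts), nrow(phages),
                     dimnames = list(hosts$host_id, phages$phage_id))
    scores[cbind(match(long$host_id, hosts$host_id),
                 match(long$phage_id, phages$phage_id))] <- long$score
  }
  vals <- scores[!is.na(scores)]
  if (!all(vals %in% c(0, 0.5, 1)))
    cc_stop("crisprcolony_input_error",
            "scores must be 0, 0.5 or 1 (or missing)")
  stopifnot(nrow(scores) == nrow(hosts), ncol(scores) == nrow(phages))
  rownames(hosts) <- NULL; rownames(phages) <- NULL
  structure(list(scores = scores, hosts = hosts, phages = phages),
            class = "resistance_matrix")
}

#' @export
print.resistance_matrix <- function(x, ...) {
  cat(sprintf(
    "<resistance_matrix> %d hosts x %d phages; host times: %s; phage times: %s\n",
    nrow(x$scores), ncol(x$scores),
    paste(sort(unique(x$hosts$host_timepoint)), collapse = ", "),
    paste(sort(unique(x$phages$phage_timepoint)), collapse = ", ")))
  invisible(x)
}

#' Ordinal resistance score for a spot observation
#'
#' Bacterial growth in the phage spot is full resistance (1), a clear spot
#' is no resistance (0), partial inhibition scores 0.5.
#'
#' @param category character vector over \{"full_resistance",
#'   "no_resistance", "partial"\}.
#' @return numeric vector of scores.
#' @export
score_observation <- function(category) {
  map <- c(full_resistance = 1, no_resistance = 0, partial = 0.5)
  if (!all(category %in% names(map)))
    cc_stop("crisprcolony_input_error",
            "unknown category: %s",
            paste(setdiff(category, names(map)), collapse = ", "))
  unname(map[category])
}

#' Mean resistance of one host against phages of a time point
#'
#' Arithmetic mean over non-missing scores against every phage of the given
#' time point(s); missing cells are excluded from the denominator, not
#' imputed. Passing several time points pools their phages (e.g. the
#' founder against all post-infection phage populations).
#'
#' @param mat a [resistance_matrix()].
#' @param host host id.
#' @param phage_timepoint one or more phage time points.
#' @return mean score in `[0, 1]`.
#' @export
mean_resistance <- function(mat, host, phage_timepoint) {
  if (!host %in% mat$hosts$host_id)
    cc_stop("crisprcolony_input_error", "unknown host: %s", host)
  cols <- mat$phages$phage_timepoint %in% phage_timepoint
  if (!any(cols))
    cc_stop("crisprcolony_input_error", "no phages at time point(s) %s",
            paste(phage_timepoint, collapse = ", "))
  vals <- mat$scores[match(host, mat$hosts$host_id), cols]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L)
    cc_stop("crisprcolony_undefined_mean",
            "all scores missing for host %s at the requested time point(s)",
            host)
  mean(vals)
}

#' Resistance trajectories for every host
#'
#' Per-host mean score against each phage time point, ordered by phage
#' time, with the contemporary score (host and phage time points coincide)
#' flagged.
#'
#' @param mat a [resistance_matrix()].
#' @return data.frame with `host_id`, `host_timepoint`, `phage_timepoint`,
#'   `mean_score`, `n_scored`, `contemporary`.
#' @export
trajectories <- function(mat) {
  ptimes <- sort(unique(mat$phages$phage_timepoint))
  rows <- lapply(seq_len(nrow(mat$hosts)), function(i) {
    host <- mat$hosts$host_id[i]
    ht <- mat$hosts$host_timepoint[i]
    do.call(rbind, lapply(ptimes, function(pt) {
      cols <- mat$phages$phage_timepoint == pt
      vals <- mat$scores[i, cols]
      vals <- vals[!is.na(vals)]
      data.frame(host_id = host, host_timepoint = ht, phage_timepoint = pt,
                 mean_score = if (length(vals)) mean(vals) else NA_real_,
                 n_scored = length(vals), contemporary = pt == ht,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
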