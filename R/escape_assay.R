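## Phage escape quantification: titers from spot dilution series, Poisson
## confidence intervals, detection limits, efficiency of plaquing (EOP),
## and spike-in arithmetic for raising an escaper frequency.

#' Spot/dilution plaque assay
#'
#' @param host_id host strain identifier.
#' @param dilution_factor positive fractions of the stock plated at each
#'   spot (e.g. `10^-(0:7)`).
#' @param plaques non-negative integer plaque counts per spot.
#' @param volume_ml plated volume per spot in ml (default 0.002, a 2 uL
#'   spot).
#' @param stock_titer total phage concentration of the stock in PFU/ml, if
#'   known independently.
#' @return object of class `plaque_assay`.
#' @export
plaque_assay <- function(host_id, dilution_factor, plaques,
                         volume_ml = 0.002, stock_titer = NA_real_) {
  stopifnot(length(dilution_factor) == length(plaques),
            all(dilution_factor > 0), all(plaques >= 0),
            all(plaques == round(plaques)), volume_ml > 0)
  structure(list(host_id = host_id,
                 spots = data.frame(dilution_factor = dilution_factor,
                                    plaques = as.integer(plaques)),
                 volume_ml = volume_ml, stock_titer = stock_titer),
            class = "plaque_assay")
}

#' @export
print.plaque_assay <- function(x, ...) {
  cat(sprintf("<plaque_assay> host %s, %d spots, %g ml/spot\n",
              x$host_id, nrow(x$spots), x$volume_ml))
  print(x$spots)
  invisible(x)
}

#' Phage titer from a spot dilution series
#'
#' Uses the single most-dilute spot whose count falls in the countable
#' range (default 1-200 plaques), matching spot-assay practice; `method =
#' "pooled"` instead pools all countable spots (sum of plaques over sum of
#' plated stock-equivalents). An all-zero series yields a below-detection
#' result carrying the one-plaque detection limit at the least-dilute spot.
#' The confidence interval is the exact Poisson (Garwood) interval on the
#' plaque count, divided through by the plated stock-equivalent volume.
#'
#' @param assay a [plaque_assay()].
#' @param countable inclusive count range considered countable (default
#'   `c(1, 200)`).
#' @param conf confidence level (default 0.95).
#' @param method "single" (most-dilute countable spot) or "pooled".
#' @return object of class `titer_result`: list with `titer` (PFU/ml),
#'   `ci_lower`, `ci_upper`, `below_detection`, `detection_limit` (PFU/ml),
#'   `spot_used` (row index, `NA` for pooled/below-detection).
#' @export
titer <- function(assay, countable = c(1, 200), conf = 0.95,
                  method = c("single", "pooled")) {
  method <- match.arg(method)
  spots <- assay$spots
  v <- assay$volume_ml
  limit <- 1 / (max(spots$dilution_factor) * v)
  ok <- spots$plaques >= countable[1] & spots$plaques <= countable[2]
  if (!any(ok)) {
    if (all(spots$plaques == 0))
      return(structure(list(titer = NA_real_, ci_lower = NA_real_,
                            ci_upper = NA_real_, below_detection = TRUE,
                            detection_limit = limit, spot_used = NA_integer_),
                       class = "titer_result"))
    cc_stop("crisprcolony_input_error",
            "no spot in the countable range [%g, %g] and counts not all zero",
            countable[1], countable[2])
  }
  alpha <- 1 - conf
  if (method == "single") {
    i <- which(ok)[which.min(spots$dilution_factor[ok])]
    k <- spots$plaques[i]
    denom <- spots$dilution_factor[i] * v
    spot_used <- i
  } else {
    k <- sum(spots$plaques[ok])
    denom <- sum(spots$dilution_factor[ok]) * v
    spot_used <- NA_integer_
  }
  structure(list(
    titer = k / denom,
    ci_lower = qgamma(alpha / 2, k) / denom,
    ci_upper = qgamma(1 - alpha / 2, k + 1) / denom,
    below_detection = FALSE, detection_limit = limit, spot_used = spot_used
  ), class = "titer_result")
}

#' @export
print.titer_result <- function(x, ...) {
  if (x$below_detection)
    cat(sprintf("<titer_result> below detection (< %.3g PFU/ml)\n",
                x$detection_limit))
  else
    cat(sprintf("<titer_result> %.3g PFU/ml [%.3g, %.3g]\n",
                x$titer, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Efficiency of plaquing (EOP)
#'
#' Plaques formed on the test strain relative to the total number of phage
#' particles in the stock. For a host carrying a single targeting spacer
#' the EOP equals the escaper frequency for that spacer. A below-detection
#' test titer propagates as a one-sided upper bound (never reported as
#' zero); a below-detection stock makes the EOP undefined.
#'
#' @param test_titer test-strain titer: a number (PFU/ml) or a
#'   [titer()] result.
#' @param stock_titer stock titer: a number or a [titer()] result.
#' @return object of class `eop_result`: list with `eop`,
#'   `below_detection` and `escaper_freq` (alias of `eop`).
#' @export
eop <- function(test_titer, stock_titer) {
  get_t <- function(x, what) {
    if (inherits(x, "titer_result")) {
      if (x$below_detection) {
        if (what == "stock")
          cc_stop("crisprcolony_undefined_eop",
                  "stock titer below detection: EOP undefined")
        return(list(value = x$detection_limit, bound = TRUE))
      }
      return(list(value = x$titer, bound = FALSE))
    }
    list(value = as.numeric(x), bound = FALSE)
  }
  tt <- get_t(test_titer, "test")
  st <- get_t(stock_titer, "stock")
  if (!is.finite(st$value) || st$value <= 0)
    cc_stop("crisprcolony_undefined_eop", "stock_titer must be positive")
  structure(list(eop = tt$value / st$value, below_detection = tt$bound,
                 escaper_freq = tt$value / st$value),
            class = "eop_result")
}

#' @export
print.eop_result <- function(x, ...) {
  cat(sprintf("<eop_result> EOP %s%.3g\n",
              if (x$below_detection) "< " else "", x$eop))
  invisible(x)
}

#' Escaper PFU to spike into a stock
#'
#' Solves `(current_freq * stock_pfu + x) / (stock_pfu + x) = target_freq`
#' for the pure-escaper PFU `x` to add so the stock reaches the target
#' escaper frequency.
#'
#' @param stock_pfu total PFU in the stock.
#' @param current_freq current escaper frequency.
#' @param target_freq desired escaper frequency (> current, < 1).
#' @return PFU of escaper stock to add.
#' @export
spike_escapers <- function(stock_pfu, current_freq, target_freq) {
  stopifnot(stock_pfu > 0, current_freq >= 0, current_freq <= 1)
  if (target_freq <= current_freq)
    cc_stop("crisprcolony_noop_error",
            "target_freq must exceed current_freq")
  if (target_freq >= 1)
    cc_stop("crisprcolony_input_error", "target_freq must be < 1")
  stock_pfu * (target_freq - current_freq) / (1 - target_freq)
}
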