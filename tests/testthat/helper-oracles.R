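# Independent brute-force oracles. These deliberately avoid Biostrings and
# every code path they are used to check: plain character vectors and
# sliding-window Hamming scans only.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

ORACLE_IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
                     R = c("A", "G"), Y = c("C", "T"), N = c("A", "C", "G", "T"))

# all-positions Hamming profile of `pat` against `x` (1-based starts)
oracle_hamming_profile <- function(x, pat) {
  xv <- strsplit(x, "")[[1]]
  pv <- strsplit(pat, "")[[1]]
  w <- length(pv); n <- length(xv)
  if (n < w) return(integer(0))
  vapply(seq_len(n - w + 1L),
         function(s) sum(xv[s:(s + w - 1L)] != pv), integer(1))
}

# greedy left-to-right non-overlapping fuzzy repeat scan
oracle_find_repeats <- function(read, model) {
  w <- nchar(model$repeat_seq)
  mism <- oracle_hamming_profile(read, model$repeat_seq)
  cand <- which(mism <= model$max_mismatches)
  keep <- integer(0); next_free <- 1L
  for (s in cand) {
    if (s >= next_free) { keep <- c(keep, s); next_free <- s + w }
  }
  data.frame(start = as.integer(keep), mismatches = as.integer(mism[keep]))
}

oracle_pam_ok <- function(genome, start0, strand, L, pam = "NGG") {
  np <- nchar(pam)
  lg <- nchar(genome)
  window <- if (strand == "+") {
    if (start0 + L + np > lg) return(FALSE)
    substr(genome, start0 + L + 1L, start0 + L + np)
  } else {
    if (start0 - np < 0) return(FALSE)
    oracle_revcomp(substr(genome, start0 - np + 1L, start0))
  }
  wv <- strsplit(window, "")[[1]]
  pv <- strsplit(pam, "")[[1]]
  all(mapply(function(b, p) b %in% ORACLE_IUPAC[[p]], wv, pv))
}

# exhaustive both-strand best-hit scan with optional PAM filter; mirrors the
# map_spacer contract (0-based start, "+" before "-" at equal start)
oracle_map_spacer <- function(spacer, genome, max_mismatches = 2L,
                              pam = "NGG", require_pam = TRUE) {
  L <- nchar(spacer)
  hp <- oracle_hamming_profile(genome, spacer)
  hm <- oracle_hamming_profile(genome, oracle_revcomp(spacer))
  hits <- rbind(
    data.frame(start = seq_along(hp) - 1L, strand = "+", mism = hp),
    data.frame(start = seq_along(hm) - 1L, strand = "-", mism = hm)
  )
  hits <- hits[hits$mism <= max_mismatches, , drop = FALSE]
  if (require_pam && nrow(hits) > 0L) {
    ok <- mapply(function(s, st) oracle_pam_ok(genome, s, st, L, pam),
                 hits$start, hits$strand)
    hits <- hits[ok, , drop = FALSE]
  }
  if (nrow(hits) == 0L)
    return(list(mapped = FALSE))
  hits <- hits[hits$mism == min(hits$mism), , drop = FALSE]
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  list(mapped = TRUE, start = hits$start[1L], strand = hits$strand[1L],
       mismatches = hits$mism[1L], ambiguous = nrow(hits) > 1L)
}
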