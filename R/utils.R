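## Small sequence utilities shared across modules. Genome coordinates are
## 0-based half-open everywhere in the user-facing API; conversion to R's
## 1-based substr() happens locally, at the call site.

DNA_BASES <- c("A", "C", "G", "T")

IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

cc_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "crisprcolony_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N and IUPAC codes).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence with a given GC content
#'
#' @param n sequence length in nt.
#' @param gc_content target GC fraction in `[0, 1]`.
#' @return a single DNA string of length `n`.
#' @export
random_dna <- function(n, gc_content = 0.5) {
  stopifnot(n >= 0, gc_content >= 0, gc_content <= 1)
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

## substring with a 0-based half-open interval [start0, start0 + len);
## vectorized over start0 (substring, not substr)
substr0 <- function(x, start0, len) {
  substring(x, start0 + 1L, start0 + len)
}

## does each base match the corresponding IUPAC pattern character?
iupac_base_match <- function(bases, pattern_chars) {
  mapply(function(b, p) b %in% IUPAC[[p]], bases, pattern_chars,
         USE.NAMES = FALSE)
}

## hamming distance between equal-length strings (vectorized over b)
hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  vapply(strsplit(b, ""), function(bv) sum(av != bv), integer(1))
}

## mutate one position of a sequence to a different random base
point_mutate <- function(seq, pos1) {
  old <- substr(seq, pos1, pos1)
  new <- sample(setdiff(DNA_BASES, old), 1L)
  substr(seq, pos1, pos1) <- new
  seq
}

## apply iid per-base substitution errors at rate `rate`
sequencing_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0) return(seq)
  for (pos in sample.int(n, k)) seq <- point_mutate(seq, pos)
  seq
}
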