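## Spacer-to-protospacer mapping with PAM validation, and seed/PAM escape
## mutation typing. Coordinates are 0-based half-open; alignment is
## substitution-only (no gaps), which matches escaper variation in this
## system at the scales analyzed.

#' Validate the PAM downstream of a protospacer
#'
#' Checks the bases immediately 3' of the protospacer, on the
#' protospacer-bearing strand, against an IUPAC pattern (default NGG). A
#' PAM window running off the linear genome end returns `FALSE` with
#' attribute `end_of_genome = TRUE`.
#'
#' @param genome DNA string.
#' @param hit list with `start` (0-based), `strand` and either `spacer` or
#'   `length`; typically a [map_spacer()] result.
#' @param pam_pattern IUPAC pattern (default "NGG").
#' @return logical scalar, with attribute `end_of_genome`.
#' @export
validate_pam <- function(genome, hit, pam_pattern = "NGG") {
  L <- if (!is.null(hit$length)) hit$length else nchar(hit$spacer)
  np <- nchar(pam_pattern)
  lg <- nchar(genome)
  if (hit$strand == "+") {
    off_end <- hit$start + L + np > lg
    window <- if (off_end) "" else substr0(genome, hit$start + L, np)
  } else {
    off_end <- hit$start - np < 0
    window <- if (off_end) "" else revcomp(substr0(genome, hit$start - np, np))
  }
  if (off_end)
    return(structure(FALSE, end_of_genome = TRUE))
  ok <- all(iupac_base_match(strsplit(window, "")[[1]],
                             strsplit(toupper(pam_pattern), "")[[1]]))
  structure(ok, end_of_genome = FALSE)
}

## all substitution-only hits of `spacer` on one strand, as 0-based starts
## with mismatch counts
strand_hits <- function(spacer, genome_ds, max_mismatches, strand) {
  pat <- if (strand == "-") revcomp(spacer) else spacer
  m <- Biostrings::matchPattern(pat, genome_ds,
                                max.mismatch = max_mismatches,
                                with.indels = FALSE, fixed = TRUE)
  starts <- Biostrings::start(m)
  if (length(starts) == 0L)
    return(data.frame(start = integer(0), strand = character(0),
                      mismatches = integer(0)))
  mism <- Biostrings::neditStartingAt(Biostrings::DNAString(pat), genome_ds,
                                      starting.at = starts,
                                      with.indels = FALSE, fixed = TRUE)
  data.frame(start = as.integer(starts) - 1L, strand = strand,
             mismatches = as.integer(mism), stringsAsFactors = FALSE)
}

#' Map a spacer to its protospacer on the phage genome
#'
#' Best substitution-only hit over both strands by fewest mismatches. With
#' `require_pam = TRUE` only hits with a valid PAM are eligible. When two
#' or more hits tie at the best score the hit is flagged `ambiguous` (such
#' spacers are excluded from priming distance analysis); the reported
#' coordinates are then the first best hit (smallest start, "+" before "-").
#'
#' @param spacer spacer sequence (>= 15 nt).
#' @param genome DNA string (or `DNAString`).
#' @param max_mismatches substitutions tolerated (default 2).
#' @param pam IUPAC PAM pattern (default "NGG").
#' @param require_pam restrict to hits with a valid PAM (default TRUE).
#' @return object of class `protospacer_hit`: list with `spacer`, `start`
#'   (0-based, interval `[start, start + L)` in plus-strand coordinates),
#'   `strand`, `pam` (observed PAM on the protospacer strand), `mismatches`,
#'   `ambiguous`, `mapped`. Unmapped spacers return `mapped = FALSE` with
#'   `NA` coordinates (recorded, not fatal).
#' @export
map_spacer <- function(spacer, genome, max_mismatches = 2L, pam = "NGG",
                       require_pam = TRUE) {
  spacer <- toupper(spacer)
  if (nchar(spacer) < 15L)
    cc_stop("crisprcolony_precondition_error", "spacer shorter than 15 nt")
  genome_chr <- if (is.character(genome)) genome else as.character(genome)
  genome_ds <- if (is.character(genome)) Biostrings::DNAString(genome) else genome
  hits <- rbind(strand_hits(spacer, genome_ds, max_mismatches, "+"),
                strand_hits(spacer, genome_ds, max_mismatches, "-"))
  L <- nchar(spacer)
  if (nrow(hits) > 0L && require_pam) {
    ok <- vapply(seq_len(nrow(hits)), function(i)
      as.logical(validate_pam(genome_chr,
                              list(start = hits$start[i],
                                   strand = hits$strand[i], length = L),
                              pam)), logical(1))
    hits <- hits[ok, , drop = FALSE]
  }
  if (nrow(hits) == 0L)
    return(structure(list(spacer = spacer, start = NA_integer_,
                          strand = NA_character_, pam = NA_character_,
                          mismatches = NA_integer_, ambiguous = FALSE,
                          mapped = FALSE),
                     class = "protospacer_hit"))
  best <- hits$mismatches == min(hits$mismatches)
  hits <- hits[best, , drop = FALSE]
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  top <- hits[1L, ]
  np <- nchar(pam)
  pam_obs <- if (top$strand == "+") {
    if (top$start + L + np <= nchar(genome_chr))
      substr0(genome_chr, top$start + L, np) else NA_character_
  } else {
    if (top$start - np >= 0)
      revcomp(substr0(genome_chr, top$start - np, np)) else NA_character_
  }
  structure(list(spacer = spacer, start = top$start, strand = top$strand,
                 pam = pam_obs, mismatches = top$mismatches,
                 ambiguous = nrow(hits) > 1L, mapped = TRUE),
            class = "protospacer_hit")
}

#' @export
print.protospacer_hit <- function(x, ...) {
  if (!x$mapped) {
    cat("<protospacer_hit> unmapped\n")
  } else {
    cat(sprintf("<protospacer_hit> [%d, %d) %s, PAM %s, %d mismatch(es)%s\n",
                x$start, x$start + nchar(x$spacer), x$strand, x$pam,
                x$mismatches, if (x$ambiguous) " [ambiguous]" else ""))
  }
  invisible(x)
}

## vectorized PAM validation for many (start, strand) hits of length-L
## protospacers; same contract as validate_pam
pam_ok_vec <- function(genome, start0, strand, L, pam) {
  np <- nchar(pam); lg <- nchar(genome)
  plus <- strand == "+"
  win <- character(length(start0))
  in_p <- plus & (start0 + L + np <= lg)
  in_m <- !plus & (start0 - np >= 0)
  win[in_p] <- substring(genome, start0[in_p] + L + 1L, start0[in_p] + L + np)
  win[in_m] <- revcomp(substring(genome, start0[in_m] - np + 1L,
                                 start0[in_m]))
  ok <- in_p | in_m
  if (any(ok)) {
    pv <- strsplit(toupper(pam), "")[[1]]
    mat <- matrix(unlist(strsplit(win[ok], ""), use.names = FALSE), nrow = np)
    good <- rep(TRUE, sum(ok))
    for (k in seq_len(np)) good <- good & mat[k, ] %in% IUPAC[[pv[k]]]
    ok[ok] <- good
  }
  ok
}

## batched exact (0-mismatch) mapping of equal-width spacers via a PDict
map_spacers_exact <- function(spacers, genome, pam, require_pam) {
  gd <- Biostrings::DNAString(genome)
  L <- nchar(spacers[1L])
  one_strand <- function(strand) {
    pats <- if (strand == "-") revcomp(spacers) else spacers
    m <- Biostrings::matchPDict(Biostrings::PDict(pats), gd)
    starts <- IRanges::start(m)
    data.frame(idx = rep(seq_along(spacers), lengths(starts)),
               start = unlist(starts, use.names = FALSE) - 1L,
               strand = strand, stringsAsFactors = FALSE)
  }
  hits <- rbind(one_strand("+"), one_strand("-"))
  if (require_pam && nrow(hits))
    hits <- hits[pam_ok_vec(genome, hits$start, hits$strand, L, pam), ,
                 drop = FALSE]
  n_hits <- tabulate(hits$idx, nbins = length(spacers))
  hits <- hits[order(hits$idx, hits$start, hits$strand), , drop = FALSE]
  first <- hits[!duplicated(hits$idx), , drop = FALSE]
  tab <- data.frame(
    spacer = spacers, start = NA_integer_, strand = NA_character_,
    pam = NA_character_, mismatches = NA_integer_,
    ambiguous = n_hits > 1L, mapped = n_hits > 0L,
    stringsAsFactors = FALSE
  )
  tab$start[first$idx] <- first$start
  tab$strand[first$idx] <- first$strand
  tab$mismatches[first$idx] <- 0L
  np <- nchar(pam)
  plus <- which(tab$mapped & tab$strand == "+" &
                  tab$start + L + np <= nchar(genome))
  minus <- which(tab$mapped & tab$strand == "-" & tab$start - np >= 0)
  tab$pam[plus] <- substring(genome, tab$start[plus] + L + 1L,
                             tab$start[plus] + L + np)
  tab$pam[minus] <- revcomp(substring(genome, tab$start[minus] - np + 1L,
                                      tab$start[minus]))
  tab
}

#' Map many spacers, returning a hit table
#'
#' With `max_mismatches = 0` and equal-length spacers the whole dictionary
#' is matched in one pass (`matchPDict`); otherwise each spacer is mapped
#' with [map_spacer()]. Both paths honour the same contract.
#'
#' @inheritParams map_spacer
#' @param spacers character vector of spacer sequences.
#' @return data.frame with one row per input spacer: `spacer`, `start`,
#'   `end`, `strand`, `pam`, `mismatches`, `ambiguous`, `mapped`.
#' @export
map_spacers <- function(spacers, genome, max_mismatches = 2L, pam = "NGG",
                        require_pam = TRUE) {
  uniq <- unique(spacers)
  if (max_mismatches == 0L && length(unique(nchar(uniq))) == 1L) {
    tab <- map_spacers_exact(uniq, genome, pam, require_pam)
  } else {
    genome_ds <- Biostrings::DNAString(genome)
    rows <- lapply(uniq, function(s)
      map_spacer(s, genome_ds, max_mismatches, pam, require_pam))
    tab <- data.frame(
      spacer = vapply(rows, `[[`, character(1), "spacer"),
      start = vapply(rows, `[[`, integer(1), "start"),
      strand = vapply(rows, `[[`, character(1), "strand"),
      pam = vapply(rows, `[[`, character(1), "pam"),
      mismatches = vapply(rows, `[[`, integer(1), "mismatches"),
      ambiguous = vapply(rows, `[[`, logical(1), "ambiguous"),
      mapped = vapply(rows, `[[`, logical(1), "mapped"),
      stringsAsFactors = FALSE
    )
  }
  tab$end <- tab$start + nchar(tab$spacer)
  out <- tab[match(spacers, tab$spacer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify an escape mutation as seed, PAM or distal
#'
#' Compares wild-type and mutant target sequences spanning protospacer plus
#' PAM, with the protospacer written PAM-distal to PAM-proximal (the PAM is
#' the last `pam_len` bases). Offsets use PAM-proximal numbering: position
#' 1 is the protospacer base nearest the PAM, increasing toward the distal
#' end; PAM bases get negative offsets (-1 = first PAM base). Class
#' precedence for multiple mutations is PAM > seed > distal; all mutated
#' offsets are reported.
#'
#' @param wild_target,mutant_target equal-length strings (protospacer +
#'   PAM).
#' @param seed_len seed-region length, PAM-proximal nt (default 8, the
#'   upper end of the critical 6-8 nt region).
#' @param pam_len PAM length (default 3).
#' @return object of class `escape_call`: list with `class` (one of
#'   "none", "seed", "PAM", "distal") and `positions` (integer offsets).
#' @export
classify_escape_mutation <- function(wild_target, mutant_target,
                                     seed_len = 8L, pam_len = 3L) {
  wild_target <- toupper(wild_target); mutant_target <- toupper(mutant_target)
  if (nchar(wild_target) != nchar(mutant_target))
    cc_stop("crisprcolony_input_error",
            "wild and mutant targets must have equal length")
  n <- nchar(wild_target)
  L <- n - pam_len
  if (L <= 0)
    cc_stop("crisprcolony_input_error", "target shorter than the PAM")
  wv <- strsplit(wild_target, "")[[1]]
  mv <- strsplit(mutant_target, "")[[1]]
  diff1 <- which(wv != mv)                      # 1-based string positions
  ## PAM-proximal numbering: protospacer base at string pos i (i <= L) is
  ## offset L - i + 1; PAM base at string pos L + j is offset -j.
  positions <- ifelse(diff1 <= L, L - diff1 + 1L, -(diff1 - L))
  cls <- if (length(positions) == 0L) "none"
  else if (any(positions < 0L)) "PAM"
  else if (any(positions >= 1L & positions <= seed_len)) "seed"
  else "distal"
  structure(list(class = cls, positions = as.integer(positions)),
            class = "escape_call")
}

#' @export
print.escape_call <- function(x, ...) {
  cat(sprintf("<escape_call> %s%s\n", x$class,
              if (length(x$positions))
                paste0(" at offset(s) ", paste(x$positions, collapse = ", "))
              else ""))
  invisible(x)
}
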