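## Synthetic-data generator. Emulates the inputs of a solid-media spacer
## acquisition experiment: a phage genome, clonal colonies founded by a
## single spacer that expand their arrays by priming-biased acquisition,
## amplicon reads over the CRISPR locus, escaper phage populations, spot
## plaque assays and time-shift resistance matrices. Every output carries
## ground-truth labels so downstream modules can be tested exactly.

## A 36-nt type II-A direct repeat (S. pyogenes SF370 convention); the
## repeat/leader/barcode are configuration, not data.
DEFAULT_REPEAT <- "GTTTTAGAGCTATGCTGTTTTGAATGGTCCCAAAAC"
DEFAULT_LEADER <- "ATAAAATTTAAGTATTAAAAATAGTTTAGGATTC"

#' Generator configuration
#'
#' Bundles every tunable of the synthetic-data generator with validated
#' defaults. Probabilities reflect the experimental system being emulated:
#' roughly 1 in 1e7 naive infected cells survive by acquiring a spacer, 1 in
#' 1e6-1e7 phage escape a given spacer, and primed acquisition is strongly
#' biased to the 500 bp flanking the existing target.
#'
#' @param genome_length phage genome length in bp (default 45000, a typical
#'   staphylococcal siphovirus scale).
#' @param gc_content genome GC fraction (default 0.33, AT-rich host range).
#' @param repeat_seq direct repeat sequence (36-nt type II-A default).
#' @param leader_seq leader sequence upstream of the first repeat.
#' @param barcode_length length of the randomized clonality barcode placed
#'   upstream of the leader (default 10 nt).
#' @param spacer_length spacer length in nt (default 30).
#' @param naive_rate probability a naive infected cell survives by spacer
#'   acquisition (default 1e-7); carried for completeness, colony simulation
#'   starts from a surviving founder.
#' @param priming_prob probability of acquiring each additional spacer
#'   (geometric stopping; default 0.3).
#' @param local_fraction fraction of primed spacers drawn from within
#'   `local_window` of the founder target (default 0.8).
#' @param local_window half-width in bp of the local priming window
#'   (default 500).
#' @param escape_freq fraction of escaper genomes in a phage population
#'   (default 1e-7).
#' @param read_error_rate per-base substitution probability on reads
#'   (default 1e-3).
#' @param max_spacers cap on spacers per array (default 4, the most ever
#'   observed in this system).
#' @param pam PAM pattern in IUPAC code, immediately 3' of the protospacer
#'   (default "NGG").
#' @param rng_seed integer seed; all generator functions are deterministic
#'   given the config.
#' @return an object of class `generator_config` (a validated list).
#' @export
generator_config <- function(genome_length = 45000L,
                             gc_content = 0.33,
                             repeat_seq = DEFAULT_REPEAT,
                             leader_seq = DEFAULT_LEADER,
                             barcode_length = 10L,
                             spacer_length = 30L,
                             naive_rate = 1e-7,
                             priming_prob = 0.3,
                             local_fraction = 0.8,
                             local_window = 500L,
                             escape_freq = 1e-7,
                             read_error_rate = 1e-3,
                             max_spacers = 4L,
                             pam = "NGG",
                             rng_seed = 1L) {
  cfg <- list(
    genome_length = as.integer(genome_length), gc_content = gc_content,
    repeat_seq = toupper(repeat_seq), leader_seq = toupper(leader_seq),
    barcode_length = as.integer(barcode_length),
    spacer_length = as.integer(spacer_length),
    naive_rate = naive_rate, priming_prob = priming_prob,
    local_fraction = local_fraction, local_window = as.integer(local_window),
    escape_freq = escape_freq, read_error_rate = read_error_rate,
    max_spacers = as.integer(max_spacers), pam = toupper(pam),
    rng_seed = as.integer(rng_seed)
  )
  probs <- c("gc_content", "naive_rate", "priming_prob", "local_fraction",
             "escape_freq", "read_error_rate")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      cc_stop("crisprcolony_config_error", "%s must be a probability in [0,1]", p)
  }
  if (cfg$genome_length <= 2L * cfg$spacer_length)
    cc_stop("crisprcolony_config_error",
            "genome_length must exceed twice the spacer length")
  if (!nzchar(cfg$repeat_seq) || identical(cfg$repeat_seq, cfg$leader_seq))
    cc_stop("crisprcolony_config_error",
            "repeat_seq must be nonempty and distinct from leader_seq")
  if (cfg$local_window <= 0 || cfg$max_spacers < 1L)
    cc_stop("crisprcolony_config_error", "local_window and max_spacers must be positive")
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic phage genome
#'
#' Stand-in for a real phage reference (the mapper accepts any FASTA). The
#' genome is linear: injected from a defined end, no wraparound anywhere in
#' the pipeline.
#'
#' @param config a [generator_config()].
#' @return a single DNA string of length `config$genome_length`.
#' @export
generate_phage_genome <- function(config) {
  if (config$genome_length < 1000L)
    cc_stop("crisprcolony_config_error", "genome_length must be >= 1000")
  withr::local_seed(config$rng_seed)
  random_dna(config$genome_length, config$gc_content)
}

#' Enumerate valid protospacer start positions
#'
#' A position is a valid protospacer start when the PAM pattern matches
#' immediately 3' of the protospacer on the protospacer-bearing strand.
#' Windows are truncated at the linear genome ends.
#'
#' @param genome DNA string.
#' @param spacer_length protospacer length L.
#' @param pam IUPAC PAM pattern (default "NGG").
#' @return data.frame with columns `start` (0-based, half-open
#'   `[start, start+L)` on the plus-strand coordinate system) and `strand`.
#' @export
pam_sites <- function(genome, spacer_length, pam = "NGG") {
  g <- strsplit(genome, "")[[1]]
  lg <- length(g)
  L <- spacer_length
  pamv <- strsplit(toupper(pam), "")[[1]]
  np <- length(pamv)
  ok_plus <- rep(TRUE, lg)   # indexed by 0-based start s: s+1 in R
  ok_minus <- rep(TRUE, lg)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (k in seq_len(np)) {
    allowed <- IUPAC[[pamv[k]]]
    ## + strand: genome base at 0-based s+L+k-1 must be in `allowed`
    idx <- seq_len(lg) + L + k - 1L           # 1-based positions
    valid <- idx <= lg
    m <- valid & (g[pmin(idx, lg)] %in% allowed)
    ok_plus <- ok_plus & m
    ## - strand: complement of genome base at 0-based s-k must be allowed
    idx <- seq_len(lg) - k                    # 1-based positions
    valid <- idx >= 1L
    m <- valid & (comp[g[pmax(idx, 1L)]] %in% allowed)
    ok_minus <- ok_minus & m
  }
  s <- 0:(lg - 1L)
  in_bounds <- s <= lg - L
  plus <- s[ok_plus & in_bounds]
  minus <- s[ok_minus & in_bounds]
  data.frame(
    start = c(plus, minus),
    strand = rep(c("+", "-"), c(length(plus), length(minus))),
    stringsAsFactors = FALSE
  )
}

## extract the protospacer sequence for a site (strand-aware)
protospacer_seq <- function(genome, start, strand, L) {
  s <- substr0(genome, start, L)
  ifelse(strand == "-", revcomp(s), s)
}

#' Simulate a clonal phage-resistant colony
#'
#' Every cell descends from one founder that acquired a single spacer; the
#' whole colony shares the founder spacer and one plasmid barcode.
#' Additional spacers are appended leader-proximally with probability
#' `priming_prob` each (geometric stopping, capped at `max_spacers` total),
#' their targets drawn from a mixture: with probability `local_fraction`
#' uniformly among valid protospacers within `local_window` bp of the
#' founder target, otherwise uniformly among all valid protospacers.
#'
#' @param genome DNA string.
#' @param founder_position 0-based start of the founder protospacer; must be
#'   a valid site (PAM present) on `founder_strand`.
#' @param n_cells number of cells (arrays) to simulate.
#' @param config a [generator_config()].
#' @param founder_strand strand of the founder protospacer ("+" or "-").
#' @param colony_id identifier stored on the colony.
#' @param sites optional precomputed [pam_sites()] table for `genome`
#'   (saves recomputation when simulating many colonies on one genome).
#' @return an object of class `simulated_colony`: list with `colony_id`,
#'   `founder_spacer`, `founder_position`, `founder_strand`, `barcode`,
#'   `arrays` (list of [spacer_array()], leader-proximal first, founder
#'   last) and `truth` (per-spacer data.frame: cell, acq_order, spacer,
#'   position, strand, primed, local).
#' @export
simulate_colony <- function(genome, founder_position, n_cells, config,
                            founder_strand = "+", colony_id = "colony1",
                            sites = NULL) {
  stopifnot(n_cells >= 1)
  L <- config$spacer_length
  if (is.null(sites)) sites <- pam_sites(genome, L, config$pam)
  is_founder_site <- sites$start == founder_position &
    sites$strand == founder_strand
  if (!any(is_founder_site))
    cc_stop("crisprcolony_invalid_target",
            "founder_position %d (%s) has no valid PAM", founder_position,
            founder_strand)
  other <- sites[!is_founder_site, , drop = FALSE]
  local_ok <- abs(other$start - founder_position) <= config$local_window
  local_sites <- other[local_ok, , drop = FALSE]
  if (nrow(local_sites) == 0L && config$local_fraction > 0)
    cc_stop("crisprcolony_invalid_target",
            "no valid protospacers within the local window of the founder")

  withr::local_seed(config$rng_seed)
  founder_spacer <- protospacer_seq(genome, founder_position, founder_strand, L)
  barcode <- random_dna(config$barcode_length, 0.5)

  n_extra <- pmin(rgeom(n_cells, prob = 1 - config$priming_prob),
                  config$max_spacers - 1L)
  k_total <- sum(n_extra)
  use_local <- runif(k_total) < config$local_fraction
  pick_local <- if (nrow(local_sites)) sample.int(nrow(local_sites), k_total,
                                                  replace = TRUE)
                else rep(NA_integer_, k_total)
  pick_other <- sample.int(nrow(other), k_total, replace = TRUE)
  extra_start <- ifelse(use_local, local_sites$start[pick_local],
                        other$start[pick_other])
  extra_strand <- ifelse(use_local, local_sites$strand[pick_local],
                         other$strand[pick_other])

  ## flat per-spacer truth in chronological (acquisition) order
  cell <- rep(seq_len(n_cells), n_extra + 1L)
  acq_order <- sequence(n_extra + 1L)
  position <- integer(length(cell)); strand <- character(length(cell))
  is_founder <- acq_order == 1L
  position[is_founder] <- founder_position
  strand[is_founder] <- founder_strand
  position[!is_founder] <- extra_start
  strand[!is_founder] <- extra_strand
  spacer <- protospacer_seq(genome, position, strand, L)
  truth <- data.frame(
    cell = cell, acq_order = acq_order, spacer = spacer,
    position = position, strand = strand, primed = !is_founder,
    local = ifelse(is_founder, NA, use_local[pmax(cumsum(!is_founder), 1L)]),
    stringsAsFactors = FALSE
  )
  by_cell <- split(spacer, cell)
  arrays <- lapply(seq_len(n_cells), function(i)
    spacer_array(rev(by_cell[[i]]), barcode = barcode,
                 read_id = sprintf("%s_cell%04d", colony_id, i)))
  structure(list(
    colony_id = colony_id, founder_spacer = founder_spacer,
    founder_position = founder_position, founder_strand = founder_strand,
    barcode = barcode, arrays = arrays, truth = truth
  ), class = "simulated_colony")
}

#' Simulate amplicon reads over the CRISPR locus
#'
#' Each read is `barcode + leader + repeat + (spacer + repeat)*n`, spacers
#' appearing leader-proximal (most recently acquired) first, with iid
#' per-base substitution errors at `config$read_error_rate`.
#'
#' @param colony a [simulate_colony()] result.
#' @param config a [generator_config()].
#' @param reads_per_array reads sequenced per cell/array (>= 1).
#' @return object of class `simulated_reads`: data.frame with columns
#'   `read_id`, `cell`, `sequence`; attribute `colony_id`.
#' @export
simulate_reads <- function(colony, config, reads_per_array = 1L) {
  stopifnot(reads_per_array >= 1L)
  withr::local_seed(config$rng_seed + 1L)
  rows <- list()
  ridx <- 0L
  for (i in seq_along(colony$arrays)) {
    arr <- colony$arrays[[i]]
    body <- paste0(colony$barcode, config$leader_seq, config$repeat_seq,
                   paste0(arr$spacers, config$repeat_seq, collapse = ""))
    for (r in seq_len(reads_per_array)) {
      ridx <- ridx + 1L
      rows[[ridx]] <- data.frame(
        read_id = sprintf("%s_read%05d", colony$colony_id, ridx),
        cell = i,
        sequence = sequencing_errors(body, config$read_error_rate),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "colony_id") <- colony$colony_id
  class(out) <- c("simulated_reads", "data.frame")
  out
}

#' Simulate a phage population containing escaper mutants
#'
#' Escapers carry a single-nucleotide substitution in the designated region
#' of the target: the seed (PAM-proximal 8 nt of the protospacer) or the
#' PAM itself.
#'
#' @param genome wild-type phage genome (DNA string).
#' @param protospacer spacer-matching sequence whose target is mutated; must
#'   occur exactly on the genome (either strand).
#' @param escape_freq fraction of escaper genomes.
#' @param mutation_class "seed" or "PAM".
#' @param n_phage total particle count in the population.
#' @param seed RNG seed.
#' @param seed_len seed-region length in nt (default 8).
#' @param pam_len PAM length in nt (default 3).
#' @return object of class `phage_population`: list with `wild_genome`,
#'   `escaper_genome`, `n_wild`, `n_escaper`, `n_phage`, `escape_freq`,
#'   `mutation` (description of the escaping substitution) and the target
#'   coordinates.
#' @export
simulate_escaper_population <- function(genome, protospacer, escape_freq,
                                        mutation_class = c("seed", "PAM"),
                                        n_phage, seed = 1L,
                                        seed_len = 8L, pam_len = 3L) {
  mutation_class <- match.arg(mutation_class)
  stopifnot(escape_freq >= 0, escape_freq <= 1, n_phage >= 0)
  hit <- map_spacer(protospacer, genome, max_mismatches = 0L,
                    require_pam = FALSE)
  if (!hit$mapped)
    cc_stop("crisprcolony_invalid_target",
            "protospacer not found on the genome")
  withr::local_seed(seed)
  L <- nchar(protospacer)
  ## 0-based genome positions of the mutable window, strand-aware: the seed
  ## is the PAM-proximal end of the protospacer, the PAM is 3' of it.
  if (hit$strand == "+") {
    region0 <- if (mutation_class == "seed")
      (hit$start + L - seed_len):(hit$start + L - 1L)
    else (hit$start + L):(hit$start + L + pam_len - 1L)
  } else {
    region0 <- if (mutation_class == "seed")
      hit$start:(hit$start + seed_len - 1L)
    else (hit$start - pam_len):(hit$start - 1L)
  }
  region0 <- region0[region0 >= 0 & region0 < nchar(genome)]
  mut_pos0 <- sample(region0, 1L)
  escaper <- point_mutate(genome, mut_pos0 + 1L)
  n_escaper <- rpois(1L, escape_freq * n_phage)
  structure(list(
    wild_genome = genome, escaper_genome = escaper,
    n_escaper = n_escaper, n_wild = max(n_phage - n_escaper, 0),
    n_phage = n_phage, escape_freq = escape_freq,
    mutation = list(class = mutation_class, position = mut_pos0,
                    ref = substr0(genome, mut_pos0, 1L),
                    alt = substr0(escaper, mut_pos0, 1L)),
    target = list(start = hit$start, strand = hit$strand, length = L)
  ), class = "phage_population")
}

## can a phage genome escape targeting by `spacer`? Escape means the best
## match to the spacer now carries a seed or PAM mutation (or is gone).
escapes_spacer <- function(phage_genome, wild_genome, spacer,
                           seed_len = 8L, pam_len = 3L) {
  wt <- map_spacer(spacer, wild_genome, max_mismatches = 0L,
                   require_pam = FALSE)
  if (!wt$mapped) return(TRUE)
  L <- nchar(spacer)
  tgt <- function(g) {
    if (wt$strand == "+")
      paste0(substr0(g, wt$start, L), substr0(g, wt$start + L, pam_len))
    else
      paste0(revcomp(substr0(g, wt$start, L)),
             revcomp(substr0(g, wt$start - pam_len, pam_len)))
  }
  call <- classify_escape_mutation(tgt(wild_genome), tgt(phage_genome),
                                   seed_len = seed_len, pam_len = pam_len)
  call$class %in% c("seed", "PAM")
}

#' Simulate a spot/dilution plaque assay
#'
#' Plaque counts at each dilution are Poisson with mean equal to the number
#' of phage able to escape every host spacer, times dilution and plated
#' volume. An all-zero series is flagged below detection ("n.d.").
#'
#' @param population a [simulate_escaper_population()] result.
#' @param host_spacers character vector of spacers carried by the host
#'   (length 0 = non-CRISPR host).
#' @param dilution_factors positive fractions, e.g. `10^-(0:7)`.
#' @param volume_ml plated volume per spot (default 0.002, a 2 uL spot).
#' @param seed RNG seed.
#' @return a [plaque_assay()] object with the simulated counts.
#' @export
simulate_plaque_assay <- function(population, host_spacers, dilution_factors,
                                  volume_ml = 0.002, seed = 1L) {
  stopifnot(all(dilution_factors > 0),
            !is.unsorted(rev(dilution_factors)))   # most concentrated first
  withr::local_seed(seed)
  wt_escapes <- length(host_spacers) == 0L ||
    all(vapply(host_spacers, function(s)
      escapes_spacer(population$wild_genome, population$wild_genome, s),
      logical(1)))
  esc_escapes <- length(host_spacers) == 0L ||
    all(vapply(host_spacers, function(s)
      escapes_spacer(population$escaper_genome, population$wild_genome, s),
      logical(1)))
  plating_pfu <- population$n_wild * wt_escapes +
    population$n_escaper * esc_escapes
  ## population counts are per total stock; concentration per ml assumes the
  ## stock is held in 1 ml, so `plating_pfu` doubles as PFU/ml
  counts <- rpois(length(dilution_factors),
                  plating_pfu * dilution_factors * volume_ml)
  plaque_assay(host_id = "sim_host", dilution_factor = dilution_factors,
               plaques = counts, volume_ml = volume_ml,
               stock_titer = population$n_phage)
}

#' Simulate a time-shift resistance matrix
#'
#' The paper-style design: hosts are the founder (time 0) plus `n_colonies`
#' colonies per post-infection time point; phages are 12 stock isolates
#' (time 0) plus one phage population per colony. A documented toy
#' co-evolution rule scores each host x phage pair: a colony sampled at
#' time-rank `r` has resistance level `rate * r` (`rate` 1 for mono-spacer
#' founders, 2 for multi; the founder itself has level 1), a phage
#' population sampled at rank `r` has infectivity level `r` (stock 0), and
#' the ordinal score is 1, 0.5 or 0 as the host level exceeds, equals or
#' falls short of the phage level. Mono-founder colonies therefore plateau
#' at partial contemporary resistance (coexistence) while multi-founder
#' colonies reach full resistance, and the founder loses resistance against
#' future phage. With `noise > 0` each score is replaced by a uniform draw
#' from \{0, 0.5, 1\} with that probability.
#'
#' @param n_colonies hosts (and phage populations) per time point
#'   (default 12).
#' @param timepoints ordered post-infection sampling times in hours
#'   (default `c(24, 36, 48)`).
#' @param improvement_rule "monotone" (hosts gain resistance over time) or
#'   "none" (levels frozen; all scores identical).
#' @param founder "mono" or "multi": multi-spacer founders improve at twice
#'   the rate (rate 2 vs 1 level per time step).
#' @param noise probability a score is replaced by a random category
#'   (default 0).
#' @param seed RNG seed.
#' @return a [resistance_matrix()] object.
#' @export
simulate_timeshift <- function(n_colonies = 12L,
                               timepoints = c(24, 36, 48),
                               improvement_rule = c("monotone", "none"),
                               founder = c("mono", "multi"),
                               noise = 0, seed = 1L) {
  improvement_rule <- match.arg(improvement_rule)
  founder <- match.arg(founder)
  stopifnot(n_colonies >= 1L, !is.unsorted(timepoints))
  withr::local_seed(seed)
  rate <- if (founder == "multi") 2 else 1
  tp <- c(0, timepoints)
  rank_of <- function(t) match(t, tp) - 1L

  hosts <- data.frame(
    host_id = c("founder",
                sprintf("host_t%d_%02d", rep(timepoints, each = n_colonies),
                        rep(seq_len(n_colonies), length(timepoints)))),
    host_timepoint = c(0, rep(timepoints, each = n_colonies)),
    stringsAsFactors = FALSE
  )
  phages <- data.frame(
    phage_id = c(sprintf("stock_%02d", seq_len(12L)),
                 sprintf("phage_t%d_%02d", rep(timepoints, each = n_colonies),
                         rep(seq_len(n_colonies), length(timepoints)))),
    phage_timepoint = c(rep(0, 12L), rep(timepoints, each = n_colonies)),
    stringsAsFactors = FALSE
  )
  host_level <- if (improvement_rule == "none") rep(1, nrow(hosts)) else
    ifelse(hosts$host_timepoint == 0, 1,
           rate * rank_of(hosts$host_timepoint))
  phage_level <- if (improvement_rule == "none") rep(0, nrow(phages)) else
    rank_of(phages$phage_timepoint)

  diff <- outer(host_level, phage_level, `-`)
  scores <- matrix(0.5, nrow(hosts), nrow(phages),
                   dimnames = list(hosts$host_id, phages$phage_id))
  scores[diff > 0] <- 1
  scores[diff < 0] <- 0
  if (noise > 0) {
    flip <- matrix(runif(length(scores)) < noise, nrow(hosts))
    scores[flip] <- sample(c(0, 0.5, 1), sum(flip), replace = TRUE)
  }
  resistance_matrix(scores = scores, hosts = hosts, phages = phages)
}
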