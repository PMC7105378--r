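# Shared fixtures, built in code at test time.

# a small world: config, genome, valid protospacer sites and a founder site
# near the given position
make_world <- function(seed = 1L, genome_length = 20000L, priming_prob = 0.3,
                       local_fraction = 0.8, read_error_rate = 0,
                       founder_near = genome_length %/% 3L, ...) {
  cfg <- generator_config(genome_length = genome_length,
                          priming_prob = priming_prob,
                          local_fraction = local_fraction,
                          read_error_rate = read_error_rate,
                          rng_seed = seed, ...)
  genome <- generate_phage_genome(cfg)
  sites <- pam_sites(genome, cfg$spacer_length, cfg$pam)
  founder <- sites[which.min(abs(sites$start - founder_near)), ]
  list(cfg = cfg, genome = genome, sites = sites,
       founder_start = founder$start, founder_strand = founder$strand)
}

barcode_spec_for <- function(cfg) {
  list(leader_len = nchar(cfg$leader_seq), barcode_len = cfg$barcode_length)
}

# full simulate -> parse -> map -> pairs path on one colony
make_pairs <- function(world, n_cells, max_mismatches = 0L) {
  col <- simulate_colony(world$genome, world$founder_start, n_cells,
                         world$cfg, founder_strand = world$founder_strand,
                         sites = world$sites)
  reads <- simulate_reads(col, world$cfg)
  parsed <- parse_reads(reads, repeat_model(world$cfg$repeat_seq),
                        barcode_spec = barcode_spec_for(world$cfg))
  spacers <- unique(unlist(lapply(parsed$arrays, `[[`, "spacers")))
  hits <- map_spacers(spacers, world$genome, max_mismatches = max_mismatches,
                      pam = world$cfg$pam)
  list(colony = col, parsed = parsed, hits = hits,
       pairs = extract_pairs(parsed$arrays, hits))
}

# exact share of valid protospacer sites within +/- window of the founder
site_window_share <- function(world, window = 500L) {
  d <- abs(world$sites$start - world$founder_start)
  keep <- !(world$sites$start == world$founder_start &
              world$sites$strand == world$founder_strand)
  mean(d[keep] <= window)
}
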