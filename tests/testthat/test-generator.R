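test_that("generator_config validates its invariants", {
  cfg <- generator_config()
  expect_s3_class(cfg, "generator_config")
  expect_error(generator_config(priming_prob = 1.2),
               class = "crisprcolony_config_error")
  expect_error(generator_config(genome_length = 50, spacer_length = 30),
               class = "crisprcolony_config_error")
  expect_error(generator_config(repeat_seq = ""),
               class = "crisprcolony_config_error")
  expect_error(generator_config(repeat_seq = "ACGT", leader_seq = "ACGT"),
               class = "crisprcolony_config_error")
})

test_that("generate_phage_genome: length, determinism, GC content", {
  cfg <- generator_config(genome_length = 10000L, rng_seed = 1L)
  g <- generate_phage_genome(cfg)
  expect_equal(nchar(g), 10000L)
  expect_true(all(strsplit(g, "")[[1]] %in% c("A", "C", "G", "T")))
  expect_identical(g, generate_phage_genome(cfg))
  expect_error(generate_phage_genome(generator_config(genome_length = 999L,
                                                      spacer_length = 30L)),
               class = "crisprcolony_config_error")

  ## binomial oracle: GC fraction within 3 SE of the target
  cfg2 <- generator_config(genome_length = 100000L, gc_content = 0.5,
                           rng_seed = 42L)
  gc <- mean(strsplit(generate_phage_genome(cfg2), "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.5 * 0.5 / 100000))
})

test_that("pam_sites agrees with exhaustive per-site PAM validation", {
  w <- make_world(seed = 11L, genome_length = 2000L)
  L <- w$cfg$spacer_length
  lg <- nchar(w$genome)
  expected <- do.call(rbind, lapply(c("+", "-"), function(st) {
    s <- 0:(lg - L)
    ok <- vapply(s, function(x) oracle_pam_ok(w$genome, x, st, L), logical(1))
    data.frame(start = s[ok], strand = st, stringsAsFactors = FALSE)
  }))
  got <- w$sites[order(w$sites$strand, w$sites$start), ]
  expected <- expected[order(expected$strand, expected$start), ]
  rownames(got) <- rownames(expected) <- NULL
  expect_equal(got, expected)
})

test_that("simulate_colony: degenerate rates, forced mixture, closed form", {
  w <- make_world(seed = 2L, priming_prob = 0)
  col <- simulate_colony(w$genome, w$founder_start, 50, w$cfg,
                         founder_strand = w$founder_strand, sites = w$sites)
  expect_true(all(vapply(col$arrays, `[[`, integer(1), "n_spacers") == 1L))
  expect_true(all(vapply(col$arrays, function(a) a$spacers[a$n_spacers],
                         character(1)) == col$founder_spacer))

  ## forced local mixture: every primed target within the window
  w1 <- make_world(seed = 3L, priming_prob = 0.9, local_fraction = 1)
  col1 <- simulate_colony(w1$genome, w1$founder_start, 300, w1$cfg,
                          founder_strand = w1$founder_strand, sites = w1$sites)
  primed <- col1$truth[col1$truth$primed, ]
  expect_gt(nrow(primed), 0)
  expect_true(all(abs(primed$position - w1$founder_start) <= 500))

  ## closed-form multi-spacer fraction: P(>= 1 extra) = priming_prob
  w2 <- make_world(seed = 4L, priming_prob = 0.3)
  col2 <- simulate_colony(w2$genome, w2$founder_start, 10000, w2$cfg,
                          founder_strand = w2$founder_strand, sites = w2$sites)
  n <- vapply(col2$arrays, `[[`, integer(1), "n_spacers")
  expect_true(all(n >= 1L & n <= w2$cfg$max_spacers))
  expect_lt(abs(mean(n >= 2) - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))

  ## invalid founder target
  bad <- 0L
  while (any(w$sites$start == bad & w$sites$strand == "+")) bad <- bad + 1L
  expect_error(simulate_colony(w$genome, bad, 10, w$cfg, sites = w$sites),
               class = "crisprcolony_invalid_target")
})

test_that("simulate_reads has the amplicon structure and exact error-free round trip", {
  w <- make_world(seed = 5L, priming_prob = 0)
  col <- simulate_colony(w$genome, w$founder_start, 5, w$cfg,
                         founder_strand = w$founder_strand, sites = w$sites)
  reads <- simulate_reads(col, w$cfg)
  ## error rate 0, 1-spacer array: exactly two repeat copies
  n_rep <- lengths(gregexpr(w$cfg$repeat_seq, reads$sequence, fixed = TRUE))
  expect_true(all(n_rep == 2L))
  expect_true(all(startsWith(reads$sequence,
                             paste0(col$barcode, w$cfg$leader_seq,
                                    w$cfg$repeat_seq))))

  ## parser round trip recovers arrays exactly, in simulated order
  w3 <- make_world(seed = 6L, priming_prob = 0.6)
  col3 <- simulate_colony(w3$genome, w3$founder_start, 400, w3$cfg,
                          founder_strand = w3$founder_strand, sites = w3$sites)
  reads3 <- simulate_reads(col3, w3$cfg)
  parsed <- parse_reads(reads3, repeat_model(w3$cfg$repeat_seq),
                        barcode_spec = barcode_spec_for(w3$cfg))
  expect_equal(unname(parsed$stats[["parseable"]]), 400L)
  for (i in seq_along(col3$arrays)) {
    expect_identical(parsed$arrays[[i]]$spacers, col3$arrays[[i]]$spacers)
    expect_identical(parsed$arrays[[i]]$barcode, col3$barcode)
  }
})

test_that("simulated reads are byte-identical for a fixed config + seed", {
  w <- make_world(seed = 9L, priming_prob = 0.5, read_error_rate = 0.001)
  col <- simulate_colony(w$genome, w$founder_start, 50, w$cfg,
                         founder_strand = w$founder_strand, sites = w$sites)
  r1 <- simulate_reads(col, w$cfg)
  r2 <- simulate_reads(col, w$cfg)
  expect_identical(r1, r2)
})

test_that("simulate_escaper_population places the mutation and obeys rates", {
  w <- make_world(seed = 7L)
  sp <- substr(w$genome, w$founder_start + 1L,
               w$founder_start + w$cfg$spacer_length)
  if (w$founder_strand == "-") sp <- oracle_revcomp(sp)

  pop0 <- simulate_escaper_population(w$genome, sp, 0, "seed", 1e6, seed = 1L)
  expect_equal(pop0$n_escaper, 0)
  expect_identical(pop0$n_wild, 1e6)

  ## expected 20,000 escapers at freq 1e-5 in 2e9 particles (Poisson)
  pop <- simulate_escaper_population(w$genome, sp, 1e-5, "seed", 2e9,
                                     seed = 2L)
  expect_lt(abs(pop$n_escaper - 20000), 4 * sqrt(20000))

  ## closed loop: the planted mutation classifies as its own class, for
  ## founders on either strand
  for (cls in c("seed", "PAM")) {
    p <- simulate_escaper_population(w$genome, sp, 1e-5, cls, 1e6, seed = 3L)
    L <- nchar(sp)
    tgt <- function(g) {
      if (p$target$strand == "+")
        substr(g, p$target$start + 1L, p$target$start + L + 3L)
      else
        oracle_revcomp(substr(g, p$target$start - 2L, p$target$start + L))
    }
    call <- classify_escape_mutation(tgt(p$wild_genome), tgt(p$escaper_genome))
    expect_identical(call$class, cls)
  }

  expect_error(simulate_escaper_population(w$genome, strrep("A", 30), 0.1,
                                           "seed", 1e6),
               class = "crisprcolony_invalid_target")
})

test_that("simulate_plaque_assay: Poisson means, multi-spacer below detection", {
  w <- make_world(seed = 8L)
  sp <- crisprcolony:::protospacer_seq(w$genome, w$founder_start,
                                       w$founder_strand,
                                       w$cfg$spacer_length)
  pop <- simulate_escaper_population(w$genome, sp, 1e-5, "seed", 1e9,
                                     seed = 4L)

  ## host with no spacers sees the full titer
  counts <- vapply(1:50, function(i) {
    simulate_plaque_assay(pop, character(0), 1e-6, seed = 1000L + i)$spots$plaques
  }, numeric(1))
  expect_lt(abs(mean(counts) - 1e9 * 1e-6 * 0.002), 3 * sqrt(2000 / 50))

  ## host with the targeting spacer sees only escapers
  a1 <- simulate_plaque_assay(pop, sp, 1, seed = 5L)
  expect_lt(abs(a1$spots$plaques - pop$n_escaper * 0.002),
            4 * sqrt(pop$n_escaper * 0.002))

  ## three spacers, independent escape of all required: below detection
  far <- w$sites[abs(w$sites$start - w$founder_start) > 100, ]
  others <- far[c(1L, nrow(far)), ]
  sp2 <- crisprcolony:::protospacer_seq(w$genome, others$start[1],
                                        others$strand[1], 30)
  sp3 <- crisprcolony:::protospacer_seq(w$genome, others$start[2],
                                        others$strand[2], 30)
  a3 <- simulate_plaque_assay(pop, c(sp, sp2, sp3), 10^-(0:3), seed = 6L)
  expect_true(all(a3$spots$plaques == 0))
  expect_true(titer(a3)$below_detection)
})

test_that("simulate_timeshift obeys its documented rule", {
  ## no improvement: all scores identical
  m0 <- simulate_timeshift(4, c(24, 36, 48), "none", noise = 0, seed = 1L)
  expect_equal(length(unique(as.vector(m0$scores))), 1L)

  ## monotone rule recovered by mean_resistance (the rule is the oracle)
  m <- simulate_timeshift(12, c(24, 36, 48), "monotone", "mono",
                          noise = 0, seed = 2L)
  expect_equal(dim(m$scores), c(1L + 3L * 12L, 12L + 3L * 12L))
  tr <- trajectories(m)
  for (pt in c(0, 24, 36, 48)) {
    sub <- tr[tr$phage_timepoint == pt, ]
    agg <- aggregate(mean_score ~ host_timepoint, sub, mean)
    agg <- agg[order(agg$host_timepoint), ]
    expect_true(all(diff(agg$mean_score) >= 0))
  }
  ## contemporary resistance of the sampled colonies non-decreasing in time
  ct <- tr[tr$contemporary & tr$host_timepoint > 0, ]
  agg <- aggregate(mean_score ~ host_timepoint, ct, mean)
  expect_true(all(diff(agg$mean_score[order(agg$host_timepoint)]) >= 0))
})
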