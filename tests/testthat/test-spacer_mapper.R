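test_that("map_spacer finds planted hits with strand symmetry", {
  w <- make_world(seed = 30L, genome_length = 5000L)
  s <- w$sites[w$sites$strand == "+", ][5L, ]
  spacer <- substr(w$genome, s$start + 1L, s$start + 30L)

  hit <- map_spacer(spacer, w$genome)
  expect_true(hit$mapped)
  expect_equal(hit$start, s$start)
  expect_identical(hit$strand, "+")
  expect_equal(hit$mismatches, 0L)
  expect_identical(substr(hit$pam, 2, 3), "GG")

  ## reverse complement: same interval, flipped strand. The rc'd spacer has
  ## its PAM on the minus strand, so validation must be off for this probe.
  rc <- map_spacer(oracle_revcomp(spacer), w$genome, require_pam = FALSE)
  expect_equal(rc$start, hit$start)
  expect_identical(rc$strand, "-")

  ## strand involution across many simulated spacers
  picks <- w$sites[seq(1, nrow(w$sites), length.out = 20), ]
  for (i in seq_len(nrow(picks))) {
    sp <- crisprcolony:::protospacer_seq(w$genome, picks$start[i],
                                         picks$strand[i], 30L)
    a <- map_spacer(sp, w$genome, require_pam = FALSE)
    b <- map_spacer(oracle_revcomp(sp), w$genome, require_pam = FALSE)
    if (!a$ambiguous && !b$ambiguous) {
      expect_equal(b$start, a$start)
      expect_true(b$strand != a$strand)
    }
  }
})

test_that("map_spacer matches the exhaustive both-strand Hamming oracle", {
  set.seed(31)
  w <- make_world(seed = 31L, genome_length = 3000L)
  for (i in 1:40) {
    kind <- i %% 4
    if (kind == 0) {                       # clean planted
      s <- w$sites[sample.int(nrow(w$sites), 1), ]
      sp <- crisprcolony:::protospacer_seq(w$genome, s$start, s$strand, 30L)
    } else if (kind == 1) {                # planted with 1-2 substitutions
      s <- w$sites[sample.int(nrow(w$sites), 1), ]
      sp <- crisprcolony:::protospacer_seq(w$genome, s$start, s$strand, 30L)
      for (e in seq_len(sample(1:2, 1)))
        sp <- crisprcolony:::point_mutate(sp, sample(nchar(sp), 1))
    } else if (kind == 2) {                # random (usually unmapped)
      sp <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    } else {                               # planted, PAM validation off path
      s <- w$sites[sample.int(nrow(w$sites), 1), ]
      sp <- crisprcolony:::protospacer_seq(w$genome, s$start, s$strand, 30L)
    }
    for (rp in c(TRUE, FALSE)) {
      got <- map_spacer(sp, w$genome, max_mismatches = 2L, require_pam = rp)
      exp <- oracle_map_spacer(sp, w$genome, max_mismatches = 2L,
                               require_pam = rp)
      expect_equal(got$mapped, exp$mapped)
      if (exp$mapped) {
        expect_equal(got$start, exp$start)
        expect_identical(got$strand, exp$strand)
        expect_equal(got$mismatches, exp$mismatches)
        expect_equal(got$ambiguous, exp$ambiguous)
      }
    }
  }
})

test_that("ambiguous and unmapped spacers are flagged, short spacers rejected", {
  set.seed(32)
  base <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  sp <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  ## plant the same protospacer + AGG twice
  genome <- paste0(base, sp, "AGG", paste(rep("T", 50), collapse = ""),
                   sp, "AGG", base)
  hit <- map_spacer(sp, genome, max_mismatches = 0L)
  expect_true(hit$mapped)
  expect_true(hit$ambiguous)
  expect_equal(hit$start, 2000L)   # first best hit reported

  miss <- map_spacer(strrep("ACGTG", 6), paste(rep("A", 3000), collapse = ""))
  expect_false(miss$mapped)
  expect_error(map_spacer("ACGTACGTACGT", genome),
               class = "crisprcolony_precondition_error")
})

test_that("every simulated spacer maps back to its truth position", {
  w <- make_world(seed = 33L, priming_prob = 0.6)
  col <- simulate_colony(w$genome, w$founder_start, 300, w$cfg,
                         founder_strand = w$founder_strand, sites = w$sites)
  hits <- map_spacers(unique(col$truth$spacer), w$genome,
                      max_mismatches = 0L)
  m <- hits[match(col$truth$spacer, hits$spacer), ]
  ok <- m$mapped & !m$ambiguous
  expect_equal(m$start[ok], col$truth$position[ok])
  expect_equal(m$strand[ok], col$truth$strand[ok])
  expect_true(all(m$mismatches[ok] == 0L))
  expect_gt(mean(ok), 0.99)
})

test_that("validate_pam: IUPAC semantics and genome-end flag", {
  genome <- paste0(strrep("T", 50), "AGG", strrep("T", 10))
  hit <- list(start = 20L, strand = "+", length = 30L)   # PAM at 50..52
  expect_true(as.logical(validate_pam(genome, hit, "NGG")))
  expect_false(as.logical(validate_pam(genome, hit, "NGA")))

  genome2 <- paste0(strrep("T", 50), "AGT", strrep("T", 10))
  expect_false(as.logical(validate_pam(genome2, hit, "NGG")))

  ## purine-rich alternative patterns
  expect_true(as.logical(validate_pam(genome, hit, "NRG")))

  ## PAM window off the genome end: false + flag
  tail_hit <- list(start = nchar(genome) - 30L, strand = "+", length = 30L)
  v <- validate_pam(genome, tail_hit, "NGG")
  expect_false(as.logical(v))
  expect_true(attr(v, "end_of_genome"))

  ## minus-strand PAM: CCN upstream on the plus strand
  genome3 <- paste0(strrep("T", 10), "CCA", strrep("G", 30), strrep("T", 10))
  minus_hit <- list(start = 13L, strand = "-", length = 30L)
  expect_true(as.logical(validate_pam(genome3, minus_hit, "NGG")))
  edge <- list(start = 2L, strand = "-", length = 30L)
  v2 <- validate_pam(genome3, edge, "NGG")
  expect_false(as.logical(v2))
  expect_true(attr(v2, "end_of_genome"))
})

test_that("classify_escape_mutation: classes, offsets, precedence", {
  set.seed(34)
  proto <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  wt <- paste0(proto, "TGG")

  ## identical: none
  none <- classify_escape_mutation(wt, wt)
  expect_identical(none$class, "none")
  expect_length(none$positions, 0L)

  ## substitution in the GG of the PAM
  mut <- wt
  substr(mut, 32, 32) <- if (substr(wt, 32, 32) == "A") "C" else "A"
  pam_call <- classify_escape_mutation(wt, mut)
  expect_identical(pam_call$class, "PAM")
  expect_equal(pam_call$positions, -2L)

  ## substitution 3 nt from the PAM-proximal end: seed
  mut2 <- wt
  substr(mut2, 28, 28) <- if (substr(wt, 28, 28) == "A") "C" else "A"
  seed_call <- classify_escape_mutation(wt, mut2)
  expect_identical(seed_call$class, "seed")
  expect_equal(seed_call$positions, 3L)

  ## PAM-distal substitution: distal; boundary at seed_len
  mut3 <- wt
  substr(mut3, 5, 5) <- if (substr(wt, 5, 5) == "A") "C" else "A"
  expect_identical(classify_escape_mutation(wt, mut3)$class, "distal")
  mut4 <- wt
  substr(mut4, 23, 23) <- if (substr(wt, 23, 23) == "A") "C" else "A"
  expect_identical(classify_escape_mutation(wt, mut4)$class, "seed")  # offset 8
  expect_identical(classify_escape_mutation(wt, mut4, seed_len = 6L)$class,
                   "distal")

  ## precedence PAM > seed > distal, all positions reported
  mut5 <- mut
  substr(mut5, 28, 28) <- if (substr(wt, 28, 28) == "A") "C" else "A"
  substr(mut5, 5, 5) <- if (substr(wt, 5, 5) == "A") "C" else "A"
  multi <- classify_escape_mutation(wt, mut5)
  expect_identical(multi$class, "PAM")
  expect_setequal(multi$positions, c(-2L, 3L, 26L))

  expect_error(classify_escape_mutation(wt, substr(wt, 1, 10)),
               class = "crisprcolony_input_error")
})
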