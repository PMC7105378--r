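---
title: "Models and methods behind crisprcolony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crisprcolony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprcolony)
```

# The biological setting

A type II-A CRISPR-Cas system (Cas9, a repeat-spacer array, a leader)
immunizes bacteria against a lytic phage. On solid media, each surviving
colony descends from a single founder cell that acquired one spacer upon
infection. As the colony grows under continued phage pressure, escaper
phage — carrying point mutations in the seed region (the PAM-proximal
6–8 nt of the protospacer) or in the PAM itself — select for cells that
have acquired *additional* spacers. Acquisition in immune cells is
*primed*: Cas9 cleavage at the existing target produces free DNA ends
that feed the adaptation machinery, so new spacers come preferentially
from the ~500 bp flanking the existing target. The package quantifies
this process from four kinds of data: CRISPR-locus amplicon reads, a
phage reference genome, plaque-count tables, and time-shift resistance
scores.

# Array parsing

Reads have the structure `barcode + leader + repeat + (spacer + repeat)*n`.
Repeat copies are found by substitution-only fuzzy matching (default
tolerance 2 mismatches in a 36-nt repeat), selected greedily left to
right without overlap; spacers are the inter-repeat segments, accepted if
their length lies in a configurable window (default 20–45 nt; the guide
pairs over ~20 nt but observed type II spacers are longer, so the bounds
are permissive). Reads with fewer than two repeat copies are counted
*unparseable*; reads with an out-of-bounds segment are counted
*malformed*; conservation `parseable + unparseable + malformed = total`
is enforced by construction and tested. Reads are scanned in sequencing
orientation only, because amplicon primer pairs fix the orientation.

Two conventions matter everywhere downstream:

* **Leader-proximal = most recent.** New spacers insert at the leader end
  of the array, so the *founder* (chronologically first) spacer is the
  leader-**distal** element of the parsed array.
* **Mono/multi call.** A colony is called *multi* iff its multi-spacer
  read fraction strictly exceeds 2%, the empirical minimum at which a
  second PCR band is visible from an amplified array. Strict inequality
  follows from reading the threshold as the minimal detectable fraction.

Barcodes (a randomized plasmid tag upstream of the leader) are cut from a
fixed window upstream of the first repeat; `barcode_concordance()` checks
clonality as the fraction of barcode groups sharing a single founder
spacer.

# Spacer mapping

`map_spacer()` reports the best substitution-only hit over both strands
(fewest mismatches; ties flagged `ambiguous` and excluded from distance
analyses). Coordinates are 0-based half-open on the plus strand,
distances use protospacer starts. PAM validation checks the bases
immediately 3′ of the protospacer *on the protospacer-bearing strand*
against an IUPAC pattern. The default PAM is `NGG` — the canonical
*S. pyogenes* Cas9 motif — and is a configuration knob so other type II
systems (e.g. *S. thermophilus* CRISPR1) can be analyzed with their own
motif. The default mapping tolerance is 2 substitutions; no gapped
alignment is offered because escaper variation in this system is
substitution-only at the analyzed scales. Escape mutations are classified
with PAM-proximal numbering (offset 1 = protospacer base nearest the PAM,
negative offsets inside the PAM), with precedence PAM > seed > distal when
several positions differ; the seed length defaults to 8, the upper end of
the critical 6–8 nt window.

# Priming statistics

For every read with ≥ 2 spacers, the chronological (first, second) pair
is the two leader-distal-most elements. The standard readout counts
**distinct second-spacer sequences per 1-kb signed-distance bin**, origin
at each pair's own first target; `distance_histogram()` reproduces this
(duplication-invariant by construction). `local_enrichment()` compares
the fraction of second targets within ±500 bp of the first target to a
uniform-placement null (window share of the genome, truncated at the
linear ends — the phage genome is treated as linear throughout, since
packaged DNA is injected from a defined end).

**A deliberate design choice:** the enrichment statistic supports two
counting bases. `use = "distinct"` mirrors the figure semantics, but it
cannot recover the generator's `local_fraction`: only a few hundred valid
protospacers exist within ±500 bp, so distinct counting saturates as
pairs accumulate, deflating the local fraction regardless of the true
mixture weight. `use = "pairs"` (the default) counts every pair and makes
the mixture identity `observed = lf + (1 − lf)·p_unif` exact, so
`est_local_fraction = (observed − p_unif)/(1 − p_unif)` is a consistent
estimator. Both observed fractions are always reported.

# Escape quantification

* `titer()` uses the single most-dilute spot in the countable range
  (default 1–200 plaques per 2 µl spot) — the spot-assay convention — and
  reports the exact Poisson (Garwood) interval. A pooled multi-spot
  estimator is available as an option. All-zero series yield a
  below-detection result carrying the one-plaque limit at the
  least-dilute spot; below-detection EOPs are reported as one-sided upper
  bounds, never as zero.
* `eop()` is test titer over total stock particles; for a host carrying a
  single targeting spacer this *is* the escaper frequency for that
  spacer.
* `spike_escapers()` solves `(f·N + x)/(N + x) = f_target` exactly; for a
  2×10⁹ PFU stock from 10⁻⁸ to 10⁻⁵ it returns ≈ 2.0×10⁴ PFU, the scale
  used experimentally.

# Time-shift analysis

Resistance is ordinal: growth in the phage spot = 1, clear spot = 0,
partial inhibition = 0.5. Scores form a hosts × phages matrix with hour
labels (host time 0 = the founder; phage time 0 = ancestral stock
isolates). Means are taken per host per phage time point over
*non-missing* entries only — missing cells (e.g. a time point with 11 of
12 samples recovered) are excluded from denominators, not imputed, and
the tests verify that NA-encoding and row deletion give identical means.
`mean_resistance()` accepts several phage time points at once so the
founder-versus-all-future-phage summary can be computed pooled or
per-time-point; values like 0.5 and 0.83 are exactly representable
(halves) or reported at 2 decimals.

# The synthetic-data generator

The generator is first-class, tested code; its defaults state the world
being emulated:

| parameter | default | why |
|---|---|---|
| `genome_length` | 45,000 bp | typical staphylococcal siphovirus genome scale (tests use 20 kb for speed and say so) |
| `gc_content` | 0.33 | AT-rich staphylococcal phage |
| `repeat_seq` | 36-nt type II-A repeat | the repeat length of the emulated locus; the true sequence is configuration, not data |
| `barcode_length` | 10 nt | a randomized plasmid tag upstream of the first repeat |
| `spacer_length` | 30 nt | typical type II spacer |
| `naive_rate` | 1e-7 | ~1 in 10⁷ naive infected cells survive by acquisition |
| `priming_prob` | 0.3 | per-cell probability of each additional spacer; geometric stopping capped at 4 spacers, the most ever observed |
| `local_fraction` / `local_window` | 0.8 / 500 bp | strong local priming bias; the window is the flanking region with marked enrichment |
| `escape_freq` | 1e-7 | 1 in 10⁶–10⁷ phage escape a given spacer |
| `read_error_rate` | 1e-3 | typical merged-amplicon substitution rate |

Colonies are clonal: one founder spacer, one barcode; extra spacers are
drawn from a mixture of uniform-within-window and uniform-over-all-valid
protospacers (a position is valid iff the PAM matches downstream on its
strand). Escaper populations carry a single uniform-random substitution
in the designated seed or PAM region; plaque counts are Poisson with mean
(escaping PFU) × dilution × volume. The time-shift simulator uses a
documented toy rule — host level `rate·t_rank` (founder 1; rate 1 for
mono-, 2 for multi-spacer founders) versus phage level `t_rank`, scored
1/0.5/0 by the sign of the difference — because no quantitative
co-evolution model exists for these assays; the rule only encodes the
qualitative expectations (founders lose ground to future phage,
multi-spacer founders gain resistance faster). A green test against this
generator establishes that the *pipeline arithmetic* is right, not that
real communities behave this way: the generator has no spatial structure,
no phage diffusion, no selection during colony growth, no chimeric or
quality-degraded reads, and its priming mixture is stationary.

# Numerical choices and degenerate inputs

* All RNG is seeded through configs/arguments; identical config + seed
  gives byte-identical outputs (tested).
* Greedy repeat selection breaks overlap ties leftmost-first; equal-start
  ties cannot occur for a fixed-width pattern.
* Best-hit ties in mapping set `ambiguous` and report the first hit
  (smallest start, "+" before "−") for determinism.
* Zero parseable reads, all-missing score rows, below-detection stocks,
  targets without a valid PAM, and PAM windows off the genome end raise
  classed errors or flags rather than silent values.
* Sub-seeds derived from a user seed stay far below 2³¹.

# Known limitations

* Substitution-only matching everywhere; indel-containing reads lose
  their arrays (counted, not recovered).
* The uniform null for enrichment uses the bp-window share by default;
  the exact site share can be supplied when the site list is known.
* The distinct-spacer histogram is a descriptive readout; no model-based
  inference of priming directionality is attempted.
* CLI subcommands cover the common paths; unusual layouts (multi-record
  genomes, per-colony pooling choices) are library-level options.
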