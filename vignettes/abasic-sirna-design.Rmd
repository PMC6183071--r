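---
title: "Designing off-target-free siRNAs with an abasic pivot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing off-target-free siRNAs with an abasic pivot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abasicsirna)
```

## The problem

An siRNA guide strand silences its intended transcript through full
complementarity, but its seed region (guide positions 2-7) also behaves
like a microRNA seed and represses hundreds of unintended transcripts.
Replacing the base at guide position 6 — the *pivot*, the position thought
to trigger the transition from initial seed nucleation to full pairing —
with an abasic spacer (a backbone unit carrying no base) abolishes this
microRNA-like off-target repression. The cost is that the initial pairing
with the on-target site, *transitional nucleation*, shrinks from five base
pairs (positions 2-6) to four (positions 2-5), and whether the siRNA keeps
its on-target potency then depends on how stable those four base pairs
are. Too weak and target recognition fails; too stable (in practice,
GC-stretch-like sequences) and potency also drops.

This package implements the resulting design procedure: score
transitional-nucleation stability with a nearest-neighbor duplex energy
model, keep the nucleation 4-mers whose stability falls in the empirically
supported potency window of −6 to −3.5 kcal/mol, and scan coding sequences
for 19-nt target sites that pass this and the other standard siRNA design
rules.

## The energy model

The thermodynamic engine computes the free energy at 37 °C of a short RNA
core hybridized to its perfect Watson-Crick reverse complement, using the
Turner 2004 nearest-neighbor parameters:

$$\Delta G = \Delta G_{\mathrm{init}} + \sum_i \Delta G_{\mathrm{stack}}(i)
  + \Delta G_{\mathrm{AU}}^{\mathrm{ends}} + \Delta G_{\mathrm{NN}}^{\mathrm{ends}},$$

with a duplex initiation of +4.10 kcal/mol, a +0.50 kcal/mol penalty per
terminal A:U pair, and — the one non-obvious convention — an *N-padding*
term: one unknown base (N) is appended at both ends of both strands, so
each helix end is scored with the parameter table's unknown-base terminal
mismatch instead of sequence-specific dangling ends. Padding removes the
artificial dangling-end contributions that otherwise distort energies of
very short (4-5 nt) cores. Reference duplex programs apply exactly this
scoring to N-padded input, which is how the convention is cross-checked in
the test suite (`RNAduplex` serves as an independent oracle and can be
selected at run time with `thermo_config(engine = "oracle")`).

An *interior* N — the abasic pivot — is unpaired on both strands and
splits the helix; it is scored as a 1×1 internal loop over unknown bases.
Consequently, for any guide with an abasic position 6,
$\Delta G[2{:}6] \equiv \Delta G[2{:}5]$: the extra column contributes
nothing.

Numerical choices worth knowing:

* Energies are summed as integer tenths of kcal/mol (the tabulated
  resolution), so results are exact and independent of summation order;
  they are reported as doubles in kcal/mol.
* The engine scores the *fully paired* duplex — that is the quantity of
  interest for perfectly complementary regions. A minimum-free-energy
  program may instead fray a helix when an interior N leaves fewer than
  about four pairable bases on one side. Within the geometry this method
  uses (a single abasic pivot at position 6 inside regions 2-5, 2-6 or
  2-19, i.e. flanks of at least four bases), the fully paired duplex is
  also the minimum-energy structure and the two agree exactly; the test
  suite checks this on thousands of random cores.
* Degenerate inputs error out rather than returning something quiet:
  all-N cores, runs of more than one interior N, and cores without two
  contiguous pairable bases are rejected.
* Only Watson-Crick pairs occur (the complement strand is derived, never
  supplied), so G:U wobble parameters are not needed.

The parameter table ships as a versioned plain-text file
(`inst/extdata/nn_rna_turner2004.tsv`) holding the sixteen Watson-Crick
stack doublets, the initiation and terminal-A:U scalars, and the
unknown-base terminal-mismatch and 1×1-loop terms per closing pair.

## The potency catalog

`build_potency_catalog()` enumerates all $4^k$ nucleation k-mers (k = 4
for abasic-pivot siRNAs), scores each with the engine, and flags those
inside the window. Both window bounds are inclusive, matching how the
window is stated. Energies are rounded to 0.01 kcal/mol before the window
test; since the engine works in exact tenths this is a no-op today, but it
pins the behavior should a future parameter set carry more decimals. Under
the default window exactly 94 of the 256 4-mers are selected, and the
selected set is closed under reverse complement (a consequence of the
stack table's symmetry). `energy_ecdf()` and `ks_two_sample()` provide the
cumulative-fraction machinery used to compare nucleation-stability
distributions; the KS p-value is the asymptotic two-sided one, the
convention of the common scientific-computing routines, rather than the
exact small-sample computation.

## The target-site filter cascade

`design()` slides a 19-nt window over each coding sequence. The guide is
the reverse complement of the sense window (guide position *i* pairs
target position 20 − *i*; this is the only orientation under which the
position-1-U and position-19-G/C rules cohere). A window is accepted only
if all of the following hold, each reported by a named reason code from
`filter_window()`:

| rule | default | rationale |
|---|---|---|
| `POS1_NOT_U` | guide position 1 is U | efficient Argonaute loading |
| `NUCLEATION_NOT_POTENT` | guide 2-5 in the 94-mer catalog | the potency window |
| `ORF_EDGE` | no window base within 100 nt of either CDS end | avoid terminal ORF regions |
| `STRETCH` | no mononucleotide or G/C-only run ≥ 4 nt in the guide | low-complexity and GC-stretch artifacts |
| `GC_CONTENT` | 6-10 G/C in 19 nt (32-52%) | duplex stability balance |
| `POS19_NOT_GC` | guide position 19 is G or C | blocks passenger-strand loading |
| `MASKED` | no overlap with mask intervals | SNPs and repeats are untrustworthy |

The integer G/C count (6-10 of 19) is the normative bound; the percentage
is derived from it. The stretch threshold of four is the stricter of the
two plausible readings of "stretches over four bases" and is configurable
(`design_config(stretch_len = )`), as are the window, the G/C bounds and
the edge exclusion.

Accepted windows then pass a transcriptome-uniqueness check against an
exact 19-mer index of the full input FASTA: every occurrence of the site
must belong to the intended gene. By default the site must additionally
occur at most once per transcript of that gene (strict mode;
`unique_within_gene = FALSE` relaxes it to cross-gene uniqueness only).
The scan is sense-strand, exact-match, CDS-only: mismatch-tolerant
off-target search is deliberately out of scope because the abasic pivot,
not site scarcity, is the off-target solution here.

Coordinates are 0-based half-open internally and 1-based inclusive in the
written TSV. Output is sorted by gene, then nucleation energy (most stable
first within the window), then position — a deterministic default chosen
here; users are expected to re-sort as they see fit.

## Screening and reporter statistics

* `select_high_confidence()` filters screening tables to guides with U (or
  U/A) at position 1 and, optionally, negative strand bias
  $\Delta\Delta G = \Delta G[2{:}6](\mathrm{antisense}) -
  \Delta G[2{:}6](\mathrm{sense})$, reporting both counts separately.
* `weighted_family_energy()` is the sequencing-frequency-weighted mean
  $\sum_i f_i \Delta G_i / \sum_i f_i$ used for small-RNA families.
* `normalized_correlation()` returns the squared Pearson correlation
  between log2 abundance and target-site count, optionally with the count
  divided by $-\Delta G$; the energy-normalized form is the one that
  linearizes site counts generated under an energy-proportional model.
* `bin_activity_by_energy()` averages activities in left-closed energy
  bins anchored at 0 kcal/mol — anchoring makes the binning reproducible
  regardless of the data's range.
* `fit_ic50()` fits the four-parameter logistic
  $r(c) = \mathrm{floor} + (\mathrm{ceiling} - \mathrm{floor}) /
  (1 + (c/\mathrm{IC}_{50})^{h})$ to all replicate points (not dose
  means), with deterministic data-driven initialization, bounds
  $h \in (0, 10]$, $\mathrm{floor} \ge 0$, and free asymptotes by default
  (`fix_asymptotes = TRUE` constrains them to 0 and 1). Flat dose tables
  and optimizer failures return `converged = FALSE` instead of raising.
  The fit is scale-equivariant in concentration.
* `relative_on_target()` is $\log_2(\mathrm{IC}_{50}^{WT} /
  \mathrm{IC}_{50}^{6\emptyset})$; values near 0 mean the abasic-pivot
  version conserved on-target activity.
* `cumulative_derepression()` compares fold-change ECDFs of a target set
  against the background with the KS test: a left-shifted target ECDF
  indicates repression, coincidence indicates derepression.

## What the synthetic data emulate — and what they do not

The fixtures module makes the whole pipeline testable offline.

`synth_transcriptome()` builds random CDSs (default: six genes of 450-800
nt at 50% GC) and embeds, working backwards from a sampled potent 4-mer
and the position-1/19 constraints, sites guaranteed to satisfy every rule;
decoys that each violate exactly one named rule; and duplicate sites
planted into two genes to exercise the uniqueness check. A deterministic
sweep then mutates any *unplanned* window that would pass the cascade (a
single targeted base change outside all planted windows), so the truth
table is exhaustive and `design()` must recover exactly its accept rows.
The generator does not emulate codon structure, isoform families, real SNP
spectra or genomic k-mer statistics — passing tests demonstrate the
correctness of the scanning logic, not genome-scale candidate yields.

`synth_screen()` draws random 19-nt duplexes and assigns activities from a
piecewise-linear energy-activity relation: a plateau (default 0.85) inside
the potency window and linear decline (0.25 per kcal/mol) outside, plus
Gaussian noise (sd 0.05). This reproduces the *shape* that motivates the
window — activity loss on both flanks — not any particular screen's
values.

`synth_dose_response()` draws four-parameter logistic responses on a
log-spaced ladder (default 10^-3 to 10^2 nM, 8 doses, 6 replicates, noise
sd 0.05, IC50 0.1 nM) for parameter-recovery tests.

All generators are seeded once per run from the spec; the same spec
reproduces byte-identical files, and written tables carry the spec in a
header comment.

## Problem sizes used by the test suite

The suite verifies the designer against an independent brute-force
re-implementation on twenty synthetic transcriptomes of roughly 2-5 kb
each, checks engine-versus-reference agreement on a thousand random cores
in a single batched oracle call, and runs one hundred seeded simulations
for IC50 recovery (median error under 20% at noise sd 0.05, exact recovery
at zero noise) and for the energy-normalized correlation comparison.
These sizes were chosen to exercise every code path densely while keeping
the default test run comfortably fast.

## Known limitations

* The energy model covers perfectly complementary duplexes with at most a
  single interior abasic/unknown position; no general secondary structure,
  bulges, wobble pairs or temperature dependence beyond 37 °C.
* Uniqueness is exact-match over the supplied CDS FASTA; UTRs, introns and
  mismatch-tolerant matches are out of scope, as are genome-to-transcript
  coordinate liftovers (masks are consumed in transcript coordinates).
* The high-confidence screening selector consumes activity values as
  given; converting raw reporter readouts to normalized inhibitory
  activities is upstream of this package.
* Counts from genome-scale scans over real annotation databases depend on
  those databases and are not reproduced by the synthetic fixtures.
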