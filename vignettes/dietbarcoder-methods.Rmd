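---
title: "Diet metabarcoding from fecal COI mini-barcodes: models and methods"
author: "dietbarcoder authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet metabarcoding from fecal COI mini-barcodes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietbarcoder)
```

## What this package computes

`dietbarcoder` reimplements, end to end, a molecular diet analysis for a
bird–insect food web. The raw material is single-end amplicon sequencing of a
157-bp COI mini-barcode (the Zeale fragment) from two kinds of feces: nestling
feces of insectivorous parids (the *consumed* prey) and moth caterpillar frass
collected under birch canopy (the *available* prey), plus laboratory control
samples of frass from a single reared species (*Samia cynthia*). The pipeline
has five stages:

1. **Demultiplexing and filtering** — reads are split by an exact 9-base index
   tag, discarded when their mean Phred quality is below Q20, and required to
   carry both first-stage PCR primers (IUPAC-aware matching) before being
   trimmed to the insert.
2. **De novo OTU clustering** — unique inserts are greedily clustered at 98%
   identity, a random member is picked as each cluster's representative, and
   OTUs with fewer than 8 reads in all samples combined are discarded.
3. **Rule-based taxonomic assignation** — each representative is compared to a
   local reference library and resolved to species, genus, family, order,
   *unidentified* or *contamination* by a fixed rule order (below).
4. **Diet statistics** — rank-level identifiability, consumed-versus-available
   species overlap, and the correlation between a species' sequence-variant
   richness and its prevalence across samples.
5. **The feeding-trial model** — ordinary least squares of the percentage of
   correct identifications on the natural log of frass dry mass (mg).

Because the original sequencer output and the live reference database are not
reproducible offline, a first-class synthetic-data module generates every
input with known ground truth, which is what the test suite exercises.

## The identity kernel

All thresholds are phrased in percent identity. The package freezes one
definition: a global, end-to-end, unit-cost edit alignment in which gaps count
as mismatches, with

$$\mathrm{identity}(a, b) = 100\,\frac{\max(|a|,|b|) - d_\mathrm{lev}(a,b)}{\max(|a|,|b|)}$$

where $d_\mathrm{lev}$ is the Levenshtein distance. Identity definitions vary
between tools (some exclude terminal gaps, some divide by the shorter
sequence); this one is symmetric, penalises length differences, and reduces
exactly to the Hamming form for the equal-length, substitution-only sequences
the simulator produces, so constructed boundary cases have exact identities
(a 200-bp pair with $k$ substitutions sits at $100 - k/2$). Inside the
clusterer the same quantity is computed by a banded Levenshtein kernel (band
half-width equal to the distance ceiling implied by the threshold, with row-
minimum early exit): values at or above the clustering threshold are exact,
and pairs beyond the band are correctly reported below it, which is all the
greedy assignment ever inspects.

## Greedy clustering semantics

The de novo clusterer dereplicates the inserts, orders unique sequences by
descending replicate count (ties lexicographic), and assigns each sequence to
the *best* existing seed with identity at or above the threshold, founding a
new seed otherwise; ties between equally good seeds go to the earliest-created
seed. Abundance ordering makes true biological variants seeds and error reads
absorbed members. The original workflow's clustering tool leaves input order
unspecified, so this ordering is a frozen design choice; a `first_fit` config
flag restores classical first-fit assignment for comparison. The 98% boundary
is inclusive: a pair at exactly 98.0% identity merges. The abundance filter is
applied after table construction, so discarded read counts remain reportable.

## The assignation rule order

The reference protocol lists determination principles rather than an
algorithm; this package freezes them into one precedence, "most specific call
any rule licenses, control rules first":

| order | rule | condition | call |
|---|------|-----------|------|
| 1 | `R9` | control sample; a control-genus hit at ≥ 97% | genus, "*Samia* sp." |
| 2 | `R9` | control sample otherwise | contamination |
| 3 | `R6` | best identity < 90% | unidentified |
| 4 | `R1` | best hit ≥ 97%, regional, named, untied | that species |
| 5 | `R3` | best hit non-regional; best regional hit > 97% | the regional species |
| 6 | `R4` | distinct species tied at the best identity | lowest common rank |
| 7 | `A95` | ≥ 95% and a same-sample OTU already fixed that species at 100% | that species |
| 8 | `R7` | ≥ 97% but the best record has no species name | its deepest rank |
| 9 | `R2` | ≥ 97%, species blocked, genus available | that genus |
| 10 | `AGEN` | ≥ 95% with a 100% same-genus same-sample anchor | that genus |
| 11 | `AMAJ` | < 97% but a strict majority of the hit list in one genus | that genus |
| 12 | `R5` | 90–97%: most specific rank shared by hits within 1 point of the best | family, else order |

Records flagged as clear database errors are excluded from the search itself,
so the next best clean match ranks first (`R8` is a property of the search,
not a branch). Design decisions worth stating explicitly:

* **Boundary inclusivity.** "97–100%" is read as ≥ 97 for species and genus
  calls; the resident-species preference demands strictly > 97 as printed;
  "below 90%" is read as < 90, so a 90.0% hit is still assignable.
* **Ties** (`R4`) are identities equal to two decimal places; the protocol
  states no tolerance.
* **Majority** (`AMAJ`) means more than half of the returned hit list (up to
  `top_k` = 20 hits, mirroring a 20-best-matches inspection window).
* The same-sample rescues (`A95`, `AGEN`) operate within a sample only. In
  multi-sample OTU tables, OTUs are assigned in descending abundance, and an
  OTU's context is the set of assignments already made to OTUs co-occurring
  with it in at least one sample.
* The genus-level rescue (`AGEN`) is kept distinct from the plain ≥ 97% genus
  call (`R2`): the two have different evidence (a 100% same-genus anchor
  versus direct similarity) and the provenance column should say which fired.
* **Degenerate constructions.** If hits tied under `R4` share no rank at all,
  the rule abstains and later rules apply; if the within-1-point set under
  `R5` spans multiple orders, the best record's family (else order) is used.
  Neither situation can arise from the synthetic libraries, whose orders
  diverge by far more than one point; they exist only for constructed inputs,
  and the tie-breaks keep the engine total and deterministic.

## The synthetic-data generator

The generator emulates the study's three data sources.

**Reference library.** Each order receives an independent random ancestor
sequence; genera mutate the ancestor at a dedicated, disjoint block of
positions; species mutate their genus ancestor at a further disjoint block;
intraspecific variants differ from the species base at positions drawn from a
reserved tail of the position pool that no block ever touches. Pairwise
differences are therefore sums of block sizes, and block sizes are the nearest
substitution counts to the divergence plan's targets (within one position,
0.64 points on 157 bp). The default plan — congeneric divergence 4%, genus
divergence 10%, intraspecific maximum 0.6% — guarantees that 98% clustering
can never merge two species and that variants of one species always co-cluster.
Plans whose intraspecific divergence reaches the congeneric target, or whose
block demand exceeds the sequence length, are rejected as infeasible. The
library carries the reference-database pathologies the assignation rules
exist for: a configurable fraction of species is non-regional, some genera
contribute records with no species name, and some species contribute
mislabeled duplicates flagged `known_error`.

**Reads.** A read is `tag + forward primer + insert + revcomp(reverse
primer)`, with degenerate primer positions resolved per read, i.i.d.
per-base substitution errors over the whole read (so primer and tag errors
feed the discard statistics naturally), and a Phred profile starting at Q30
with a linear 8-point 3′ decay — the protocol describes only an
average-quality filter, so any profile with the right mean would do.
Contaminant reads carry a uniform-random insert between the true tag and
primers: they survive demultiplexing and exercise the unidentified path.
Exactly `read_depth` reads are emitted per sample, each carrying its source
species in an internal ledger column that never reaches FASTQ. Not emulated,
deliberately: homopolymer (sequencer-specific) error profiles, PCR
efficiency bias, primer-template mismatch bias, chimeras and
reverse-complement reads. Passing tests therefore show the *logic* of the
pipeline is right, not that it is robust to every artefact of real sequencer
output.

**Feeding trial.** Per replicate of each dry-mass class,
`percent_correct = clamp(intercept + slope·ln(mass) + N(0, sd), 0, 100)`,
with the published coefficients (intercept 45.075, slope 13.433 per ln-mg)
and the study's six mass classes (0.1–50 mg) as defaults and noise SD 15 on
the percentage scale. One caveat matters for parameter recovery: at the
extreme default classes the linear mean sits close enough to the bounds
(14% at 0.1 mg, 98% at 50 mg) that the clamp truncates the noise
substantially and biases ordinary least squares. Recovery experiments in the
test suite therefore simulate the four central classes (0.3–14.4 mg), where
the clamp binds only in the far tails; recovery is asserted as 2-SE coverage
over 20 independent seeded trials rather than on a single draw, since a 2-SE
check is itself only a ~95%-probability event.

## Statistical conventions

* The detection model uses the natural log, matching the conventions of the
  statistical environment the original analysis was run in; the threshold
  mass inverts the unclamped linear form and predictions are clamped to
  [0, 100] only for reporting.
* The mass t-test is pooled-variance by default (`df = n1 + n2 − 2`, the
  integral df convention of the original analysis); a Welch option exists.
* The variant–prevalence correlation takes, per species, the number of
  distinct OTUs assigned to it across the whole data set (x) and the fraction
  of samples in which it occurs (y), with Pearson's r, `df = n − 2`, and the
  two-sided p from the t transform. Whether variant counts should be
  per-sample or dataset-wide is ambiguous in the source analysis; dataset-wide
  is the default and `per_sample = TRUE` gives the alternative.
* The pellet-count–to–dry-mass regression is forced through the origin (zero
  pellets weigh nothing), a physical constraint rather than a fitted choice;
  the pellet count needed for a target mass is rounded up.
* The trial's "percentage of correct identifications" is not pinned to a unit
  of observation in the source; here it is treated as the per-replicate
  response simulated by the trial generator.

## Determinism and problem sizes

Every stochastic step (library generation, community design, read simulation,
representative picking, trial noise) is seeded; the pipeline fans one master
seed out to per-stage seeds by fixed offsets, so stages are independently
reproducible, and identical config plus seed give byte-identical output files
(the run manifest records md5 digests). The bundled synthetic study — 9
samples (4 bird feces, 3 wild frass, 2 laboratory controls) at 2,000 reads
each, a 3-order × 12-genus × 36-species reference library with intraspecific
variants — was chosen so a full run takes seconds on a single core while
still producing tens of OTUs across every sample type; the published field
study is roughly three orders of magnitude deeper, and nothing in the
implementation depends on the small scale.

## Known limitations

* The rule precedence is a documented interpretation of a manual protocol;
  the original determinations were made by hand and may have resolved edge
  cases differently.
* No chimera detection or denoising: the reference workflow has neither, and
  the simulator does not produce chimeras by default.
* The clusterer is not a bit-for-bit reproduction of any particular
  clustering tool (word size, input order and tie handling all differ between
  implementations); it reproduces the *semantics* stated above.
* Field-scale results of the original study (its OTU counts, identifiability
  percentages and correlation coefficients) derive from unpublished raw data
  and a live database snapshot; they parameterise the generator and the
  convention checks here but are not reproduced as estimates.
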