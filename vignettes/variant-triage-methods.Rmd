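---
title: "Pedigree-aware variant triage: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-aware variant triage: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glioseg)
library(dplyr)
```

## The triage model

`glioseg` addresses a recurring situation in family-based rare-disease
genetics: a linkage analysis has localised a susceptibility signal (here,
two adjacent intervals on chromosome 17q defined by a 1.7-LOD drop around
the peaks, roughly a 99% confidence region for the locus), targeted
sequencing of the implicated families has produced thousands of annotated
variants, and the question is which of them could plausibly explain the
linkage. The package encodes the answer as a conjunction of per-variant
predicates organised into two stages, with orthogonal Sanger confirmation
between them.

A variant `v` with position `p`, functional class `f`, population
frequencies `F` (in percent) and per-individual carrier calls survives the
triage iff:

* **Linked locus** — `p` lies in the linkage locus (closed endpoints). In
  the initial stage the gate is waived when the gene is in the Cancer Gene
  Census (CGC), on the argument that a known cancer gene just outside a
  statistically defined boundary should not be discarded on position
  alone. The final stage applies the gate without the waiver, so every
  reported candidate is genuinely inside the locus.
* **Targeted region** — initially, `p` within 200 bases of a capture
  target (CGC-waived); finally, `p` strictly inside an *exonic* target
  with no pad. The pad acknowledges that capture designs recover flanking
  bases at usable depth; the final exonic restriction reflects that only
  on-design exonic calls were considered reportable.
* **Rarity** — no present frequency field strictly exceeds the threshold:
  5% initially (a loose gate that removes common polymorphisms before
  the expensive validation step), 0.1% finally ("very rare"). Absent
  frequencies never trigger a drop — novel variants must survive.
* **Family segregation** — at least one family has ≥ 1 sequenced affected
  member and *all* of its sequenced affected members carry `v`. This
  single predicate also removes variants present only in unaffected
  individuals. Unaffected carriers are permitted and reported, not
  filtered: with a low-penetrance disease, unaffected carriers (often
  young) are expected.
* **Sanger verification** — between the stages, each surviving variant is
  classified from bidirectional capillary reads of its affected carriers:
  `fully_verified` when forward and reverse reads are concordant with the
  NGS call in every affected carrier, `partially_validated` when at least
  one carrier is confirmed on both strands but not all, `design_failed`
  otherwise. Only fully verified variants proceed. The published decision
  rule does not name the case where reads exist but no individual is
  confirmed on both strands; we class it with the failures, since both
  represent an assay that confirmed nothing, and the two are
  indistinguishable downstream.
* **Protein alteration** — `f ∈ {missense, nonsense, frameshift,
  splice}` in the final stage.

Every stage appends to an audit trail (`n_in`, `n_out`, dropped keys), and
each input variant receives exactly one fate: its first dropping stage, or
`passed`. Retention percentages are reported half-up at one decimal.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `linkage_locus` | 17: 34,355,567–52,135,011 and 54,612,056–61,596,548 | bp, 1-based closed | the two 17q 1.7-LOD-drop intervals (GRCh37) |
| `target_pad_bases` | 200 | bases | capture recovers usable depth ~200 bp beyond probes |
| `initial_maf_threshold_percent` | 5 | percent | removes common polymorphisms pre-validation |
| `final_maf_threshold_percent` | 0.1 | percent | "very rare": compatible with a high-penetrance familial allele |
| `cgc_genes` | packaged 23-gene chr17 census | symbols | waiver set for the initial positional gates |
| `protein_altering` | missense, nonsense, frameshift, splice | classes | classes that change the protein product |

Both frequency thresholds are **strict**: a variant at exactly 5% or 0.1%
is kept, following the "greater than" wording of the filter definitions.
Distance for the pad rule is the gap in bases to the nearest interval
endpoint (0 inside); a tie at exactly 200 is kept. Frequencies are stored
and compared in percent throughout, matching how such tables are
published (e.g. `0.069`%).

Two stage-design choices were genuinely open and are resolved as follows.
The initial rarity filter tests the ESP and 1000 Genomes *CEU* fields, as
specified for that stage; the final very-rare filter tests **all**
provided frequency fields (ESP plus any 1000G field), the conservative
reading where the population for the final stage is not pinned down.
Second, the removal of variants "present only in unaffected individuals"
is not implemented as a separate stage: it is logically nested inside the
segregation predicate (such a variant has no family whose affected members
all carry it), so the survivor set is identical and the audit attributes
those drops to `family_segregation`.

## Coordinate and container conventions

Positions are 1-based inclusive internally (the convention in which VCF
records and the locus boundaries are written); BED input is converted on
read (`start + 1`, `end`) and overlapping records are merged. Chromosome
labels are compared after stripping a leading `chr`. Multi-allelic VCF
records are decomposed per ALT allele, because every filter is
per-allele. Heterozygous and homozygous alternate calls both count as
"carrier"; zygosity is never used. A missing genotype counts as
non-carrier in numerators while the individual stays in denominators.
Phenotype codes 0/−9 ("unknown") are treated as unaffected, since the
filters only reference the affected/unaffected strata; this is a package
convention, stated here because pedigree files in the wild leave many
relatives uncoded.

Carrier ratios, sharing (`shared` iff ≥ 2 sequenced affected carriers),
novelty (no dbSNP ID and no ESP/1000G frequency), privacy (records in
exactly one family) and multi-family gene detection operate on the final
candidate records. Ranking is by descending CADD scaled C-score with ties
broken by ascending position (the positional tie-break is this package's
own deterministic choice; published orderings are compatible with it but
silent), and unscored variants rank last rather than being excluded —
score availability is an annotation property, not a filter.

## The packaged cohort fixture

The package ships the published 20-family affected pedigree (relationship,
histology, age at diagnosis, sex, sequenced status) and the published
21-candidate table. Only parent links stated directly by the printed
relationships (father/mother rows, siblings through a listed parent) are
encoded; distant affected relatives appear as founders within their
family, which affects no computation in the package — counts use the
affected and sequenced flags only. The unaffected relatives behind the
published unaffected denominators are not individually published, so
`gliogene_cohort()` constructs **synthetic** unaffected sequenced members
per family to match the printed denominators, assigns carrier calls that
reproduce every printed ratio, and builds synthetic exonic capture
windows (±10 bp) around each candidate position, the capture design
itself being unpublished. This fixture demonstrates that the final-stage
machinery reproduces the published candidate table; it cannot, and is not
meant to, reproduce the upstream funnel from the raw cohort calls, which
would require the unavailable sequencing data.

## What the simulator emulates

`simulate_cohort()` generates the statistical structure the triage
assumes, with every random draw fixed by one seed:

* **Pedigrees** — each family descends from one founder couple, two to
  four generations, with married-in spouses; affected statuses fall on
  blood relatives only. The affected-count mixture defaults to 83% two /
  17% three affected members per family, the reported composition of
  multiplex glioma families. In a configurable fraction of families
  (default 20/23) all affected members are sequenced; in the rest none is
  (mirroring probands whose specimens failed), and unaffected members are
  sequenced independently with probability 0.6 — a round value chosen to
  give the mixed sequenced/unsequenced structure such cohorts show.
* **Planted candidates** — missense, inside the locus on exonic targets,
  frequency absent or below 0.1%, introduced by the family's root founder
  and transmitted down parent chains so that every sequenced affected
  member of the target family carries the allele. Carriers arise only
  along ancestor chains, so no genotype requires a de novo event.
* **Decoys** — one class per filter, each violating *exactly* its
  intended predicate and satisfying all others: `common_freq` (> 5%),
  `moderate_freq` (0.1–5%, added so the final very-rare filter is also
  exercised by construction), `off_locus`, `off_target`,
  `non_segregating` (all sequenced affected but one carry; the excluded
  member is chosen as a pedigree leaf so the chain union cannot cover
  everyone), `unaffected_only` (a single parentless carrier, so no
  transmission is implied), `synonymous`, `sanger_partial`,
  `sanger_failed`.
* **Background variants** — frequency drawn from a mixture of a point
  mass at "absent from databases" (probability 0.3) and a log-uniform
  spectrum over 0.01–20%; the mixture guarantees both rarity branches are
  exercised. Background genotypes are engineered, not free-random: the
  allele drops from the founder and every chain is truncated before the
  first sequenced affected member, so a background variant can never
  co-segregate by accident and its fate is known exactly at construction
  time (`rare_variant` if common, else `family_segregation`).
* **Sanger evidence** — fully concordant bidirectional reads for
  everything that should verify, one missing strand for
  `sanger_partial`, no usable reads for `sanger_failed`.

The truth table records each variant's class, intended fate, planted
family, and (for positional decoys) a compliant position, which the test
suite uses for flip tests: changing only the violating attribute must make
each decoy pass the full pipeline.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: linkage disequilibrium and haplotype structure,
sequencing and genotyping error, mutation-rate variation, relatedness
beyond a single founder couple per family, and the high-repeat regions
that cause real Sanger design failures. Recovery of the planted truth
demonstrates the correctness of the filter logic, not the power of the
design against realistic noise.

## Numerical choices and degenerate inputs

* Retention percentages round half *away from zero* at one decimal
  (base `round()` is half-even, which would report 0.05 → 0.0%);
  a stage with zero input reports `NA` rather than dividing by zero.
* The positional tie-break in ranking applies to unscored records too, so
  output order is fully deterministic; `arrange()`'s stable sort makes
  exact ties (same score, same position) preserve input order.
* Empty cohorts, empty variant sets and empty candidate lists flow
  through every stage and report writer with zero counts.
* Validation is strict at the container boundary: genotype entries for
  unsequenced individuals, dangling parent IDs, duplicate annotation
  keys, negative frequencies, frequencies outside [0, 100], identical
  ref/alt alleles and unknown genotype or strand codes are all rejected
  with named errors.

## Problem sizes used by the test suite

Unit and property tests run on cohorts of up to ~50 variants and 6–10
families; the affected-mixture check generates 200 families and accepts a
99% binomial band around 0.83; end-to-end truth recovery is asserted
across 20+ seeds at small cohort size. These sizes make every property
cheap to verify exhaustively (per-base interval oracles, brute-force
Mendelian trio checks, conjunction-of-predicates survivor oracles) while
exercising all code paths.

## Known limitations

* The exonic subset of the capture design must be supplied as a flagged
  BED column; the package cannot infer it.
* Sanger evidence enters as per-strand concordance calls; trace/quality
  processing is upstream of the package.
* The segregation predicate treats families as independent; it neither
  computes segregation LOD scores nor adjusts for kinship, and burden
  testing is out of scope.
* Genotype quality is taken at face value from the VCF `GT` field.
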