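---
title: "Methods: clustered profile-HMM annotation of nutrient cycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustered profile-HMM annotation of nutrient cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the model behind `cyclescan`, the parameters that
matter, the numerical and design choices made where the design was open, and
what the synthetic fixtures do and do not demonstrate about real data.

## The annotation model

Annotation is profile-HMM homology search, not pairwise comparison: each
protein family (a KEGG orthology entry, or a hydrogenase group) is
represented by one or more position-specific models, and an ORF is annotated
by the best-scoring model that survives a set of filters. Two properties of
metagenomes drive the design:

* **Ortho/paralog confusion.** Families with shared evolutionary origin
  produce similar match patterns. Clustering each KO's sequences *before*
  model building (rather than building one broad model per KO) keeps each
  model tight, which raises resolution between close paralogs.
* **Database size versus time.** Key marker genes for the major nutrient
  cycles are collected into small per-cycle subset databases that can be
  searched quickly on their own; the full metabolic remainder is only
  searched for ORFs that the key phase left unannotated.

### Database construction

Per KO family, in order:

1. **Length filter.** Members outside `[0.60, 1.50] × mean length` are
   discarded; both bounds are inclusive (the exclusion is phrased as
   *longer/shorter than*, so a sequence at exactly 60% or 150% stays). If
   fewer than `min_unique_seqs = 3` members would survive, the unfiltered
   set is used — the filter never causes a family to be discarded by
   itself. The filter runs before de-replication and clustering; the
   fallback restores the pre-filter set.
2. **De-replication.** Exact duplicate residue strings collapse to the first
   occurrence; sets of three or fewer entries pass unchanged.
3. **Retention.** A KO with fewer than three unique sequences is discarded —
   below that, an alignment has no information to offer a profile.
   "Unique" means exact residue-string uniqueness.
4. **Clustering.** Greedy longest-first linear scan: a sequence joins the
   first cluster whose representative it matches at ≥ 50% identity over
   ≥ 70% coverage, else it founds a cluster. The published pipeline ran a
   linear-clustering tool with equivalent thresholds; here the thresholds
   are honored as a *membership contract* (every member satisfies
   identity/coverage against its representative, testable by an independent
   aligner) rather than as a bit-exact re-implementation of that tool.
   Identity is matches / alignment columns of a global alignment (BLOSUM62,
   gap open 10, extend 0.5); coverage is both-residue columns over the
   shorter sequence's length.
5. **Pooling.** Clusters under three members merge into one pooled cluster;
   if the pool itself ends up with fewer than two members it is dropped with
   a warning (the sources are silent on this corner; one sequence cannot
   justify a profile of its own at this stage).
6. **Profile building.** MAFFT (`--quiet --anysymbol --auto`) followed by
   `hmmbuild` with default settings. The model length `hmmbuild` reports is
   stored as the profile's `target_len` and is the reference length for the
   size filter at annotation time. Clusters are numbered `0..n-1` per KO in
   descending size (ties by representative name) for determinism.
7. **Subset assembly.** A profile joins the first cycle (config declaration
   order) claiming its KO; a KO claimed twice is a configuration error, a
   config KO with no profiles is reported but not fatal. Hydrogenase groups
   are label-only families: their profiles live in the Hydrogenases subset
   and carry no KO, which also keeps them out of the KEGG-mapper output.

### Bin intake

Total bin length decides the gene-calling regime: `single` inside the
inclusive band 0.5–15 Mbp, `meta` outside it. The lower bound is what the
gene caller needs for a reliable single-genome model; the upper bound is
just above the largest known bacterial genome, so anything bigger cannot be
one organism. The same upper bound gates optional slow analyses (the rRNA
adapter hook), which keeps unbinned-assembly runs fast. Partial genes at
contig edges are always allowed. The unbinned fraction receives no special
casing: it is simply another bin, which keeps community-level summaries
complete.

### Triage tiers

All searches report at the prefilter `E ≤ 1e-06`. For ORFs of ≥ 200
residues a hit must additionally pass the scope tier — `1e-100` when only
the key subsets are searched, `1e-50` when the full database participates —
and the 20% size filter `|query − target| / target ≤ 0.20`. The tier is
keyed to the *run scope*, not the phase: in a full run, phase-1 key hits are
triaged at `1e-50`, because the full database's presence is what lowers the
false-positive risk. ORFs under 200 residues cannot reach those bit scores,
so they are judged at the prefilter only, with the size bound relaxed to
30%. All ceilings are inclusive and user-overridable.

Partial ORFs are exempt from the upper size bound only; the lower bound
still applies. The e-value used throughout is the engine's full-sequence
e-value (its default reporting unit; the sources do not distinguish
full-sequence from per-domain values).

The per-ORF winner is the highest bit score; ties break by lower e-value,
then lexicographic profile id, making the selection a total order and the
output invariant under input reordering. An ORF annotated in phase 1 is
final and never revisited in phase 2.

### Summaries

For gene *g* with coverage table *d*:

* `n_hits` — annotations across all bins;
* `n_bins` — distinct bins with ≥ 1 annotation;
* `%O-depth` — `100 · Σ d(bins harboring g) / Σ d(bins with coverage)`.

Bins without a coverage row leave both numerator and denominator (with a
warning); without any coverage table the column is `NA`. Abundance is
printed to one decimal; internal arithmetic is full precision. Processes
aggregate member genes by `max` (a multi-subunit system is as abundant as
any single detected subunit) except hydrogenase classes, which `sum` over
their group profiles. Process membership ships as an editable YAML because
the gene-to-process mapping is an analysis choice with direct impact on
results.

## Parameters at a glance

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `len_lo_frac` / `len_hi_frac` | 0.60 / 1.50 | fraction of mean | removes fragments and fusions before clustering |
| `min_unique_seqs` | 3 | sequences | minimum information for a profile |
| `cluster_min_id` / `cluster_min_cov` | 0.5 / 0.7 | fraction | cluster membership contract |
| `min_cluster_size` | 3 | sequences | smaller clusters pool |
| `min_single_bp` / `max_single_bp` | 0.5 / 15 | Mbp | single-genome gene-calling band |
| `e_prefilter` | 1e-06 | e-value | weakest similarity ever accepted |
| `e_key` / `e_full` | 1e-100 / 1e-50 | e-value | scope-dependent stringency |
| `small_aa` | 200 | residues | small-protein path threshold |
| `size_frac` / `size_frac_small` | 0.20 / 0.30 | fraction of model length | motif-only hit removal |

Every effective value is echoed into the run manifest, so overrides are
always on record.

## Numerical choices and degenerate inputs

* All threshold comparisons are inclusive (`≤`, `≥`).
* Sorting keys are fully specified everywhere a tie could occur (cluster
  order, best-hit selection, bin/ORF output order), so reruns are
  byte-identical.
* The size-filter denominator is the profile model length (the profile side
  of the comparison is fixed at build time; the query varies).
* Gene calls whose translation is entirely `X` (N-runs in the contig) are
  dropped; an all-N contig therefore yields zero ORFs.
* U/O residues are tolerated in input and mapped to C/K for alignment
  scoring, since BLOSUM62 has no rows for them.
* Repeated application of the length filter is *not* idempotent in general:
  the band is recomputed from the surviving mean, which can shift and drop
  further members. What holds, and what the tests assert, is monotone
  shrinkage, exact identity whenever the fallback fires, and convergence to
  a fixed point.
* A failing KO (build) or bin (annotate) is isolated, recorded in the
  manifest, and the run continues.

## The synthetic-data generator

`make_family()` derives members from a shared base sequence: fixed conserved
motif blocks at 10%/55% of the length (high-information columns for the
profile), independent substitutions elsewhere at the `divergence` rate, and
occasional 1–3-residue indels. `make_outgroup()` produces decoys verified to
stay under 25% identity to every family member. `make_community()`
reverse-translates members (uniform codon choice, translation table 11,
no internal stops), plants them on alternating strands separated by random
intergenic sequence, prefixes each full gene with a Shine–Dalgarno motif
(`AGGAGG` + 5–7 nt spacer) so the gene caller sees ordinary prokaryotic gene
anatomy, truncates the first gene of the first bin at the contig edge to
exercise partial-gene handling, and records every coordinate in a truth
table. Everything is reproducible from the seeds.

The reference conditions (the `community` preset) are three bins of depths
10/30/60 carrying 19 planted key genes across four cycles, two non-key genes
and four decoys — small enough to annotate in seconds, rich enough to
exercise both phases, the small-protein path (truncated gene), KO-less
profiles, and the abundance arithmetic.

**What passing these fixtures does not show:** real communities have skewed
codon usage, overlapping genes, mobile elements, sequencing and assembly
error, and — most importantly — homology structure between families
(paralogs at 30–60% identity) that synthetic independent families do not
reproduce. The fixtures validate the *mechanics* (filters, tiers,
selection, aggregation, determinism) exactly; they do not measure real-world
annotation precision, which depends on the reference database used.

## Problem sizes used in testing

The test and acceptance runs use deliberately desk-scale sizes, chosen as
the smallest instances that still exercise every code path: 10 KO families
of 8 members, a three-bin community with 25 planted genes, 1,000 randomized
triage instances against the brute-force oracle, and 200 randomized
invariant runs. The full suite completes in well under a minute of compute
plus a few seconds of external-engine calls.

## Known limitations

* The greedy clusterer is a contract-faithful stand-in, not a re-encoding
  of any particular linear-clustering tool; cluster *boundaries* may differ
  from other tools even though every membership satisfies the same
  identity/coverage contract.
* rRNA detection and taxonomy are adapter hooks only; tRNA/ncRNA/CRISPR
  scans and BLAST-based fallback annotation of leftover ORFs are out of
  scope.
* KEGG-module completeness scoring and Krona HTML rendering are not
  included (the Krona text file feeds the standard importer).
* Per-contig coverage is not supported; abundance is per-bin, matching the
  one-depth-per-bin tables produced by common binning workflows.
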