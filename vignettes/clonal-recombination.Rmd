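---
title: "Estimating recombination versus mutation in clonal endosymbionts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating recombination versus mutation in clonal endosymbionts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalrm)
library(dplyr)
```

## The problem

*Wolbachia*, *Cardinium* and similar intracellular bacteria are inherited
maternally, so their populations should diversify clonally: new strains
should arise one point mutation at a time. Multilocus sequence surveys of
these symbionts instead show alleles shared promiscuously among otherwise
distinct strains, a signature of homologous recombination — individual gene
fragments moving between lineages, presumably via phages or transient
co-infections. The quantity of interest is the **recombination:mutation
(r/m) ratio**: during short-term clonal diversification, how many new
alleles arise by recombinational import for every allele arising by de
novo point mutation?

`clonalrm` implements the counting approach used for bacterial MLST data.
It is deliberately model-free: no coalescent, no likelihood — just typing,
graph clustering, and a transparent classification of observed allele
differences. That makes the estimate conservative and easy to audit, at
the cost of using only the most closely related strains in the sample.

## The method, step by step

### Typing

Within each locus alignment, every unique sequence is an allele
(consecutive ids in order of first appearance); every unique tuple of
alleles across loci is a sequence type (ST). Two choices matter here and
are fixed by design:

* **Gaps are characters.** Sequences differing only by an indel are
  different alleles. Endosymbiont surface genes (e.g. *wsp*) segregate
  small in-frame indels, and collapsing them would hide real variation.
* **Ambiguity codes never wildcard-match.** A sequence containing an
  IUPAC code joins an existing allele only by exact string equality. This
  is conservative and reproducible; the alternative (fuzzy matching)
  would make allele identity depend on comparison order.

Isolates not typed at every locus are excluded from ST assignment (and
reported), but retained for per-locus diversity. This mirrors common
practice when a single highly divergent strain fails amplification at one
locus: its exclusion is an explicit, configured decision
(`exclude_isolates`), not an automatic outlier rule.

### Diversity panel

For each locus the package reports alignment length, allele count,
variable sites, nucleotide diversity π, maximum p-distance, and dN/dS.
Distances use **pairwise deletion**: a column is dropped only for the
pairs in which either sequence has a gap, `N`, or an ambiguity code. This
keeps per-pair denominators maximal and matches the default behaviour of
the standard desktop tools this panel is meant to be comparable with. π
is computed over all isolate sequences (not one per allele), so common
alleles weigh more — the convention for population samples.

dN/dS uses the Nei–Gojobori (1986) counting method: potential synonymous
sites per codon are the fractions of single-base changes preserving the
amino acid (changes to stop codons count as nonsynonymous); codons
differing at several positions average their synonymous/nonsynonymous
steps over all mutational pathways with equal weight, excluding pathways
through stop codons (if all are blocked, all are used). The per-pair
proportions pS and pN are averaged across pairs and Jukes–Cantor
corrected before the ratio. When dS is 0 — identical sequences, or purely
nonsynonymous variation — the ratio is reported as undefined rather than
infinite. The raw pS/pN are returned alongside for transparency. Note
that the Jukes–Cantor transform is undefined at proportions ≥ 0.75; on
very short, very diverged fragments the corrected values can therefore be
`NA` even when the raw proportions are fine.

### Clonal complexes

STs differing at exactly one locus (single-locus variants, SLVs) are
linked; connected components with at least two STs are clonal complexes.
This is the stringent L−1-of-L grouping rule of eBURST; the relaxed
L−2 grouping is intentionally not offered, because the attribution step
below only makes sense when every member is one allele away from another
member. The founding genotype of a complex is predicted as the member
with the greatest number of SLV links within the complex, ties broken by
higher isolate frequency, then lowest ST id. The full decision trace
(degree, frequency per member) is kept in the result.

Two caveats are worth stating. First, in a fully connected clique of
equal-frequency STs the tie-break is arbitrary; for published tables
whose founding genotypes are known, `founder_hint` pins them. The
classification *totals* are robust to this choice in practice, because
re-rooting a clique relabels which member is "variant" but preserves diff
classes; the per-variant table, however, does change. Second, complex
labels (I, II, ...) are assigned by decreasing isolate count, so they need
not match any published labelling — comparisons should go by membership.

### Attribution and the r/m ratio

For each member ST, each locus where its allele differs from the
founder's contributes a variant allele; a variant shared by several
members of one complex counts once there, but the same allele deviating
in another complex counts again — each complex is an independent
diversification experiment. Diff counts exclude gap-containing columns.
Classification:

| n_diffs | sharing | class | strict rule | inclusive rule |
|---|---|---|---|---|
| 1 | polymorphism unique | `unique_single` | mutation | mutation |
| 1 | polymorphism recurs in another allele | `nonunique_single` | dropped | recombination |
| 2 | — | `double` | dropped | by allele recurrence outside the complex |
| ≥ 3 | — | `import` | recombination | recombination |

The ≥ 3 threshold generalizes the empirical observation that clear imports
differ at four or more sites while the ambiguous class stops at two; it is
configurable (`import_threshold`). "Recurs" for a single change means the
identical polymorphism — same column, same derived base — in any other
allele at that locus across the full dataset; for a double, it means the
identical allele carried by an ST outside the complex. The strict and
inclusive ratios bracket the estimate; both are reported, with explicit
numerators and denominators, and a zero mutation denominator yields a
flagged infinite ratio rather than an error.

The per-locus concentration of variant alleles is tested with a plain
goodness-of-fit chi-square against uniform expectation (df = L − 1, no
continuity correction — standard for a multi-cell goodness-of-fit). With
counts as small as these the chi-square approximation is rough; the
statistic is exact arithmetic, but the p-value should be read as
indicative.

### The reference fixture

The package ships, as plain TSV, the clonal-complex table of a published
*Wolbachia* MLST survey of spider mites: 22 STs in five complexes, 44 of
64 isolates, founder profiles, per-variant diff counts and sharing flags.
Running the pipeline on it reproduces the survey's headline numbers — 17
variant alleles splitting 1/3/2/11, strict ratio 11:1, inclusive 15:2, and
the trmD-heavy per-locus counts (10, 3, 3, 1; chi-square 11.0). Three of
the annotation flags (which three singles are non-unique, which double
recurs) are inferred from the table's typography; the totals are
insensitive to the assignment.

`fixture_sequences()` additionally fabricates per-locus alignments
realizing the table at sequence level: each allele is a fixed background
plus changes in disjoint column blocks, sized so that every
founder–variant distance equals the annotated diff count, shared
polymorphisms are placed explicitly, and one extra singleton ST (isolate
`synthX1`, labelled synthetic in the metadata) carries the one 2-diff
allele that must recur outside its complex. This gives an end-to-end
FASTA-to-report test without any network access. The fabricated
backgrounds are arbitrary, so coding-frame statistics on them are
meaningless (the pipeline duly warns about internal stop codons); only
typing, distances and attribution are exercised.

## The simulator and what it validates

`simulate_clonal()` emulates exactly the process the estimator assumes:
isolates descend from a few founders; Poisson-many point mutations hit
uniformly chosen unedited sites; Poisson-many imports replace a locus's
allele with one of a small pool of donor alleles at fixed divergence
(default 6 nt) from the founder allele. Implementation details that keep
the truth log exact: at most one import per locus per isolate (loci drawn
without replacement), and mutation sites colliding with previously edited
sites are resampled — so an isolate's distance from its founder equals the
sum of its logged edits, which the tests assert.

Defaults (4 loci × 500 bp, 2 founders, 60 isolates, import mean 0.5,
import divergence 6 nt, donor pool 8) describe a survey of the size and
clonality where this estimator is applicable: most isolates identical to
a founder, variants predominantly one event away. The recovery experiment
in the test suite runs true import:mutation rate ratios of 1:1, 5:1 and
10:1 (import mean fixed at 0.5; mutation mean 0.5, 0.1, 0.05) over 20
seeds each and requires the median strict estimate within a factor of two
of the rate ratio. The factor-two band reflects the estimator's intrinsic
discreteness at these counts — with ~2 expected mutations in a dataset,
the denominator is a small Poisson count — not a deficiency of the
implementation; with import rate 0 the estimate is exactly 0.

What the simulator does *not* emulate: a coalescent genealogy,
within-host multiple infection, selection, or demographic structure.
Passing recovery therefore shows the counting chain is correct under the
model's own assumptions, not that real surveys meet those assumptions.
Donor pools are per-founder, so simulated imports never recur across
complexes — the inclusive rule's sharing flags are exercised by the
fixture, not the simulator.

## The intragenic scan

The MaxChi-style scan takes a (parent A, parent B, child) triplet.
Informative sites are columns where the parents differ, the child matches
exactly one of them, and no gaps or ambiguity codes intervene. For every
cut with at least `min_sites_per_side` (default 3) informative sites on
each side, the 2×2 chi-square of (matches A / matches B) × (left / right)
is computed; the maximizing cut — leftmost on ties, for deterministic
output — is the candidate breakpoint, reported both as an informative-site
index and as the alignment column midway between the flanking sites. The
p-value permutes the site labels (`n_permutations`, default 1000, fixed
`seed`), using the standard (1 + exceedances)/(1 + permutations)
estimator, so the smallest attainable p is 1/(n+1). The tests verify
localization on constructed splices (±2 informative sites), an
approximately uniform p-value distribution on null triplets, reversal
symmetry, and a controlled false-call rate. This single detector stands
where a full multi-program consensus scan would be used interactively;
only the one statistic is implemented because it is the cleanest to
specify and test.

## Numerical and degenerate-input conventions

* Alignments: ragged lengths, duplicate isolate ids, zero-length or empty
  files, and non-IUPAC characters are hard errors naming the offending
  record; `U` is silently normalized to `T`; ambiguity codes are retained
  with a message.
* Distances: a pair with no comparable columns yields `NA` and is dropped
  from π means with `na.rm`.
* Fewer than 2 sequences, no fully typed isolate, single-locus pipeline
  runs, a founder lacking an allele, a variant with zero diffs: all
  explicit errors, not silent results.
* All randomness (simulator, permutation test, graph layout in plots) is
  seed-controlled; the analysis pipeline itself is deterministic, and the
  end-to-end tests assert byte-identical re-runs.

## Scale of the shipped validation

Everything validated by the test suite runs at desk scale: the fixture
(tens of STs), simulator recovery at 60 isolates × 20 seeds × 3 rate
settings, and 200-replicate permutation-null experiments. Whole-survey
quantities from the original study that require its deposited sequence
data — the 36-ST count among 64 isolates, per-locus diversity values such
as 155 variable *wsp* sites or 18 *trmD* alleles, and the documented
natural *wsp* mosaic — are reachable by pointing `run_mlst_pipeline()` at
the downloaded per-locus FASTA, but are intentionally not bundled: the
package ships only in-table data and code-generated sequences.

## Limitations

* The counting estimator uses only within-complex variation; diversity
  between complexes and in singleton STs carries recombination signal it
  ignores. Published comparisons treat it as a lower bound.
* Attribution assumes the predicted founder is ancestral. Degree and
  frequency are good proxies in star-like complexes and weak in cliques;
  the `founder_hint` escape hatch exists for externally known founders.
* Single-nucleotide changes are attributed to mutation although
  recombination between near-identical alleles can mimic them — another
  reason the strict ratio is conservative.
* dN/dS per locus is a purifying-selection sanity check, not a per-site
  selection scan.
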