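---
title: "Methods: disproportionality signals and drug-gene interaction networks"
author: "pvnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signals and drug-gene interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvnet)
```

# Scope

pvnet implements the two analysis arms commonly combined in
pharmacoepidemiological safety studies of a single drug — the motivating
use case being montelukast and neuropsychiatric adverse events:

1. **Signal detection** in a spontaneous-report database (FAERS-style
   DEMO/DRUG/REAC tables): case deduplication, suspect-role filtering,
   preferred-term (PT) to system-organ-class (SOC) mapping, and reporting
   odds ratios (ROR) with Wald confidence intervals and the standard
   signal rule.
2. **Drug-gene interaction network analysis**: one-hop expansion of a
   seed drug-gene list through a PSI-MITAB interactome, MCODE
   molecular-complex detection, and per-cluster hypergeometric
   over-representation analysis against pathway (GMT) and disease-gene
   collections.

Both arms are validated against a synthetic-data module that generates
inputs with known ground truth, because the real resources (the
multi-million-report FAERS corpus, the licensed MedDRA dictionary,
iRefIndex, DGIdb/DSigDB/STITCH, KEGG, DisGeNET) are either licensed,
versioned snapshots, or too large to ship. The package therefore makes no
claim to reproduce any published count from those resources; it reproduces
the *methods*, verifiably.

# The spontaneous-report model

## Case deduplication

Spontaneous-report systems receive resubmissions of the same patient case
from several reporting sources and in several versions. The store keys
reports by `report_key` (one per submitted version, FAERS `primaryid`) and
cases by `case_id` (FAERS `caseid`). `deduplicate()` keeps, per case, the
report with the greatest *version rank*: the case version number when the
table carries one, else the receipt date (`fda_dt`), else file order.
Remaining ties are broken by the lexicographically greatest `report_key`.
The choice of tie-break is arbitrary but fixed, so the operation is
deterministic and idempotent; which FAERS fields best identify "the same
patient" is genuinely open, and demographic matching is deliberately out
of scope — only case-id versioning is used.

## Roles and exposure

FAERS assigns each drug row a role: primary suspect (PS), secondary
suspect (SS), concomitant (C), interacting (I). Analyses of a drug of
interest conventionally restrict to PS entries; `filterByRole()` keeps the
requested roles and excludes reports left with no drug rows (they carry no
exposure information under the restriction). Reports with zero *events*
are retained — they contribute to the unexposed/no-event margins of the
2x2 tables.

Drug names are normalized by case-folding, trimming and collapsing
internal whitespace. No active-ingredient or brand-name dictionary is
applied: mapping brand names to ingredients requires a licensed or
versioned resource and would make results depend on it.

## The reporting odds ratio

For a target drug and event term, each deduplicated report falls in
exactly one cell of

|            | event `+` | event `-` |
|------------|-----------|-----------|
| drug `+`   | a         | b         |
| drug `-`   | c         | d         |

and the ROR is the cross-product ratio `ad / bc`, with Wald interval
`exp(log(ROR) ± z * sqrt(1/a + 1/b + 1/c + 1/d))`, `z = 1.959964` (the
97.5% normal quantile). The Wald interval on the log scale is the standard
in the ROR pharmacovigilance literature. A **signal** is declared when the
CI lower bound exceeds 1 *and* `a >= 2`.

Numerical choices:

* The point estimate is computed as the literal cross-product ratio, so it
  is exact for integer cells; logs appear only in the interval.
* Zero cells make the estimate undefined. The default (`zeroCell =
  "undefined"`) reports `NA` and `is_signal = FALSE`; the opt-in
  Haldane-Anscombe policy adds 0.5 to every cell and flags the result
  `corrected`. Corrections change inference, so they are never silent.
* Under the correction, the `a >= 2` condition still uses the observed
  `a`: the report-count requirement refers to real reports.
* No multiple-testing adjustment is applied across scanned events; the
  signal rule is the classical per-term criterion, and `scanEvents()`
  output is ordered deterministically (descending ROR, undefined last,
  ties alphabetical) so repeated runs are byte-identical.

The comparator is always "all other drugs in the store"; stratified or
class-restricted comparators are out of scope.

# The network model

## One-hop seed expansion

"Genes that directly or indirectly interact" with a drug are modelled as
the seed genes plus their direct interactors, as the subgraph *induced* on
that closed neighbourhood — neighbour-neighbour edges are kept. One hop is
the only reading consistent with sub-network-scale results: transitive
closure would pull in essentially the whole giant component of any real
interactome. Seeds absent from the interactome are reported, not invented
as isolated nodes. Gene identity is the uppercased symbol; no alias or
ortholog resolution is attempted (the shipped montelukast seed fixture
keeps its published spelling "SLCO2B" verbatim rather than silently
correcting it to SLCO2B1).

The PSI-MITAB reader takes symbols from the alias columns (5/6), falling
back to alternative-identifier and unique-identifier columns stripped of
database prefixes, reads taxa from columns 10/11, tolerates extra columns
(as iRefIndex emits), drops self-interactions and collapses repeated pairs
while counting source records per edge.

## MCODE

MCODE detects densely interconnected regions in three stages, implemented
from scratch on top of igraph primitives:

1. **Vertex weighting.** For each vertex `v` with degree at least
   `degreeCutoff` (default 2), take the subgraph induced on the closed
   neighbourhood `N[v]`, find its highest k-core (the largest `k` whose
   k-core is non-empty), and set
   `weight(v) = k * density(highest k-core)` with density
   `2E / (n(n-1))`. For a complete graph K_n every weight is `n - 1`.
2. **Complex prediction.** Repeatedly seed from the unvisited vertex of
   highest weight and grow breadth-first (depth bound `maxDepth`,
   default 100), admitting an unvisited neighbour `u` iff
   `weight(u) >= weight(seed) * (1 - nodeScoreCutoff)` (default cutoff
   0.2). Admitted vertices are marked visited whether or not the
   candidate survives post-processing.
3. **Post-processing.** Candidates whose induced subgraph has no k-core
   with `k >= kCore` (default 2) are discarded; `haircut` (default on)
   iteratively removes degree-<2 members; `fluff` (default off) adds
   unvisited neighbours whose closed-neighbourhood density exceeds
   `fluffDensityCutoff` and is the only stage that can make complexes
   overlap. The complex score is `density * size`.

Where the behaviour of the familiar Cytoscape plug-in is
version-dependent (traversal order, tie handling), pvnet fixes
deterministic rules: ties in seed selection and in the final ordering go
to the lexicographically smallest vertex name, growth is breadth-first,
and complexes are ordered by descending score. Exact concordance with any
particular plug-in build is therefore not promised; determinism is.

Two behaviours of the algorithm itself are worth knowing when
interpreting output. First, equally dense regions connected by even a
single edge merge into one complex whenever the far side's weights clear
the admission band — the admission rule bounds weights relative to the
seed, not connectivity. Second, the admission band (20% below the seed's
weight by default) means members of a dense module whose weights trail
the seed's by more than the band are left out, so predicted complexes are
often conservative cores of the underlying module. Both effects are
visible in the planted-module validation below.

## Over-representation analysis

A query gene list is tested against every set of a collection with the
hypergeometric upper tail: with universe size `N`, set size `K`, query
size `n` and overlap `k`, `p = P(X >= k)`, `X ~ Hypergeom(N, K, n)`,
evaluated through the log-space survival function for stability. The
universe defaults to the union of the collection's genes — the common
behaviour of enrichment tools when no background is given — and can be
overridden; the query is intersected with the universe first.
Benjamini-Hochberg adjustment spans *all* tested terms, not only the
reported (`k >= 1`) ones, and significance requires `p <= 0.05` and
`q <= 0.1` by default. The q-value defaults to the BH-adjusted p itself
(Storey's estimator with `pi0 = 1`), because pi0 estimation is unstable
for the small term counts typical of per-cluster analyses; a smoothed
Storey estimate is available as an option and can only tighten q.

# The synthetic-data generators

`simulateReports()` emulates a spontaneous-report database: each report
exposes each drug independently, each event occurs with probability
`odds/(1+odds)` where the odds are the event's baseline odds multiplied by
the odds ratios of injected drug-event associations whose drug is exposed.
Multiplying *odds* (not probabilities) makes the injected odds ratio the
exact estimand of the ROR for rare events. One uniformly chosen exposed
drug is marked PS, the rest C, and a configurable fraction of cases is
re-emitted as an earlier case version so deduplication has planted
duplicates to find. Defaults — 20,000 reports, five drugs at 5% exposure,
six PTs across two SOCs at baseline odds 0.01, one injected association of
odds ratio 10, 20% duplicates — are the conditions used throughout the
package's validation; 5% exposure and 1-in-100 baseline odds are rates a
pharmacovigilance analyst would call a common drug and a moderately rare
event. Under these conditions the measured ROR is mildly attenuated
(expectation near 8 rather than 10): a report whose PS drug is a
comparator can still expose the target drug and carry its elevated event
odds, inflating the non-exposed event rate. That attenuation is a real
property of PS-restricted disproportionality analysis, not a simulation
artefact, and the validation band accounts for it.

`simulatePpi()` generates a planted-partition interactome: dense modules
(`pIn`, default 0.9, two modules of 12) over a sparse background (`pOut`,
default 0.02, 100 background nodes), emitted as minimal PSI-MITAB with
`taxid:9606`. Note that *all* non-intra-module pairs are edged at `pOut`,
including cross-module pairs, so with the default sizes the two modules
are directly linked in most realizations — which exercises the MCODE
merging behaviour described above and keeps top-2 module recovery at the
Jaccard-0.8 level rare. `simulateGenesets()` aligns gene-set collections
with the planted modules (each module's members plus 10% decoys, plus
uniform noise sets), emitted both as GMT and as a disease-gene TSV.

All generators take an explicit integer seed, restore the caller's RNG
state, and are bit-reproducible given configuration and seed.

What the generators do *not* emulate — and what passing tests therefore do
not show about real data: real FAERS marginal distributions, reporting
biases, drug-name mess and MedDRA term inventories; scale-free interactome
degree distributions and redundant iRefIndex records beyond exact
duplicate pairs; ontology structure or set-size distributions of real
pathway databases.

# Validation design and problem sizes

The test suite checks every statistic against an independent oracle at
sizes chosen to keep the whole suite in the low minutes on one core:
exact cross-product RORs over all 2x2 tables with cells 1..6; Wald
coverage of a true odds ratio of 1 over 2,000 multinomial tables of 500
reports (expected in the usual 93-97% Wald band); hypergeometric upper
tails against exact combinatorial summation for every parameter
combination with N <= 12; BH against hand-evaluated step-up vectors;
MCODE against hand-workable graphs (complete graphs with satellites,
paths, bridged cliques) and brute-force k-core fixed points; estimator
recovery of an injected odds ratio of 10 over 100 simulated databases of
20,000 reports; planted-set enrichment rank-1 recovery and null-query
specificity over 100 collections; and byte-identical reruns of both
pipelines. `scripts/acceptance.R` recomputes the headline quantities of
the same design from scratch against the installed package.

# Known limitations

* No PRR, IC/BCPNN or EBGM statistics; no stratified or adjusted RORs; no
  time-to-onset analysis.
* The PT-to-SOC map is a flat two-column table supplied by the user; the
  MedDRA hierarchy itself is licensed and cannot be shipped.
* Duplicate detection is by case-id versioning only.
* MCODE complexes are deterministic but, as discussed, merge bridged
  dense regions and trim low-weight module members; they should be read
  as cores, not as exhaustive module memberships.
* Enrichment p-values inherit the usual caveats of the hypergeometric
  model: independence of genes is assumed and the universe choice
  materially changes results.
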