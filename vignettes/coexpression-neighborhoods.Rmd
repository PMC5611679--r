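---
title: "HRR co-expression neighborhoods: models, choices, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HRR co-expression neighborhoods: models, choices, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrrnet)
```

## The statistic

Given a genes-by-samples matrix of TPM values, the co-expression strength
between two genes is their Pearson correlation coefficient (PCC) across
samples. Raw PCC thresholds behave badly across genes — a hub gene can be
"highly correlated" with thousands of partners while a quietly expressed
gene correlates weakly with everything. Rank-based statistics normalise for
this. The directed rank `rank(A, B)` is the position of B when all of A's
partners are sorted by PCC, best first. The Highest Reciprocal Rank is

$$\mathrm{HRR}(A, B) = \max\{\mathrm{rank}(A, B),\ \mathrm{rank}(B, A)\},$$

the *worse* of the two directed ranks. A pair has small HRR only when each
gene ranks the other highly — a stringent, symmetric reciprocity criterion.
The *co-expression neighborhood* of a query gene is the set of partners with
HRR within a cutoff (500 by default, a conventional choice for
genome-scale plant matrices with tens of thousands of genes).

Ranks are computed on *signed* PCC descending: the neighborhoods are lists
of co-expressed genes, so anti-correlated partners deliberately rank last.
Mutual Rank (the geometric mean of the two directed ranks) is a related but
different statistic and is out of scope.

## Rank construction details

The rank definition leaves three things open; `hrrnet` fixes them as
follows, and each choice is enforced by tests:

* **Rank direction.** Rank 1 is the most-correlated partner, self excluded.
  This is the only direction under which "HRR below a cutoff" selects
  strongly co-expressed pairs.
* **Tie policy.** Ordinal, with ties broken by ascending partner
  identifier in byte (C-locale) order. Every rank table is therefore a
  permutation of `1..G-1` and results are bit-reproducible. Fractional or
  average ranks would break the permutation property and downstream
  cutoffs. Two floating-point PCC values tie only when they are exactly
  equal; no epsilon snapping is applied, so results are deterministic given
  the input bytes.
* **Cutoff inclusivity.** `hrr <= cutoff` by default; an exclusive
  `hrr < cutoff` variant is a flag, since both conventions circulate and
  differ only at the boundary value.

Ranking happens against every gene that survives the zero-variance filter
(PCC is undefined for constant genes, so they are removed and reported
before any correlation is computed), not against a further-curated
expressed subset; curation is left to the caller.

## Per-query computation and the brute-force reference

`hrr_neighborhood()` never materialises the full G×G correlation matrix.
It computes the query's correlation row, ranks it, and then — because
`HRR >= rank(query, partner)` — only the partners the query itself ranks
within the cutoff can pass. For those candidates, the reciprocal rank is
obtained by counting, blockwise over candidate rows, how many genes beat
the query in each candidate's correlation row. This is `O(cutoff · G)`
memory-light work per query instead of `O(G²)`.

`hrr_all_pairs()` is the deliberately naive reference: full correlation
matrix, full rank tables, HRR by definition for every unordered pair,
guarded to 2000 genes. The test suite requires the fast path to reproduce
the reference *exactly* — same partners, same ranks, same HRR — for every
gene of a fixed-seed random 300 × 25 matrix and across cutoffs. Both paths
evaluate correlations through the same per-pair routine (`stats::cor` with
an explicit `y`), whose results do not depend on how rows are grouped into
blocks, so agreement is exact rather than within a tolerance.

## List comparison

Within a species, neighborhoods are compared by exclusive Venn region
counts (`venn_regions()`): every gene in the union is bucketed by its exact
membership signature, so counts always sum to the union size. The
graphical ellipse layout of a Venn diagram is intentionally not produced;
the counts are the analysis result.

Across species, lists live in different identifier namespaces and are
bridged by an ortholog map that may be many-to-many. "Shared" is defined
at the *pair* level — an ortholog pair counts when its X member is in the X
list and its Y member in the Y list — while distinct shared genes are
counted per species and percentages are taken against each species' own
list size. Under many-to-many maps this is the only definition that keeps
both percentages at or below 100; the pair count, the two distinct-gene
counts, and both percentages are all reported rather than collapsing them
into a single ambiguous "shared genes" number.

## GO enrichment

Over-representation of a term in a query list of size $n$ against a
universe of size $N$ with $K$ carriers is tested with the upper-tail
hypergeometric probability
$P(X \ge k) = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}$,
evaluated via `stats::phyper` (log-space available for extreme tails). The
defaults mirror standard practice for co-expression lists: biological
process terms only, raw p-value cutoff `alpha = 0.001` with **no**
multiple-testing correction (Benjamini–Hochberg is available but off), and
terms reported only when at least `min_genes = 5` *query* genes carry them.
The `min_genes` filter is interpreted on the query count `k` because the
reported bar for a term is the number of co-expressed genes behind it; a
universe-count interpretation (`K >= 5`) is a switch.

The universe defaults to the annotated genes among those that survived the
variance filter. This keeps $N$, $K$ and $n$ drawn from the same
population; an all-genes universe is available. Query genes outside the
universe are dropped from $n$ with a warning rather than failing the run.
Annotations are used exactly as provided — there is no ontology-graph
ancestor propagation, which would require an OBO parse that is out of
scope.

## The synthetic study generator

Real genome-scale corpora (tens of thousands of genes over hundreds of
heterogeneous public RNA-seq runs) cannot be shipped or rebuilt at desk
scale, so every stage is validated against a generator with known ground
truth. The model is a single latent factor per module:

$$x_{gs} = \mu + \beta_m z_{ms} + \varepsilon_{gs}, \qquad
z_{ms} \sim \mathcal{N}(0, 1), \quad \varepsilon_{gs} \sim \mathcal{N}(0, \sigma^2),$$

with background genes lacking the factor term. Its virtue is the exact
closed form for the expected within-module correlation,
$\beta^2 / (\beta^2 + \sigma^2)$, which gives analytic acceptance surfaces:
the defaults $\beta = 2, \sigma = 1$ plant modules at PCC $0.8$.
Non-negativity is achieved by shifting the whole matrix so its minimum is
zero — PCC is shift-invariant, so the planted structure is preserved
*exactly*, unlike exponentiation. The default study size is 1000 genes ×
100 samples with one 50-gene module; at that size the module is recovered
by a 49-partner HRR neighborhood with precision ≥ 0.9 over 20 replicate
seeds, and the tests assert exactly that.

Seeding is hierarchical: each module's latent vector and each gene's noise
vector draw from their own stream derived from the global seed, so adding
a module leaves earlier genes' values unchanged (up to the global shift) —
a property the tests check directly.

Annotation simulation plants one biological-process term per module
covering a configurable fraction (default 0.8) of its genes, plus
background terms sprinkled independently (default rate 0.05 per gene-term
pair) with aspects cycling over the three GO aspects so aspect filtering
is exercised. Ortholog simulation pairs a configurable fraction of
species-X genes bijectively (default 0.8), gives another fraction two
partners (default 0.1, modelling duplication), and leaves the rest
unmapped.

What the generator does **not** emulate, and hence what passing tests do
not show: negative-binomial count noise, library-size and batch effects,
zero inflation, overlapping modules, and correlated background structure.
The generator validates the *algorithmic* pipeline, not robustness to
RNA-seq count pathology; PCC and HRR operate on TPM-scale real values
either way.

## Numerical and I/O choices

* Matrix TSVs are written with `%.17g` formatting and parsed back through
  R's `strtod`, so a write/read cycle reproduces every double bit-exactly;
  the round-trip is asserted in tests.
* `NA` cells, ragged rows, duplicate identifiers and negative TPM are
  rejected with the offending row named, rather than silently coerced.
* Correlation uses the sample (n−1) normalisation throughout; PCC itself
  is normalisation-independent.
* All list orderings use byte-order (radix) sorting, so outputs do not
  depend on the session locale.
* The pipeline writes a manifest (config echo, input MD5 checksums,
  package and R versions, stage timings). Analysis outputs are
  byte-reproducible across reruns on identical inputs; the manifest's
  timings are the only varying artifact.

## Problem sizes used by the test and acceptance runs

Exactness checks run on a 300-gene × 25-sample random matrix (full
all-pairs reference) and a 4-gene hand-computed example; recovery checks
use twenty replicates of the 1000 × 100 planted-module study and ten
replicates for enrichment recovery; Monte-Carlo validation of the
hypergeometric tail uses 10⁵ draws per parameter set with universes up to
10⁴. These sizes make the complete suite run in well under a minute per
stage while keeping every statistical check comfortably powered.

## Known limitations

* HRR neighborhoods are query-centric lists, not a global network; no
  clustering or module *discovery* is provided — the comparison targets
  are the query genes the user names.
* Transcript-to-gene aggregation is not performed; the quantification
  table's `Name` column is taken as the analysis unit.
* Ortholog maps are inputs; no orthology inference is attempted.
* With the raw-p default, the 0.001 cutoff controls neither FWER nor FDR;
  users scanning many terms should switch on the BH option.
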