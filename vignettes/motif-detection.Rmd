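---
title: "Motif detection in samples of vertex-labeled directed networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif detection in samples of vertex-labeled directed networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labmotif)
```

## The problem

Effective connectivity analysis of multichannel EEG yields, per subject or
condition, a directed graph on a fixed set of electrode labels: an edge
u → v records a significant directed influence from channel u to channel v.
A study group is therefore a *sample* of directed simple graphs that all
live on one identical, pairwise-distinct label set. This package asks which
small connected subnetworks recur across such a sample more often than the
sample's overall connection density explains — the network-motif question,
specialized to labeled samples.

The labeling changes everything about how motifs are found:

* two subnetworks are identical exactly when they have the same set of
  directed labeled edges, so graph isomorphism never needs to be decided and
  a motif retains its *position* (which electrodes it spans), not just its
  shape;
* a given subnetwork can occur at most once per network, so counts within
  one network are uninformative and the usual z-score against rewired
  random ensembles is unusable. Significance must come from the count
  across the sample, for which an analytic null distribution exists.

## Model and procedure

Let the sample be $\mathcal{N} = (\mathcal{N}_1, \dots, \mathcal{N}_n)$ on
$\nu$ labels, member $i$ having $k_i$ of the $\nu(\nu-1)$ possible directed
edges (no loops, no multi-edges; mutual connections are two opposite edges).

**Enumeration.** For each member, every one of the $\binom{\nu}{\nu_S}$
vertex combinations is examined and its *induced* subnetwork (exactly the
member's edges with both endpoints inside the combination) is kept when it
is weakly connected. Each distinct labeled subnetwork is counted once per
member containing it; `subnetwork_census()` aggregates the counts.

**Null model.** `fit_null()` estimates the independent-edge density
$$q = \frac{1}{n\,\nu(\nu-1)} \sum_{i=1}^n k_i,$$
the normalized mean edge count. Under the null every ordered pair of
distinct vertices carries an edge independently with probability $q$, so a
null network has $q\,\nu(\nu-1)$ edges in expectation.

**Occurrence probability.** A candidate subnetwork $S$ with $\eta_S$ edges
on $\nu_S$ vertices can have at most $\eta_{S\max} = \nu_S(\nu_S-1)$ edges.
Because counting is by *induced* subgraph, $S$ occurs in a null network iff
its $\eta_S$ edges are present and the other
$\eta_{S\max} - \eta_S$ ordered pairs among its vertices are absent:
$$P(S) = q^{\eta_S}(1-q)^{\eta_{S\max}-\eta_S}.$$
The indicator variables across members are i.i.d., so the sample count of
$S$ is $\mathrm{Binomial}(n, P(S))$.

**Test.** `motif_detect()` computes the exact one-sided upper-tail binomial
p-value per observed subnetwork — only *over*representation is tested, per
the method's definition of a motif — and applies the Holm step-down
correction at familywise level $\alpha = 0.05$ (configurable). Survivors
are the motifs.

## Design choices

**Weak connectivity.** Whether "connected" should ignore edge direction is
genuinely open; we use weak connectivity. It is the notion under which the
classical triad census arises: there are exactly 54 connected labeled
3-digraphs falling into 13 isomorphism classes, the counts the field quotes
for 3-subnetworks, and the package's enumeration reproduces both
(`count_weak_digraphs(3)` is 54; the test suite groups them into 13 classes
by brute-force relabeling). Strong connectivity would give different and
unfamiliar counts.

**The multiple-testing family.** "All subnetworks of a certain order are
tested" does not by itself fix the family size $m$. The default
(`family_mode = "all-possible"`) takes every connected labeled pattern of
the order as a hypothesis, $m = \binom{\nu}{\nu_S} W(\nu_S)$ with
$W(\nu_S)$ the number of weakly connected digraphs on $\nu_S$ labeled
vertices — 4536 for 3-subnetworks on 9 labels. Unobserved patterns
implicitly carry p-value 1: they can never be rejected but they enlarge the
correction factors, making this the conservative reading.
`family_mode = "observed-only"` restricts the family to patterns actually
seen, for sensitivity analysis; both the mode and $m$ are recorded in the
fit and in written tables. $W$ is computed by the inclusion–exclusion
recurrence $W(m) = D(m) - \sum_{j<m} \binom{m-1}{j-1} W(j) D(m-j)$ with
$D(m) = 2^{m(m-1)}$; `all_connected_keys()` generates the patterns
exhaustively for orders 2–4 and cross-checks the recurrence in the tests.

**Holm, not FDR.** The correction controls the familywise error rate in the
strong sense rather than the false discovery rate — the conservative choice
appropriate when a declared motif is to be interpreted individually.
Internally the adjustment is `stats::p.adjust(p, "holm", n = m)`, which for
$m \ge$ the number of observed patterns is exactly the step-down formula
$\tilde p_{(k)} = \max_{j \le k} \min\{1, (m-j+1)\,p_{(j)}\}$; ties in the
p-values are reported in canonical key order, which cannot affect the
adjusted values.

**Numerical conventions.** $P(S)$ is evaluated in log space for
$0 < q < 1$, so tiny probabilities reach the binomial tail unrounded, and
tables print p-values in scientific notation rather than flushing them to
zero. The degenerate densities use $0^0 = 1$: at $q = 0$ the census is
necessarily empty (an observed subnetwork would be inconsistent and raises
an error); at $q = 1$ any observed non-complete induced pattern likewise
raises a consistency error, since a density-one sample contains only
complete networks. The binomial tail is the exact survival function
(`pbinom(count - 1, n, p, lower.tail = FALSE)`), never a normal
approximation.

**Canonical keys.** A subnetwork is serialized as its edges sorted by
(tail, head) and joined as `"C3>Cz;Cz>C3"`. The separators `>` and `;` (and
`,`, whitespace) are forbidden in labels, so serialization is a bijection on
weakly connected labeled edge sets; parse–serialize round trips are tested
property-style. Vertex identity is purely by label string, and adjacency
matrices are normalized to sorted label order so that files listing the
same network with different vertex orders compare equal.

**Sample members need not be connected.** Connectivity is a requirement on
candidate *subnetworks*, not on the input networks — real effective
connectivity networks are occasionally disconnected and are accepted as-is.

## The synthetic-data generator

`generate_null_sample()` draws each member with i.i.d. edges at probability
$q$; its defaults are the study conditions this package is dimensioned for:
$n = 16$ networks on the 9 electrode labels at density $q = 36.79/72
\approx 0.511$, the mean edge count reported for real ECN samples.
`generate_ecn_like_sample()` is the convenience wrapper with exactly those
settings. One root seed deterministically derives a substream per member
(Lehmer-style mixing), so enlarging $n$ does not reshuffle earlier members'
draws and every generator is a pure function of configuration and seed.

`plant_subnetwork()` forces a chosen pattern into each member with a given
penetrance. Planting sets the key's edges present **and** the remaining
ordered pairs among its vertices absent: counting is by induced subnetwork,
so planting only the edges would yield a different induced pattern whenever
background edges land inside the vertex set.

What the generator emulates is precisely the method's null hypothesis plus
an optional localized effect. Real ECNs have structure the generator does
not: spatially correlated edges, degree heterogeneity across electrodes,
within-subject dependence between frequency bands. Passing calibration and
recovery tests on generated data therefore validates the statistical
machinery under its own assumptions; it does not certify the i.i.d.-edge
null as a faithful model of brain connectivity — that is an interpretive
judgement outside the package's scope.

## Verification in the test suite

The suite checks, among others: exact agreement of the enumerator with a
brute-force igraph oracle on random networks of up to 5 vertices; the
54/13 triad census; normalization of the pattern probabilities over a fixed
vertex subset; agreement of the analytic occurrence probability with
exhaustive enumeration of all 64 weighted 3-vertex digraphs to $10^{-12}$;
the binomial tail against direct summation for $n \le 32$; Holm against the
literal step-down formula. Two simulation studies run at the study
conditions ($\nu = 9$, $n = 16$, $q = 0.51$): 200 pure null samples bound
the familywise false-motif rate at order 3, and 100 planted samples at
penetrance 1 establish near-certain recovery. These sizes give Monte-Carlo
standard errors of about 0.015 and 0.01 respectively, small enough to
detect a miscalibrated test while keeping the default suite quick.

## Limitations

* Exhaustive enumeration scales as $\binom{\nu}{\nu_S}$ per member; the
  package targets small dense networks (tens of vertices, orders 2–4), not
  genome-scale graphs.
* Only overrepresentation is tested; anti-motifs (significantly *rare*
  patterns) are out of scope, as are degree-preserving null models and
  isomorphism-class aggregation.
* The null model shares one density $q$ across all vertex pairs; strong
  degree heterogeneity in real data will concentrate spurious
  overrepresentation on high-degree vertices, a caveat for interpretation
  rather than a computational issue.
* `predict()` is not provided: the estimator has no new-data prediction
  task. `simulate()` fills the corresponding role by drawing samples from
  the fitted null.

## Session

```{r}
sessionInfo()
```
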