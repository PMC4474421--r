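---
title: "Signed network discovery of compound-CYP interactions and its validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed network discovery of compound-CYP interactions and its validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypnet)
```

## The model

`cypnet` works on a layered, signed, directed interaction graph. Nodes are
compounds, CYP regulators (transcription factors and nuclear receptors that
control CYP expression) and CYP enzymes. An edge `a -> b` with sign +1 means
*a activates / up-regulates b*, sign -1 means inhibition / down-regulation,
and sign 0 marks a curated interaction whose direction the source did not
state. The central modelling assumption is **sign composition**: the net
direction of an indirect effect along a path is the product of the edge
signs, with 0 absorbing. Activating a repressor of an enzyme (+1 then -1)
predicts net down-regulation of the enzyme; any unknown-direction edge on
the path makes the whole prediction unknown.

```{r motif}
tab <- interaction_table(
  entities = data.frame(
    id = c("RA", "DAX1", "CYP19A1"),
    name = c("retinoic acid", "DAX1", "aromatase"),
    role = c("compound", "regulator", "enzyme")
  ),
  records = data.frame(
    source_id = c("RA", "DAX1"),
    target_id = c("DAX1", "CYP19A1"),
    sign = c(1L, -1L)
  )
)
net <- build_network(tab, c("compound", "regulator"), c("regulator", "enzyme"))
predict_interactions(net)
```

This is a *prediction of direction*, not of magnitude, and it inherits every
limitation of the curated edges: a literature-curated activation observed in
one tissue need not hold in another, which is exactly why the package ships
the validation-statistics side as well. Sign composition also ignores dose,
saturation and combinatorial regulation — two regulators acting on one
enzyme are aggregated only at the level of agreement between their paths.

## Conflict handling: conservative zeros

Curated databases contain contradictions. Everywhere signs disagree, the
package resolves to 0 (unknown) and warns, never by majority vote:

* duplicate edges for one ordered pair with different signs collapse to a
  sign-0 edge at network build or merge time;
* multiple paths from one compound to one enzyme with different net signs
  aggregate to 0, with all paths reported.

A majority rule would let a single extra curation flip a prediction's
direction; an explicit "unknown" is the honest summary. At read time,
conflicting records are *kept* as separate rows (only exact duplicates are
collapsed, with a multiplicity count), so the conflict is visible in the
data rather than resolved silently during parsing. Unmappable effect
keywords (e.g. a direction-less "binds") are hard parse errors rather than
silent sign-0 edges, because silent coercion would leak unknowns into every
downstream composition; users who want to keep such rows can pre-map them
explicitly.

## The elimination rules

The discovery network is reduced by two rules, exposed in `filter_config()`:

1. compounds with fewer than `min_compound_edges` (default 3) distinct
   incident edges are eliminated — weakly connected compounds are too
   thinly evidenced to support composed predictions;
2. regulators associated with no compound are eliminated.

Two genuinely open choices are made explicit here. First, "edges" is read as
*distinct incident edges* (in + out) in the deduplicated network, not
multiplicity of curation records — the least surprising reading, and the one
under which re-curation of the same fact cannot rescue a compound. Second,
the two rules are applied as a single ordered pass by default (degree rule
measured on the input network, orphan rule measured after the degree pass).
Removals cascade — dropping regulators lowers compound degrees — so
`iterate_to_fixpoint = TRUE` repeats both passes until stable, in which case
re-filtering is the identity. Neither order is claimed to be canonical;
both are available and both are oracle-tested.

## Clusters, path tracing, tie-breaks

Each regulator with at least one compound in-neighbour defines a hub
cluster whose members are those compounds; a compound influencing several
regulators sits in several clusters, and cluster size ranks regulators by
the breadth of compound influence. Ordering is size-descending with ties
broken by hub id (lexicographic) — reproducibility over arbitrariness.

`trace_paths()` enumerates **simple** directed paths (no repeated node) from
a compound to every terminal leaf (out-degree-0 node), with a depth cap
(default 10 edges). The curated two-layer network needs depth 2, but curated
data can contain regulator-regulator edges and even cycles; simple-path
enumeration with a cap keeps the search finite and the output deterministic
(paths are emitted in lexicographic node-sequence order, which a DFS over
lexicographically sorted adjacency lists yields for free).
`predict_interactions()` then narrows terminals to enzymes. Zero-length
paths are not emitted: a compound is not a prediction about itself.

## Validation statistics

The wet-lab design the statistics serve is a 6-group dose series (vehicle +
5 doses) in triplicate, so k = 6, N = 18, and the ANOVA has (5, 12) degrees
of freedom.

**Fold change.** The assay's fold-change formula is a user choice, not a
fixed convention: `ddct` computes per-replicate `2^-(Ct - mean vehicle Ct)`
(no reference gene — the package deliberately has no multi-target
normalisation), `ratio` divides relative values by the vehicle mean. The
per-dose *mean* fold change is the geometric mean (arithmetic mean of the
log2 values): it is the natural average for a log-scale assay, and it makes
the vehicle group's mean fold change exactly 1 by construction, which an
arithmetic mean would not.

**ANOVA.** `anova_oneway()` is the classical fixed-effects decomposition
(delegated to `stats::aov`; an explicit brute-force sums-of-squares oracle
backs it in the tests) with the p-value recomputed through the package's
`f_sf()`, i.e. the regularized-incomplete-beta identity
`sf = I_x(d2/2, d1/2)`, `x = d2/(d2 + d1 F)` — `pbeta` *is* the regularized
incomplete beta, so this is exact to ~1e-15. By default the workflow runs
the ANOVA on per-replicate fold changes (the quantity the dose-response
claim is about); raw-value ANOVA is available. Replicates run on different
days are treated as independent — with triplicates there is no room for a
day random effect, and the (5, 12) layout presumes independence. Zero
variance everywhere is an error, not `F = Inf`: degenerate data must not
masquerade as overwhelming significance.

**Tukey HSD.** For balanced groups,
`q = |mean_a - mean_b| / sqrt(ms_within/n)` referred to the studentized
range distribution with (k, N - k). Unbalanced input is an error by design
rather than a silent Tukey-Kramer switch — a silent fallback would change
the test without telling the analyst. `studentized_range_sf()` evaluates
the classical double integral by nested Gauss-Legendre quadrature (192
nodes per dimension; the outer scale integral on an interval adapted to the
chi density's concentration, `1 ± O(1/sqrt(2 df))`). Against the exact
`k = 2` identity `Q = sqrt(2)|t|` the quadrature agrees to ~1e-15, and it
remains well-defined at 1 error df. The 1e-6 accuracy contract is therefore
met with two orders of magnitude to spare; `ptukey` and the t-identity
serve as independent cross-checks in the test suite.

## The synthetic generators

The generators exist so that every stage has a known answer; their defaults
are the study conditions they emulate, chosen once.

**Interaction database** (`network_sim_config()` /
`generate_interaction_db()`): compounds draw a truncated-Poisson
(`mean_compound_degree`, default 3 — matching the degree-filter threshold's
regime) number of distinct regulator partners, sampled with per-regulator
`hub_weights`; fixed weights rather than preferential attachment, because
they give simple, exact ground-truth bookkeeping while still producing the
steeply skewed cluster sizes curated pharmacology networks show (the
`analysis/` workflow uses Zipf-like weights `1/rank`). Regulators draw
enzyme partners uniformly at rate `mean_regulator_degree` (default 2; the
generator needs *some* rate for the second layer and the spec of the
database leaves it open). Signs are iid from `sign_probs` (default
0.45/0.45/0.10 — a small unknown-direction fraction, as curated exports
have). Planted paths are embedded verbatim, and the recorded truth is the
aggregate net sign per (compound, enzyme). To keep that truth exact, random
edges are never drawn *out of* a planted compound or planted regulator — a
random out-edge there could open a second path to a planted enzyme with a
different sign and flip the true aggregate to 0; planted nodes may still
receive random edges. What the generator does **not** emulate: curation
errors (false edges, wrong directions) beyond the sign-0 fraction, so
planted-truth recovery shows pipeline correctness, not robustness to a
noisy literature.

**qPCR data** (`qpcr_sim_config()` / `generate_qpcr()`): Ct for dose d is
`baseline_ct - log2_effects[d] + N(0, noise_sd)` — Gaussian noise on the
Ct (log2-expression) scale, the standard qPCR error model; one effect unit
is one cycle, i.e. a 2-fold change. Defaults: 6 doses
(0, 0.1, 1, 10, 100, 1000 nM), 3 replicates, baseline 24 cycles, noise SD
0.25 cycles (a typical replicate spread for a well-behaved assay), and a
saturating effect profile (0, 0.75, 1.5, 2.25, 2.4, 2.5 log2 units) —
monotone through the low doses, flattening at the top. Not emulated:
day-to-day batch structure, amplification-efficiency deviation from 2,
reference-gene normalisation. Passing tests on this generator therefore
demonstrate the statistics, not robustness to real assay artefacts.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on generated data at
deliberately modest sizes — oracle comparisons on graphs of at most 12
nodes (exhaustive path enumeration is exponential), 50-network
planted-truth sweeps at 12 x 6 x 5 entities, 2000 null ANOVA simulations at
6 x 3 — sizes at which the brute-force oracles are exact and the whole
suite runs in well under a minute per property. Determinism is explicit
everywhere: generators restore the caller's RNG state, equal seeds give
byte-identical outputs, and the workflow writes a manifest echoing its
configuration.

Known limitations, beyond those noted above: no attempt is made to
reproduce counts that depend on any specific proprietary curated export;
the degree filter's reading of "edges" and the single-pass default are
documented choices, not established conventions; and Tukey support is
intentionally balanced-only.
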