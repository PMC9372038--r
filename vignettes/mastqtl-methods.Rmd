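---
title: "Meta-QTL analysis for multiple abiotic stress tolerance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-QTL analysis for multiple abiotic stress tolerance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mastqtl)
```

# The problem

QTL mapping studies for abiotic stress tolerance in bread wheat — drought
(DS), heat (HS), combined drought and heat (D+H), salinity (SS),
water-logging (WS), pre-harvest sprouting (PHS) and aluminium toxicity (AS) —
report loci on incompatible study-specific linkage maps, with wide and
heterogeneous confidence intervals. A meta-QTL (MQTL) analysis places all
published QTLs on one consensus map, clusters their peaks per chromosome, and
reports consensus loci with drastically narrower intervals. Loci whose member
QTLs span many stress classes are candidates for *multiple abiotic stress
tolerance* (MAST) breeding. `mastqtl` implements that pipeline end to end,
together with downstream physical anchoring, GWAS co-localization, candidate
gene mining, promoter cis-element scanning and cross-cereal (ortho-MQTL)
comparison, plus a ground-truthed synthetic-data generator used by the test
suite.

# Data model and imputation

A QTL record carries its study, population type and size, stress class,
chromosome, flanking markers, genetic peak and 95% CI (cM), LOD and PVE.
Validation never drops rows silently: rejected rows (unknown chromosome,
inverted CI, bad stress label, ...) are reported with reasons, mirroring the
explicit attrition accounting of published meta-analyses.

Missing fields are imputed by the field's conventions: LOD 3.0 and PVE 10
where absent; a missing peak becomes the midpoint of the flanking markers on
the source map. A missing 95% CI is estimated from the population-specific
empirical equation

\[ \mathrm{CI}_{95} = \frac{k}{N \cdot R^2}, \]

with \(N\) the population size and \(R^2\) the PVE as a proportion. The
constants default to the Darvasi–Soller lineage values \(k = 530\) (F2 and
backcross), \(287\) (doubled haploid), \(163\) (RIL); `other` populations use
the DH constant. The source literature for these equations does not print a
single canonical set, so the constants are exposed in `ci_config()` rather
than asserted.

# Consensus map

Published LP-based consensus-map software is replaced here by a documented,
deterministic anchor-average algorithm: per chromosome, each source map is
shifted to start at 0; markers shared by two or more maps (anchors) are
placed at the weighted mean of their shifted positions (weights default to
per-map marker counts); every other marker is placed by piecewise-linear
interpolation between its flanking anchors on its own map, with end-segment
extrapolation. The construction is symmetric in the listed map order under
equal weights, and preserves any anchor ordering on which all source maps
agree. The densest map per chromosome acts as the *frame*: where the
averaged order contradicts the frame's order the markers are flagged
`order_conflict` rather than force-reordered — forcing frame order after
averaging would contradict the weighted-mean placement rule, so the conflict
is surfaced instead of hidden. Maps sharing fewer than two anchors cannot be
rescaled; their private markers are reported `unanchored`, and when a whole
chromosome has fewer than two anchors the frame map alone is the backbone.
QTL flanking markers missing from the consensus are injected afterwards by
interpolation (`augment_consensus()`), as meta-analyses do to maximise
projectable QTLs.

# Projection

A QTL travels from its source map to the consensus through a *context*: a
pair of common markers flanking its peak. Among all flanking common pairs
the selected context minimises the interval-length discrepancy
\(|\log(L_\mathrm{cons}/L_\mathrm{src})|\) subject to the ratio cap
`max_ratio` (default 5); enumerating all pairs implements the outward
widening search. The peak maps through the context's affine transform; CI
endpoints map through the piecewise-linear transform over *all* common
markers, so an endpoint outside the context uses its own nearest common
interval. Rejections carry reasons: `no_common_markers`, `peak_out_of_map`,
`no_feasible_context`, `degenerate_context`, `heterogeneous_context`,
`large_CI`.

Two further thresholds are deliberate, documented surrogates for
undocumented behaviour of the published projection tool: a two-interval
proportionality z-test (threshold `min_p`, default 0.05; the z-score compares
the log local scales at the two CI endpoints against the spread of log scales
along the chromosome, floored at 0.25 so near-identical maps are never
rejected), and a projected-CI cap `max_ci_cm` (default 50 cM) implementing
the practice of discarding QTLs whose intervals are too diffuse to cluster.

# Meta-analysis model

On each chromosome the projected peak positions \(x_i\) follow a Gaussian
mixture with *known per-observation variances*:

\[ x_i \mid k \sim \mathcal{N}(\mu_k, \sigma_i^2), \qquad
   \sigma_i = \mathrm{CI}_{95,i} / 3.92, \]

the standard inversion of a normal 95% interval, floored at 0.05 cM. Only
the \(K\) means and \(K-1\) mixing weights are free, so \(d = 2K - 1\). EM
maximises the likelihood (E-step posteriors; M-step weights as posterior
means and component means as posterior-weighted inverse-variance means) with
quantile-spread initialisation plus jittered restarts, stopping when the
log-likelihood changes by less than 1e-8 (at most 2000 iterations).

\(K\) is chosen by vote over five criteria: AIC, AICc, AIC3, BIC and AWE
(classification likelihood under hard assignment, penalty
\(2d(3/2 + \log n)\)). The selected \(K\) must take the minimum in at least
three of the five; failing that, the BIC-minimal \(K\) is used, and remaining
ties go to the smaller \(K\). `k_max` defaults to `min(n, 10)` per
chromosome.

Hard membership requires a maximum posterior of at least 0.5 (below it the
QTL is reported *unassigned*, never forced). A component's position is the
inverse-variance weighted mean of its members,
\(\hat\mu = \sum x_i/\sigma_i^2 \big/ \sum 1/\sigma_i^2\), with
\(\mathrm{CI}_{95} = \hat\mu \pm 1.96/\sqrt{\sum 1/\sigma_i^2}\) — pooling
never widens the interval beyond any single member's. Single-member
components are singletons; components whose members all share one study are
*single-study hotspots* and are discarded: a true MQTL needs at least two
QTLs from distinct studies. Survivors are named `MQTL<chrom>.<rank>` by
ascending position. MQTL LOD and PVE are plain arithmetic means of the
members (a posterior-weighted mean is available via `pve_weighting =
"posterior"`; published meta-analyses do not state which they use, and the
plain mean is the default because it matches the stated definition).

# Physical anchoring and downstream layers

Genetic CIs become physical intervals through the nearest consensus markers
at or outside the CI endpoints that have physical positions; missing flanks
fall back outward with `extended_left`/`extended_right` flags. The physical
peak is

\[ \mathrm{peak} = \mathrm{start} +
   \frac{\mathrm{end} - \mathrm{start}}{\mathrm{end}_{cM} - \mathrm{start}_{cM}}
   \cdot \frac{\mathrm{CI}_{95}}{2}, \]

clamped into the interval; a zero-width genetic span (0.00-cM CIs do occur in
published tables) takes the bp midpoint. Coordinates are 1-based inclusive
internally; BED export converts to 0-based half-open.

Co-localization uses closed-interval, any-overlap semantics on 1-based
coordinates (boundary hits count; the convention is documented because
published methods rarely state it). An MQTL is GWAS-validated when at least
one marker–trait association falls inside its physical interval; an optional
LD window exists but defaults to 0 (exact containment).

Gene mining follows the two-rule window: MQTLs with a physical CI of at most
2 Mb are mined whole; wider ones are mined 1 Mb either side of the physical
peak. Differential expression is a pure fold-change filter on log2 TPM:
\(|\log_2 \mathrm{FC}| \ge 1\) (i.e. two-fold) per condition versus its
control, computed per time point. The often-printed rule "FC ≥ 2 or
FC ≤ −2" cannot be read literally on a ratio scale; the two-fold reading is
the only consistent one and is the default (`min_fc = 2`). A pseudocount
(0.01) guards zero TPM when raw values are supplied. Candidates are tiered
by the number of datasets supporting them; three or more marks a gene
*promising*.

Promoters are the 1500 bp upstream of the translational start (reverse
complement for minus-strand genes), truncated with a flag at chromosome
ends. Cis-element scanning is exact IUPAC-consensus matching on the sense
strand only, against a bundled motif table (ABRE, MBS, ARE, LTR, STRE,
WUN-motif and friends) with growth/stress/hormone/core/uncharacterized
categories. This is a deterministic offline stand-in for matrix-based web
scanners: adequate for categorical tallies, not a per-motif score
replication, and the package treats it as such.

Ortho-MQTL detection joins mined wheat genes to a user-supplied orthologue
table and declares a (wheat MQTL, foreign MQTL) pair when at least
`min_genes` (default 1; published analyses accept "a few to hundreds")
orthologues fall inside the foreign interval.

# The synthetic-data generator

`simulate_scenario()` fixes the study conditions; `simulate_studies()` and
`simulate_omics()` realise them deterministically under the scenario seed.
The default scenario uses three chromosomes (one per subgenome, 150 cM /
150 Mb each — physical lengths scaled down from real wheat chromosomes),
a base map of 5 markers/cM (sparser than the ~15 markers/cM of real
consensus maps, so marker density is not flattering the method), three
reference maps (60% subsets, 0.05 cM jitter, terminal markers retained so
the consensus origin matches the truth's coordinate frame), eight RIL/DH
studies of 150–300 individuals each carrying 40% of the base markers
(affine scale 0.9–1.1, 0.1 cM jitter, order repaired by re-sorting), and
about 200 QTLs around six true MQTLs, two/three/one per chromosome,
separated by at least eight times the largest per-QTL standard deviation.
Peaks are drawn in consensus coordinates as
\(\mathcal{N}(\mu_\mathrm{true}, \sigma)\) with \(\sigma\) implied by the
population's CI equation (PVE 8–25%), then pushed into each study's frame
through that study's map, so projection must invert a known transform.
Configurable fractions of records lose their LOD, PVE, CI or peak to
exercise imputation, and a small fraction get an unresolvable flanking
marker to exercise the unprojectable path. Every true MQTL is a MAST locus
by construction: its members cover all stress classes before the weighted
stress draw (weights roughly follow the published per-stress QTL
proportions, salinity and drought heaviest).

The omics layers plant their own truth: six MTAs per true locus within
±0.1 Mb (tight linkage with the causal position on the scaled-down genome;
background rate 0 by default, so every validation is informative), four
genes per locus within ±50 kb among 80 background genes per chromosome —
both planting scales sit inside the position resolution the meta-analysis
achieves under the default conditions (standard error of an MQTL position
about 0.25–0.3 cM, i.e. 0.25–0.3 Mb here), so recovery metrics measure the
implementation rather than seed luck — eleven promising genes differential (|log2FC| 1.5–3) in at
least three of four expression datasets plus six decoys in one or two,
three literature motifs planted per promoter at recorded offsets, and two
conserved regions per foreign species with orthologues placed inside the
foreign intervals plus a negative control outside.

What the generator does *not* emulate — and what green tests therefore do
not show about real data: genotype-level linkage (no meioses or
recombination), non-normal peak error, correlated QTL effects across
studies, pleiotropy structure beyond label sharing, expression dispersion
(noise sd 0.05 around planted effects), and real marker ascertainment.
Passing the suite demonstrates correctness of the computations under the
stated model, not field performance.

# Numerical choices and problem sizes

Degenerate inputs are handled explicitly: zero-length projection contexts
reject rather than divide by zero; zero-width genetic spans anchor to bp
midpoints; empty chromosomes, empty annotations and empty hit lists return
typed empty tibbles; sigma is floored at 0.05 cM; EM weights are floored at
1e-12 and renormalised. Ties break deterministically (smaller K, tighter
context, frame-map order), so equal inputs give byte-identical artifacts
under a fixed seed.

The test-suite and acceptance-script problem sizes are chosen to exercise
every path at desk scale: the default scenario (~200 QTLs, ~2 250 base
markers) runs the whole pipeline in under a minute; the model-selection
recovery study uses 100 seeded chromosomes with true \(K \in \{1,2,3\}\),
15–25 QTLs per component and \(K\) fitted up to 5 with 4 restarts; the EM
oracle check enumerates all hard assignments at \(n \le 8\). Chromosome-level
fits use `k_max = 6` and 5 restarts in the end-to-end runs, ample for six
planted loci.

# Known limitations

The consensus algorithm is an order-preserving surrogate, not an LP
reconstruction; maps with gross order conflicts are flagged, not re-solved.
The homogeneity z-test is a calibrated heuristic, not the published tool's
internal statistic. Mixture components share no spatial prior, so two true
loci closer than a few member standard deviations merge. The fold-change
DEG filter carries no dispersion model by design (the published method used
none). The promoter scanner reports consensus matches only — position
weight matrices are out of scope.
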