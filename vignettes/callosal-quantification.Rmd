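---
title: "Quantifying callosal connectivity from retrograde tracer data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying callosal connectivity from retrograde tracer data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpnquant)
```

## The measurement problem

A retrograde tracer deposited in one cortical area is taken up by axon
terminals and transported back to the cell bodies that project there. Charting
the labeled neurons therefore maps the area's afferents: neurons in the same
hemisphere are its ipsilateral cortico-cortical input, and neurons in the
opposite hemisphere are callosal projection neurons (CPNs), whose axons cross
the corpus callosum. Callosal input divides further into the *homotopic*
projection — from the contralateral area with the same name as the injected
one — and *heterotopic* projections from all other contralateral areas.

`cpnquant` implements the quantitative side of this analysis for bilateral
charts of macaque frontoparietal injections: per-case counting with the
standard exclusions, the derived case statistics, laminar classification of
connections, and the cross-case statistics used to compare region groups. A
ground-truth simulator makes every stage testable without access to raw
charts, which are generally unpublished.

## Case-level statistics

For one injection case let $I$ be the number of labeled neurons in the
ipsilateral hemisphere *outside the injected area* (uptake at the deposit
itself is not an afferent and is counted separately, never silently dropped),
$C$ the number in the contralateral hemisphere, and $H \le C$ the count in
the homotopic area. The package computes:

* **Callosal percentage** $\%\mathrm{CPN} = 100\,C/(I+C)$ — the weight of the
  callosal input in the area's overall cortical afferents
  (`percent_cpn()`).
* **Homotopic fraction** $100\,H/C$ — the homotopic share of the callosal
  input (`homotopic_fraction()`). When $C = 0$ this is *undefined* and is
  returned as `NA` with a warning: a case with no CPNs carries no information
  about their homotopic share, and reports omit the value rather than plot a
  zero.
* **Areal distributions** — per-area percentages of each hemisphere's
  labeling after the exclusions (injected area ipsilaterally, homotopic area
  contralaterally), normalized to 100 (`areal_distribution()`).
* **Laterality index** — for each area holding strictly more than 1% of the
  ipsilateral labeling, the ratio of contralateral to ipsilateral counts in
  that area (`laterality_index()`). It is 0 when the area projects only
  ipsilaterally, 1 at bilateral symmetry, and exceeds 1 when the
  contralateral area dominates. The 1% floor keeps the denominator away from
  unstable small counts; it is applied to the ipsilateral distribution
  *after* the injected-area exclusion, and the inequality is strict, so an
  area at exactly 1% is excluded. Areas labeled only contralaterally can
  never pass the filter; they are listed in a `contra_only` attribute so no
  labeling disappears unaccounted.

The injected-area exclusion is deliberately one-sided. Ipsilaterally the
injected area contains the deposit and must be excluded from counting;
contralaterally the homotopic area is a genuine callosal projection and is
counted in $C$ and $H$ — it is excluded only from the contralateral *areal
distribution*, which describes the heterotopic landscape.

Presentation columns are rounded half-up to one decimal (`round_half_up()`),
matching how such tables are conventionally printed; all internal computation
and all correlations use full precision. This matters: rounding %CPN to one
decimal before correlating shifts a coefficient of −0.240 by a few
thousandths.

### Subfield injections and homotopy

The homotopy map between hemispheres is the identity on area names
(`homotopic_of()`), which makes it an involution by construction. Injection
sites, however, are often labeled at subfield granularity ("46d rostral")
while neuron records carry area-level labels ("46d"). The package resolves
this with an explicit parent map (`area_level_of()`): the homotopic
counterpart of a subfield injection is the *whole* contralateral area at the
granularity present in the records. Whether a homotopic count after a
subfield injection should instead cover only the mirror subfield cannot be
decided from area-level records; the coarser reading is the package's
convention and is stated here rather than buried in code.

Area-label matching is exact after whitespace trimming — no case folding, no
fuzzy matching. In a vocabulary where "F5a" and "F5p" are different areas,
silent fuzzy rescue is a worse failure mode than a loud error; unknown labels
raise a referential error naming the three closest known labels.

## Laminar classification

The laminar origin of a projection carries a hierarchical signal: projections
arising mainly from superficial layers (II–III) are *feedforward*, mainly
from deep layers (V–VI) *feedback*, and bilaminar origins *lateral*. The
package quantifies this as the superficial fraction
$s = n_\mathrm{sup}/(n_\mathrm{sup}+n_\mathrm{deep})$ per (case, hemisphere,
source area), with unknown-layer neurons tallied but excluded from the ratio
(`superficial_fraction()`).

The qualitative "mainly"/"more equally" criterion has no canonical numeric
boundary, so the package makes one explicit and configurable
(`classify_laminar()`): $s \ge 0.70$ is feedforward, $s \le 0.30$ feedback,
between them lateral. The defaults are symmetric and conventional for
supragranular-fraction criteria; both thresholds are closed (a projection
exactly at 0.70 is feedforward) and every output records the thresholds used.
Classification is monotone in $s$ by construction. Projections with fewer
than `min_neurons = 20` layer-assigned neurons are `indeterminate` rather
than classified from noise; the floor is configurable and guards against
over-reading sparse labeling.

`laminar_summary()` applies this per (target, source, hemisphere), tags
homotopic rows, and flags contralateral patterns that differ from the same
source's ipsilateral pattern — the cross-hemisphere comparison that makes
laminar divergence visible. Laminar analysis conventionally samples a denser
section series than areal plotting; the section filter uses modular
arithmetic on the section position (default every 300 µm, configurable
phase), so a 600 µm plotting series is simply every second laminar section.

## Cross-case statistics

Two Pearson correlations (`pearson_cor()`, two-sided t test on $n-2$ df)
serve specific inferential roles: total labeled neurons vs %CPN checks that
callosal weight is not an artifact of tracer transport efficacy, and %CPN vs
homotopic fraction checks whether callosal weight predicts its composition.

Group comparisons of callosal labeling use a negative-binomial rate-ratio
regression (`nb_rate_regression()`): contralateral count ~ region group with
$\log(\text{total})$ as exposure offset, log link, NB2 variance
$\mu + \alpha\mu^2$. Case totals differ by a factor of 30 and per-group
counts are far more variable than Poisson (the fitted $\alpha \approx 0.26$
on the bundled table), so a Poisson model would wildly overstate precision.
The dispersion is estimated by maximum likelihood via `MASS::glm.nb`
(convergence tolerance $10^{-8}$, up to 100 IRLS iterations); it can be fixed
by the caller, with $\alpha = 0$ giving the exact Poisson limit — a property
the tests exercise by verifying that rate ratios at $\alpha \to 0$ match a
Poisson fit to $10^{-6}$. All pairwise group contrasts are exponentiated into
rate ratios with Wald p-values, Benjamini–Hochberg adjusted across exactly
that pairwise set (`bh_adjust()`, validated input over `stats::p.adjust`).

Group membership for the bundled table follows the package's explicit
convention: prefrontal (9 cases), premotor — frontal motor without F1 —
(10 cases), parietal including the two weakly callosal PF cases (12 cases);
F1 and the frontal opercular injections stay out of the comparison. F1 is
kept as its own region class throughout the parcellation so this exclusion is
structural, not ad hoc. With this membership the parietal group labels CPNs
at 0.46 times the prefrontal rate and 0.54 times the premotor rate. The
corresponding Wald p-values depend on the dispersion estimator, which varies
across software; the package therefore treats the rate ratios as the stable
quantities and the p-values as estimator-dependent, asserting only their
significance pattern.

`region_summary()` reports per-group mean and range of %CPN, recomputed at
full precision from counts; presentation rounds the mean to the nearest
integer.

## The synthetic generator

`simulate_case()` draws a bilateral labeling dataset from explicit ground
truth, so every pipeline stage has a known right answer:

* the case total is negative-binomial with mean `mean_total` and dispersion
  $\alpha$ (`dispersion`, default 0.2 — the magnitude of cross-case
  overdispersion the NB regression is built for; 0 gives Poisson);
* the callosal count is binomial in the total at `pct_cpn_true`; its
  homotopic part binomial at `pct_homotopic_true`;
* heterotopic and ipsilateral neurons are multinomial over configurable areal
  weights (overdispersion thus acts on the case level with multinomial
  thinning to areas);
* each projection's neurons get a layer — unknown with rate 5% by default,
  exercising the exclusion path, else superficial with that projection's
  true s-fraction — and a uniform position on a 300 µm section grid.

Records are emitted aggregated per (section, hemisphere, area, layer), which
is statistically identical to per-neuron rows and much smaller. Each case
draws from a private RNG stream seeded by its config, leaving the caller's
RNG untouched; `paper_like_suite()` derives one stream per case from a master
seed, so the 36-case design (totals and true percentages set to the bundled
table) is reproducible case by case.

The generator emulates the *statistical* structure of charted material:
overdispersed totals, a homotopic/heterotopic mixture, laminar mixtures,
sectioned sampling. It does not emulate spatial topography within areas,
tracer-specific uptake differences, or correlated laminar structure across
sections. Tests passing on synthetic data therefore validate the counting and
inference machinery, not the anatomical realism of any particular chart.

## Validation design and problem sizes

The test suite checks three layers. Exact layer: all 36 bundled rows satisfy
total = ipsi + contra, and both derived percentage columns reproduce the
printed ones exactly after half-up rounding. Oracle layer: BH adjustment
against a hand-written step-up oracle over all 120 permutations of five
p-values; Pearson against the closed-form covariance formula to $10^{-12}$;
the NB log-likelihood against the density-based sum; label exchange inverting
rate ratios to $10^{-9}$. Recovery layer: laminar class recovery on 200
synthetic connections with designed s-fractions {0.85, 0.5, 0.15} and at
least 200 assigned neurons each (≥ 95% required; the binomial sampling noise
at these sizes puts each design several standard deviations from the nearest
boundary); %CPN unbiasedness within ±0.5 percentage points over 200
replicates at 10,000 neurons per case; and a designed rate ratio of 0.5
(12 cases per group, $\alpha = 0.3$) recovered within [0.45, 0.55] in the
median over 200 replicates. These sizes keep the full suite around ten
seconds while leaving comfortable Monte-Carlo margins.

## Known limitations

* Per-connection laminar classes from the original material cannot be
  regenerated: raw charts are unpublished, and the published class tables
  carry no counts. Laminar validation is therefore property-based on
  synthetic ground truth.
* The homotopy-of-subfields convention above is one of two defensible
  readings; users whose records carry subfield labels bilaterally can supply
  a parcellation without parent links to get mirror-subfield homotopy.
* The NB regression fits a single dispersion across groups; with 9–12 cases
  per group, group-specific dispersion is not estimable with any stability.
* Laterality indices are ratios of counts and inherit the noise of the
  smaller side; the 1% floor bounds but does not remove this.
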