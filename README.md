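# cpnquant

Quantitative analysis of interhemispheric (callosal) cortico-cortical
connectivity from retrograde tracer injections.

A retrograde tracer deposited in a cortical area labels the neurons that
project to it. Neurons labeled in the opposite hemisphere are callosal
projection neurons (CPNs); they split into the *homotopic* projection (from
the contralateral area with the same name as the injected one) and
*heterotopic* projections (from every other contralateral area). `cpnquant`
is for neuroanatomists who chart such material — here, macaque prefrontal,
premotor, frontal opercular, and parietal injections — and need the counting
and statistics done consistently:

* per-case aggregation with the standard exclusions: for ipsilateral count
  `I` (injected area excluded), contralateral count `C`, and homotopic count
  `H`, the callosal percentage `%CPN = 100·C/(I+C)` and homotopic fraction
  `100·H/C`;
* areal percentage distributions per hemisphere (injected area excluded
  ipsilaterally, homotopic area contralaterally) and per-area laterality
  indices `contra/ipsi` for areas holding > 1% of the ipsilateral labeling;
* laminar classification of each connection from its superficial-layer
  fraction `s = n_sup/(n_sup+n_deep)`: feedforward (`s ≥ 0.70`), lateral,
  or feedback (`s ≤ 0.30`), with an indeterminate class below 20 assigned
  neurons;
* cross-case statistics: Pearson correlations, per-region summaries, and a
  negative-binomial (NB2, variance `μ + αμ²`) rate-ratio regression of CPN
  counts on region group with `log(total)` exposure offset and
  Benjamini–Hochberg adjustment over the pairwise contrasts;
* a ground-truth simulator of bilateral labeling datasets (overdispersed
  totals, homotopic/heterotopic mixture, laminar mixtures, 300 µm section
  grid) so the whole pipeline is testable without unpublished raw charts.

A summary count table of 36 injection cases ships with the package
(`load_table2_fixture()`), along with the frontoparietal parcellation its
area labels resolve against (`default_parcellation()`).

## Worked example

```r
library(cpnquant)
fix <- load_table2_fixture()

connectivity_profile(fix, "64FB")
#> Case 64FB: %CPN = 25.8, homotopic = 57.7%

region_summary(fix, "premotor")
#> premotor: mean %CPN = 14 (range 8-18), n = 10

sub <- fix[fix$region %in% c("prefrontal", "premotor", "parietal"), ]
nb_rate_regression(sub$contra, sub$total,
                   factor(sub$region, levels = c("prefrontal", "premotor", "parietal")))
#> Negative-binomial rate-ratio regression (offset = log total)
#>   groups: prefrontal (n=9), premotor (n=10), parietal (n=12)
#>   dispersion alpha = 0.2636 (theta = 3.793)
#>   premotor_vs_prefrontal: RR = 0.850, p = 0.4906, p.adj = 0.4906
#>   parietal_vs_prefrontal: RR = 0.461, p = 0.0006, p.adj = 0.0019
#>   parietal_vs_premotor: RR = 0.542, p = 0.0054, p.adj = 0.0081
```

Reading the output: a quarter of the labeled input to rostral 46d in case
64FB is callosal, and 57.7% of those CPNs sit in contralateral 46d. Across
groups, premotor injections average 14% CPN. The regression compares
callosal labeling *rates* (CPNs per labeled neuron): parietal injections
label CPNs at 0.46× the prefrontal and 0.54× the premotor rate, both
significant after FDR adjustment, while prefrontal and premotor do not
differ. The premotor group is frontal motor cortex without F1; the parietal
group includes the two PF cases; F1 and opercular injections stay out of the
comparison.

The `analysis/` directory holds the narrative drivers — per-case
quantification (`01`), group statistics (`02`), synthetic end-to-end
validation (`03`), laminar patterns (`04`) — each a thin script over the
package writing its tables under `results/`:

```sh
Rscript analysis/01_quantify_cases.R
```

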