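# coccomix

Morphotype-resolved coccolith thickness, mass, and population calcite
budgets for *Emiliania huxleyi*, by Bayesian mixture deconvolution.

## The problem

Field samples of *E. huxleyi* mix several coccolith morphotypes — Type A,
"overcalcified" Type A (OA), Group B, and malformed (M) — that are often
used as visual proxies for calcification. Testing that assumption needs
per-morphotype coccolith *mass*, which no single instrument measures:
polarized light microscopy gives the thickness of every coccolith but
cannot tell most morphotypes apart, while scanning electron microscopy
classifies and counts morphotypes but measures only plan-view sizes.

`coccomix` joins the two. The pooled light-microscope thickness
distribution of a sample is modelled as a finite mixture of normals, one
component per morphotype, with the SEM counts as an informative Dirichlet
prior on the mixture weights:

```
x_i | z_i = k ~ N(mu_k, 1/tau_k)        k = 1..K morphotypes
mu_k  ~ N(m_k, 1/p0)                    empirically anchored (see vignette)
tau_k ~ Gamma(a0, b0)                   sigma_k = 1/sqrt(tau_k)
g_k   ~ Gamma(alpha_k, theta = 1),  g_k := max(g_k, 0.01),  pi = g / sum(g)
```

A compiled Gibbs sampler (3 chains, split Gelman–Rubin checks, median and
68% credible interval summaries, mean-sorting against label switching for
K ≥ 3) estimates per-morphotype mean thickness `mu_k` and spread
`sigma_k`. Closed-form estimators turn these into per-morphotype mass

```
m = pi * (l/2) * (w/2) * t * d        [um, g/cm^3 -> pg]
```

and population calcite

```
Ca = CD * m * N_cocco * 1e-6          [cells/L, pg -> ug/L]
```

The package also ships the surrounding pipeline: validated CSV I/O for
SEM/LM measurement tables, single-pass IQR outlier removal, rare-morphotype
exclusion, abundance tables with count margins of error, the descriptive
rank/t/normality tests, a seedable synthetic-data generator, and a
parameter-recovery simulation study with credible-interval coverage
scoring. See `vignettes/coccomix-methods.Rmd` for the model, the prior
calibration and its rationale, and known limitations.

## Worked example

Simulate a winter-coastal-like field sample (77% Type A, 22% Group B, a
trace of malformed coccoliths) and run the full per-sample pipeline:

```r
library(coccomix)

spec <- field_sample_spec()                 # documented field-like defaults
gen  <- simulate_field_sample(spec, seed = 7)
fit  <- fit_sample(gen$sem, gen$lm, meta = gen$meta,
                   mixture = mixture_config(profile = "desk", seed = 7))
print(fit)
```

```
sample synthetic-1: retained morphotypes A, B (excluded: M)
sample synthetic-1: removed 1 thickness outlier(s)

Morphotype abundance:
 morphotype count relative_abundance margin_of_error
          A   230            0.76667         0.04786
          B    68            0.22667         0.04738
          M     2            0.00667         0.00921

Posterior thickness summary:
 component mu_lo mu_median mu_hi sigma_median weight_median rhat_mu morphotype
         1 0.101     0.109 0.126       0.0202         0.227       1          B
         2 0.122     0.127 0.130       0.0216         0.773       1          A

Per-morphotype mass (pg):
 morphotype length_um width_um thickness_um mass_pg estimable
          B      3.12     2.58        0.109    1.88      TRUE
          A      3.37     2.78        0.127    2.53      TRUE

Calcite budget (ug/L):
   sample_id   station   month depth_m cell_density_l mass_pg TC_10 TC_23 TC_48
 synthetic-1 synthetic January      10          41003    2.42 0.994  2.29  4.77
```

Reading it: malformed coccoliths fell below the 1% abundance floor and
were excluded from the mixture; one thickness outlier was removed by the
Tukey-fence rule. The two-component fit assigns Group B a median
thickness of 0.109 um (68% CI 0.101–0.126) and Type A 0.127 um
(0.122–0.130), close to the generator's truth (0.097 and 0.131 um), with
all R-hat at 1.0. Combining posterior thickness with mean SEM sizes gives
1.88 pg (B) and 2.53 pg (A); at the sample's cell density of 41,003
cells/L the standing stock is 0.99–4.77 ug calcite per litre across the
10–48 coccoliths-per-cell range, 2.29 ug/L at the central 23.

A thin command-line wrapper with `fit`, `simulate`, and `evaluate`
subcommands is installed as `exec/coccomix`.

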