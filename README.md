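# wagglefit

Honeybee colonies allocate foragers through the waggle dance: successful
foragers advertise a resource's direction and distance on the dancefloor, and
nestmates may either follow such a dance (*recruits*) or search on their own
(*scouts*). `wagglefit` estimates how much of a colony's foraging is driven by
recruitment — its **waggle dance use** — from nothing more than the waggle-run
durations decoded from dancefloor video.

## The model

Waggle-run duration is linearly related to foraging distance. Scout trips end
at the first resource met along a search path, so their durations follow a
truncated, tapered exponential; recruit trips converge on the nearest
high-quality resources, giving a truncated, tapered Rayleigh. The dancefloor
mixes the two:

    P(x) = p * f_s(x) + (1 - p) * f_r(x)

    f_s(x) ∝ b_s a_s exp(-b_s a_s (x - m)) (1 - a_s x)+      scout trips
    f_r(x) ∝ 2π a_r² b_r x exp(-π b_r (a_r x)²) (1 - a_r x)+  recruit trips

with `m` the minimum recorded duration, `1/a` each component's maximum
duration, and `p` the fraction of scout trips. Waggle dance use is `1 - p`.
For each hive the package fits an **individual** model (`p = 1`, 2 free
parameters) and a **collective** model (`p` free in [0, 1], 5 free
parameters) by multistart Nelder–Mead maximum likelihood, selects between
them with AIC and Akaike weights, and screens both fits with a bootstrapped
two-sample Kolmogorov–Smirnov test. An agent-based foraging simulator
(`run_simulation()`) reproduces the exponential-vs-Rayleigh dichotomy that
motivates the two components, and a synthetic study generator
(`generate_study()`) produces study-scale multi-hive datasets with known
ground truth.

## Worked example

Generate a four-hive synthetic study with known scout fractions and run the
full pipeline:

```r
library(wagglefit)

study <- generate_study(study_config(n_hives = 4, per_hive_n = 300,
                                     p_by_hive = c(0.2, 0.45, 0.7, 1),
                                     site_class = c("urban", "agri-rural"),
                                     seed = 11))
report <- run_full_analysis(study, fit_settings(seed = 1), n_boot = 500, seed = 1)
print(report)
```

```
Analysis of 4 hive(s): 3 collective-selected, 1 individual-selected, 0 with no acceptable fit

  hive_id   n aic_individual aic_collective delta_aic   selected
1 hive_01 300          178.6          167.0    11.666 collective
2 hive_02 300          479.9          468.6    11.358 collective
3 hive_03 300          610.9          524.5    86.422 collective
4 hive_04 300          749.3          754.5    -5.202 individual
  waggle_dance_use gof_p_individual gof_p_collective classification
1           0.7972            0.456            0.986     collective
2           0.5307            0.172            0.560     collective
3           0.3399            0.008            0.386     collective
4           0.1268            0.636            0.904     individual
```

The three hives generated with recruitment (`p` = 0.2, 0.45, 0.7) are
selected as collective with waggle dance use estimates 0.80, 0.53 and 0.34
against the true values 0.80, 0.55 and 0.30, and for the first of them only
the collective model survives the goodness-of-fit screen. The scout-only
hive (`p` = 1) is correctly assigned to the individual model: the 3 extra
parameters of the collective model cost more AIC (penalty 6) than its
likelihood gain is worth. `plot_ccdf(study[[1]],
fits = report$comparisons$hive_01$fits)` shows the recruitment "hump" in the
complementary cumulative duration curve and both fitted models.

Field data enter the same pipeline through
`read_dance_table("dances.csv")` — a CSV with columns `hive_id`,
`duration_s` and optionally `site_class` — and `fit_pooled()` /
`pooled_summary()` compare per-hive fits against landscape-pooled fits.

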