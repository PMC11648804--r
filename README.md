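# metstab

Yield-stability analysis for multi-environment crop trials, built around
the workflow used to evaluate maize hybrids across seasons and cropping
systems (sole maize, maize+soybean, maize+sweet potato).

Plant breeders running a multi-environment trial (MET) face two linked
questions. Genotype-by-environment interaction (GEI) means the best hybrid
on average is not the best everywhere — so which hybrids combine high
yield with *stability*? And when maize is intercropped with a companion
crop, does the combination actually use land more efficiently than growing
each crop alone? `metstab` answers both with the field's standard
statistics, each implemented with tested numerical identities and a
synthetic-data generator that provides planted ground truth.

## What it computes

* **Combined ANOVA** — plot model
  `Y = μ + S + C + S×C + G + G×S + G×C + G×S×C + Rep(env) + ε`,
  with %SS per source and descriptive statistics (mean, min, max, SD, CV).
* **AMMI** — SVD of the double-centered genotype × environment means
  `D = Y − row mean − column mean + grand mean`, giving IPCA scores, and
  the **AMMI Stability Value**
  `ASV = sqrt(((SS1/SS2)·IPCA1)² + IPCA2²)` with `SS1/SS2 = λ₁²/λ₂²`
  (lower = more stable).
* **GGE biplot** — SVD of the environment-centered means, with the three
  analytic views: discriminativeness vs representativeness (environment
  vector lengths and angles to the average-environment axis),
  mean vs stability (projection on / distance from the AEA), and
  which-won-where (convex-hull sectors and mega-environments).
* **GSI** — genotype stability index `GSI = rASV + rX`, the sum of the
  stability rank and the performance rank (competition ties; lower is
  better).
* **LER** — land equivalent ratio `Σᵢ ICᵢ/Cᵢ` over component crops;
  `LER > 1` marks an intercrop as favorable.
* **Synthetic trials** — `simulate_trial()` draws from
  `Y = μ + Gᵢ + Eⱼ + Σₜ λₜ αᵢₜ γⱼₜ + rep + noise` with known effects, so
  every estimator above can be tested against what was planted.

## Worked example

```r
library(metstab)

tab <- simulate_study(seed = 42)   # 24 genotypes x (2 seasons x 3 systems) x 3 reps
combined_anova(tab, "GY")
```

```
              source  df        SS       MS        F            p   pct_SS
                 Rep  12   24.1740   2.0150       NA                1.05 %
          Season (S)   1   83.0378  83.0400  209.300  1.079e-35**   3.59 %
 Cropping System (C)   2  245.9840 123.0000  310.100  2.623e-71**  10.65 %
               S x C   2 1529.7400 764.9000 1928.000 6.438e-163**  66.21 %
        Genotype (G)  23  111.7530   4.8590   12.250   2.17e-30**   4.84 %
               G x S  23   37.3188   1.6230    4.090   7.23e-09**   1.62 %
               G x C  46   88.4746   1.9230    4.849  4.831e-17**   3.83 %
           G x S x C  46   80.4260   1.7480    4.408   4.65e-15**   3.48 %
               Error 276  109.4810   0.3967       NA                4.74 %
               Total 431 2310.3900       NA       NA              100.00 %

Mean 4.48  Min 0.00  Max 9.69  SD 2.32  CV 14.06 % (t/ha)
```

The df column (12, 1, 2, 2, 23, 23, 46, 46, 276; total 431) is the
classical layout for this design; `pct_SS` shows where the variation comes
from (here the environment terms dominate, as is typical when cropping
systems differ drastically). The stability pipeline continues:

```r
fit <- ammi(tab, "GY")             # AMMI decomposition of the cell means
st  <- gsi(rowMeans(cell_means(tab, "GY")), asv(fit))
head(as.data.frame(st)[order(st$rGSI), ], 5)
```

```
   genotype     mean rX       ASV rASV GSI rGSI
13      G13 4.813734  7 0.3096993    5  12    1
18      G18 4.639035 11 0.1785392    1  12    1
12      G12 4.913476  4 0.5842596   10  14    3
15      G15 5.221592  1 0.7357288   13  14    3
4       G04 4.572023 12 0.2803017    3  15    5
```

G13 and G18 share the best GSI: neither is the single highest-yielding
hybrid (rX 7 and 11) nor is either the most unstable — the rank sum
rewards the combination. Mega-environment structure comes from the GGE
which-won-where view:

```r
which_won_where(gge(tab, "GY"))$mega_environments
```

```
  sector vertex environments n_environments  mega
1      2    G07        C3,C5              2  TRUE
2      3    G17        C2,C4              2  TRUE
3      4    G15           C1              1 FALSE
4      5    G20           C6              1 FALSE
```

Each occupied sector's vertex genotype wins every environment in that
sector; sectors with two or more environments (`mega = TRUE`) are
candidate mega-environments for targeted hybrid recommendation.

The whole sequence — ANOVA, AMMI/ASV, GGE views, GSI, LER — can be run
from one configuration with `run_pipeline()`, or from a shell via the
`exec/metstab` script (`metstab run --config config.yml`, plus
`simulate`/`anova`/`ammi`/`gge`/`gsi`/`ler` subcommands).

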