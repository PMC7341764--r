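# snagmort

Height-structured drought mortality from single-survey forest inventories,
with snag death years dated from retention classes.

## The problem

During the 2012–2016 California drought, remote sensing showed tree
mortality rising with tree height, which was read as tall trees being
inherently more vulnerable to drought stress. But a pooled height–mortality
trend confounds two very different mechanisms: within-taxon vulnerability
changing with height, and the taxonomic make-up of the forest changing with
height. If vulnerable taxa dominate the tall classes, pooled mortality can
rise with height even while *every* taxon's own mortality falls — a
Simpson-type reversal driven purely by composition.

`snagmort` is for forest ecologists and biostatisticians who have a
single-visit inventory of standing trees (live, or dead with a foliage/twig
retention class) and want to (a) estimate drought-window mortality per
taxonomic group × height class with honest uncertainty about *when* each
snag died, and (b) decompose the pooled height trend into compositional and
within-group components.

## The model

For height class *i* and taxonomic group *t*, with *n*<sub>i,t</sub> trees
alive at the window start and *d*<sub>i,t</sub> of them dying in the
window, pooled mortality per class is

> *M*<sub>i</sub> = Σ<sub>t</sub> *d*<sub>i,t</sub> / Σ<sub>t</sub> *n*<sub>i,t</sub> = Σ<sub>t</sub> *m*<sub>i,t</sub> *p*<sub>i,t</sub>,

the composition-weighted mean of group rates *m*<sub>i,t</sub> with
proportions *p*<sub>i,t</sub> summing to 1. The chain that produces the
inputs:

1. **Allometry** — species-specific height–diameter curves assign each
   5-cm DBH class to a height class (5–15 m, 15–30 m, >30 m), thresholds
   rounded to the nearest 5-cm class.
2. **Death dating** — gamma distributions of time since death, fitted per
   calibration group × retention class to snags with known death years,
   give each surveyed snag a probability *q* = F(T*; α, β) of having died
   within the window (T* = 3 years for a 2014–2016 window surveyed in
   2016).
3. **Mortality MCMC** — a Metropolis-within-Gibbs sampler treats each
   snag's window membership as a latent indicator with prior *q*
   (conditional *q·m* / (*q·m* + 1 − *q*)), and samples each cell's logit
   mortality against the implied binomial likelihood under a uniform
   prior; 3 chains × 20,000 iterations, 5,000 burn-in, Gelman–Rubin
   checked. Start-of-window populations follow by survivorship:
   *n*<sub>2013</sub> = *n*<sub>2016</sub>/(1 − *m*), *d* =
   *n*<sub>2013</sub> − *n*<sub>2016</sub>.
4. **Decomposition** — direct standardizations recompute *M*<sub>i</sub>
   under a constant reference composition, or with one group's mortality
   held at its pooled value, and a trend classifier flags
   composition-driven reversals.

A synthetic-data module generates inventories and calibration sets with the
full latent structure (true death years, true cell mortalities), so the
whole chain is testable without any data download.

## Worked example

The two-species teaching scenario — both species' mortality *falls* with
height, but the vulnerable species B rises from 10% to 90% of trees:

```r
library(snagmort)
tab <- scenario_preset("shared-decline")
unique(tab[, c("height_class", "M")])$M
#> [1] 0.33 0.35 0.37          # pooled mortality rises with height...
ref <- setNames(c(0.5, 0.5), c("A", "B"))
standardize_composition(tab, ref)$M_star
#> [1] 0.45 0.35 0.25          # ...but falls under constant composition
detect_simpson_reversal(tab)$reversal
#> [1] TRUE
```

The full pipeline on the bundled synthetic landscape is driven by the
numbered scripts in `analysis/` (simulate → date snags → fit mortality →
decompose → scenarios), which write their tables under `results/`. Stage 3
prints the per-cell posterior summary, e.g. (seed 20160801):

```
Cells: 9 | max Gelman-Rubin: 1.0004
  group             height_class n_2016   mean    lo95   hi95 n_2013      d
  angiosperm        5-15m          1506 0.0509 0.0397  0.0631 1587.   80.7
  non_pinus_conifer 5-15m           668 0.213  0.184   0.243   849.  181.
  pinus             >30m             87 0.530  0.456   0.603   185.   98.1
  ...
```

and stage 4 the decomposition:

```
Observed pooled M (short/mid/tall): 0.109 / 0.14 / 0.208
Constant-composition M*:            0.133 / 0.123 / 0.12
Constant-Pinus-mortality M*:        0.121 / 0.145 / 0.156
```

Read: observed pooled mortality nearly doubles from the shortest to the
tallest class, but with the whole-population composition imposed on every
class it would have *declined* slightly — the height trend is carried by
composition, with a secondary contribution from the rising *Pinus*
gradient (third line). Point estimates sit somewhat below the generating
cell mortalities: the plug-in *q* shrinks ambiguous snags, a known
limitation discussed in the methods vignette
(`vignettes/height-mortality-decomposition.Rmd`).

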