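# flyvis

Comparative morphometrics and adaptive evolution of the peripheral visual
and antennal sensory systems of miltogrammine flesh flies
(Diptera: Sarcophagidae).

Females of many miltogrammine species locate the nests of their bee and
wasp hosts by trailing a returning host in "satellite" flight (SAT), a
finely coordinated pursuit that plausibly selects for better vision;
other species find hosts by necrophagy, hole searching or
stalking/lurking (NON-SAT). `flyvis` provides the full analysis chain for
asking whether host-finding strategy shaped eye and antennal morphology
across such a clade, for anyone working with species-level morphometric
tables and an ultrametric phylogeny:

* **Morphometrics** — derives analysis traits from linear SEM
  measurements: eye surface area by a spherical-shell approximation
  (`E_area = pi (L^2 + W^2)`, `L` the mean lateral chord, `W` the anterior
  width), hexagonal ommatidial facet area (`2.598 r^2`), real-valued
  ommatidium counts (`E_area / OM_area`), the global interommatidial
  angle (`delta_gamma = sqrt(K / OM_number)`, `K = 23818 deg^2`), dry body
  mass from head width (`0.655 H^2.526`, H in mm), and per-specimen
  derivation followed by species means with standard errors.
* **Regime mapping** — Fitch/Sankoff maximum parsimony for a binary
  host-finding character, with exhaustive enumeration of *all*
  minimum-change reconstructions and per-node ambiguity summaries.
* **OU adaptive regression** — Hansen-type Ornstein-Uhlenbeck models
  `dy = -alpha (y - theta) dt + sigma dB` on the painted tree,
  parametrized by the phylogenetic half-life `t_1/2 = ln(2)/alpha` (units
  of tree depth) and stationary variance `v_y = sigma^2/(2 alpha)`. Four
  variants per trait (intercept-only, body-size predictor, regime optima,
  regime + body size), GLS estimation of optimal and evolutionary slopes
  (related by `rho(alpha T) = 1 - (1 - e^{-alpha T})/(alpha T)`),
  2-logL support regions, phylogenetic R^2 and AICc model selection with
  the Delta < 4 support convention. The white-noise (`t_1/2 = 0`) and
  Brownian-motion (`t_1/2 = Inf`) limits are exact analytic endpoints.
* **Group statistics** — pooled two-sample t-tests, regime contrast
  ratios, OLS regressions and size-relative Pearson correlations between
  eye and antennal traits.
* **Synthetic data** — seeded pure-birth trees of depth 1, clade or
  Markov regime paintings, exact Brownian/OU tip simulation (plus an
  Euler-Maruyama reference path for optima tracking a Brownian
  predictor), and a specimen-level measurement layer, so the whole
  pipeline is testable without any external data.

The species tables of the motivating 18-species study (10 SAT, 8 NON-SAT)
are packaged verbatim as fixtures (`builtin_fixture()`).

## Worked example

```r
library(flyvis)

t1 <- builtin_fixture("table1")   # head width + visual traits, 18 species
rg <- builtin_fixture("regimes")  # SAT / NON_SAT assignment

group_summary(t1, rg, "E_area")[, c("ratio", "ratio_direction", "t", "df", "p")]
#>      ratio ratio_direction        t df           p
#> 1 1.741648     SAT/NON_SAT 3.738955 16 0.001788993
```

Satellite species have 1.74x the eye area of non-satellite species, and
the pooled t-test on species means is strongly significant. The same
fixtures give ommatidium-count ratio 1.48, facet-area ratio 1.17 and an
interommatidial-angle contrast of t = 3.96 (SAT eyes resolve finer
angles).

The phylogenetic machinery runs identically on packaged or simulated
data; the study tree is not publicly deposited, so here is the full OU
comparison on a simulated 18-tip replica:

```r
tree <- simulate_tree(18, seed = 99)
tree$tip.label <- rg$species_id
paintings <- enumerate_mp_reconstructions(tree, rg)
res <- fit_ou_models(tree, t1, paintings[[1]], "E_area")
res$comparison[, c("predictors", "t_half", "R2_phylo", "AICc", "delta", "best")]
#>        predictors      t_half      R2_phylo      AICc    delta  best
#> none         none 0.003195769 -2.220446e-16 23.132059 31.72315 FALSE
#> bm             bm 0.039134208  7.631180e-01  4.006725 12.59782 FALSE
#> regime     regime 0.000000000  4.941821e-01 14.274165 22.86526 FALSE
#> both         both 0.000000000  8.858018e-01 -8.591096  0.00000  TRUE
```

Each row is one model variant: its maximum-likelihood half-life (in units
of tree depth; small values mean fast adaptation), phylogenetic R^2, AICc
and distance `delta` from the best model. On this simulated topology the
regime + body-size model is the single best supported model
(`delta < 4` for no other), explaining 89% of the eye-area variation
with an essentially instantaneous half-life. `run_pipeline()` wraps all
stages (contrasts, parsimony, OU blocks, reports) behind one
YAML-configurable call.

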