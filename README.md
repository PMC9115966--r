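# fluxgsea

Radiogenomic analysis of dynamic [18F]-fluorodeoxyglucose (FDG) PET in
solid tumours: tracer-kinetic modelling of tumour time-activity curves
and gene-set enrichment analysis of the correlations between the
resulting imaging measures and gene expression.

In dynamic FDG-PET the tumour time-activity curve TAC(t) is driven by
the arterial input function AIF(t) through

    TAC(t) = K1 * ∫ AIF(s) R(t − s) ds + Vb * AIF(t)

where R(t) is the residue function (fraction of delivered tracer still
in tissue; R(0) = 1) and Vb the fractional blood volume. The package
fits this model in five forms — the Patlak plot, irreversible and
reversible two-tissue compartment models (2C3K, 2C4K), an irreversible
three-tissue model (3C5K) and a nonparametric B-spline residue model —
by weighted least squares with the frame weights

    w_i = (ΔT_i / A_i) * exp(−λ t_i),      λ = ln 2 / 109.77 min⁻¹,

and derives flux-constants, the rate of irreversible FDG trapping per
unit steady blood concentration (2C3K: k_flux = K1·k3/(k2+k3); Patlak:
the late-time slope K; reversible/spline models: K1·R(T_scan)), plus
static uptake measures SUV = C_tumour/(dose/weight) and TBR =
C_tumour/C_blood. Model assessment uses leave-one-frame-out
cross-validation, the Wald–Wolfowitz runs test on residual signs and
profile-likelihood 1-SD uncertainties with the dof/WSS scale factor.

On the genomic side, genes are ranked by Pearson or Spearman
correlation with an imaging measure (random tie-breaking under a
dedicated seed) and gene sets scored with the weighted running-sum
enrichment statistic against gene-wise permutation nulls; pathways are
flagged at the Bonferroni-style 0.035/N threshold and summarised through
normalised enrichment scores, leading-edge overlaps, permuted-phenotype
false-positive studies and bootstrap comparisons of per-measure pathway
counts. A seeded synthetic-cohort generator (AIFs, TACs, static uptake
inputs, expression matrices with planted pathway–imaging correlations)
replaces patient data, so the whole pipeline is testable offline.

Who it is for: imaging scientists comparing kinetic analyses of dynamic
PET, and computational biologists linking imaging phenotypes to
transcriptomics who need the full inference machinery (permutation
nulls, false-positive calibration, bootstrap comparisons) in one
reproducible, scriptable package.

## A worked example

Simulate one tumour, fit the irreversible two-tissue model, and compare
three routes to the flux-constant:

```r
library(fluxgsea)
sched <- makePaperSchedule()
sched
#> FrameSchedule: 40 frames, 45.0 min acquisition, Tscan 44.5 min post-injection
#>   frames: 1x30s, 12x5s, 6x10s, 5x30s, 10x60s, 6x300s

aif <- aifParams(delay = 0.4, A1 = 400, A2 = 6, A3 = 3,
                 mu1 = 4, mu2 = 0.12, mu3 = 0.01)
truth <- c(K1 = 0.12, k2 = 0.35, k3 = 0.07, Vb = 0.06)
fluxConstant("2C3K", truth)         # ground truth: K1 k3/(k2+k3)
#> [1] 0.02

tac <- simulateTac("2C3K", truth, aif, sched, seed = 7, noiseScale = 1.5)
fit <- fitCompartment("2C3K", tac, aif, sched, seed = 1)
fit
#> KineticFit [2C3K]: kflux 0.0198 /min, wRSS 49.75
#>    K1=0.2079, k2=0.5905, k3=0.0622, Vb=0.02097

patlakFit(tac, aif, sched, tStar = 10)@kflux
#> [1] 0.01865176

profileUncertainty(fit, tac, parameters = "kflux")
#>   parameter   estimate      lower      upper    halfWidth ...
#> 1     kflux 0.01981022 0.01920429 0.02040625 0.0006009792
```

The individual micro-parameters land far from truth (K1 fitted 0.21 vs
0.12) while the flux-constant they combine into is recovered to 1%
with a tight profile interval — the precision ordering the analysis is
built around.

Now a 30-patient cohort with a pathway planted at correlation 0.8 with
the true flux, analysed through Patlak K:

```r
co <- simulateCohort(nPatients = 30, seed = 11)
pk <- vapply(seq_len(30), function(i)
  patlakFit(co$curves[[i]]$tac, co$aifParams[[i]], sched)@kflux, 1)
round(cor(pk, co$truth$kflux), 3)   # fitted Patlak K tracks the truth
#> [1] 0.994

ids <- sprintf("G%05d", 1:2000)
spec <- expressionSpec(nGenes = 2000, nPatients = 30,
  planted = list(list(name = "GLYCOLYSIS_LIKE", genes = ids[1:50],
                      rho = 0.8, measure = "kflux")), seed = 12)
expr <- simulateExpression(spec, list(kflux = pk))
sets <- syntheticCollection(spec, nNullSets = 99, nullSetSize = 40, seed = 13)
res <- gseaRun(expr$matrix, pk, sets, method = "pearson",
               nPerm = 10000, seed = 14)
subset(res, significant, select = c(pathway, size, ES, NES, pval))
#>           pathway size ES      NES         pval
#> 1 GLYCOLYSIS_LIKE   50  1 3.502875 0.0001409046
attr(res, "threshold")              # 0.035 / 100 gene sets
#> [1] 0.00035
```

The planted pathway is the only one flagged at the 0.035/N threshold:
its permutation p-value (1.4e-4, against 10,000 gene-wise permutations)
falls below 3.5e-4 while the 99 null sets stay above it.

The end-to-end pipeline — simulate, fit AIFs and all kinetic models,
derive measures, run GSEA per measure, emit the pathway-by-measure
association grid and cohort statistics — is one call,
`runAll(config)`, driven by a YAML-able configuration with a single
master seed; rerunning a configuration reproduces every numeric table
byte for byte. `inst/scripts/run-pipeline.R` wraps it for shell use.

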