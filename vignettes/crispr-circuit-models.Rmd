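---
title: "Quantitative models for dCas9-based genetic circuits"
author: "crisprCircuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative models for dCas9-based genetic circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprCircuits)
```

# Scope and scientific background

CRISPR-interference (CRISPRi) logic gates use a catalytically dead Cas9
(dCas9, or an operator-assisted fusion variant such as dCas9 fused to the
TetR-family repressor PhlF) as a programmable transcriptional repressor:
a small guide RNA (sgRNA) directs the protein to a promoter, where
binding sterically blocks RNA polymerase. Because sgRNA:promoter pairs
are cheap to design and largely orthogonal, they are attractive as a
large regulator set for synthetic genetic circuits — but every gate draws
on the *same* finite pool of dCas9 protein, so gates loaded in parallel
interfere with each other through resource competition (retroactivity).

This package implements the quantitative layer of that engineering
problem:

1. **Gate characterization** — fitting a repressing Hill response
   function to measured input/output promoter activities
   (`fitHill()`, `gateSummary()`).
2. **Cascade prediction** — composing fitted gates layer by layer to
   predict multi-gate circuits (`composeCascade()`,
   `predictCascadeCurve()`).
3. **Resource sharing** — a mass-action model of a conserved dCas9 pool
   titrated by competing sgRNAs: ODE dynamics, steady-state closed
   forms, fitting to fold-repression-versus-competitor-count data, and a
   calculator for how many co-expressed sgRNAs a circuit tolerates
   (`simulateSharing()`, `fitSharing()`, `minSgRNAsBelowThreshold()`).
4. **Measurement reduction** — flow-cytometry summary statistics and
   immunoblot standard-curve quantification of molecules per cell
   (`summarizeEvents()`, `quantifyBlot()`).
5. **ATP accounting** — the per-protein energetic cost of a regulator
   (`proteinAtpCost()`).
6. **Synthetic data** — seeded generators with known ground truth for
   every stage (`genGateCurves()` and friends), which are the backbone
   of the test suite.

# The gate response model

A transcriptional NOT gate maps input promoter activity $x$ (arbitrary
fluorescence units, au) to output promoter activity

$$y = y_{\min} + (y_{\max} - y_{\min})\,\frac{K^n}{x^n + K^n},$$

with threshold $K$ (input at half-maximal response), cooperativity $n$,
and output range $[y_{\min}, y_{\max}]$. The implementation evaluates
the algebraically identical form $y_{\min} + (y_{\max} -
y_{\min})/(1 + (x/K)^n)$, which is exact at $x = 0$ and immune to
overflow of $x^n$ at large inputs. Useful identities: $y(0) = y_{\max}$,
$y(K) = (y_{\max}+y_{\min})/2$ exactly, and $y$ is monotone
non-increasing.

```{r hill}
rf <- ResponseFunction(yMin = 2, yMax = 100, K = 10, n = 1.6)
evalHill(rf, c(0, 10, 1e6))
gateSummary(rf)$dynamicRange
```

## Fitting choices

* **Residual scale.** Residuals are minimized on $\log y$ by default
  (`residualScale = "log"`); fluorescence spans decades and every gate
  metric is a ratio, so log residuals equalize *relative* error across
  the curve. A linear scale is exposed for users whose noise is
  additive.
* **Bounds and start values.** Bounded Levenberg–Marquardt
  (`minpack.lm::nlsLM`) with $y_{\min} \ge 0$, $y_{\max} \le 10\times$
  the maximum observation, $n \in (0.1, 10]$, and $K$ within the
  observed input range $\times\,[0.01, 100]$. Initialization is
  deterministic ($y_{\max}$ = max observed, $y_{\min}$ = min observed,
  $K$ = geometric midpoint of the positive inputs, $n = 1$), so a given
  dataset always produces the same fit.
* **Replicates** enter as pooled residuals rather than being averaged
  first, preserving their weight in the objective.
* **Degenerate inputs.** Fewer than four distinct input levels, flat
  output (no repression signal), and non-positive outputs under log
  residuals are rejected with errors naming the defect, rather than
  returning a boundary fit.
* An uninduced point at $x = 0$ is legal; the Hill form needs no log
  transform of $x$ itself.

# Cascade composition

Layered NOT gates are predicted by plain functional composition
$f_L \circ \cdots \circ f_1$: the output activity of one layer is fed
directly, in the same arbitrary units, as the input of the next. This is
a *units assumption* — it is justified when all promoters are
characterized against the same reporter in the same context, and it is
deliberately not corrected for resource loading (the sharing model
below quantifies that separately, and divergence between composed
prediction and measurement at deep stacks is a finding, not a bug).

Two structural properties follow immediately and are enforced by tests:
the **parity law** (a stack of $k$ repressors is non-increasing for odd
$k$, non-decreasing for even $k$) and **range containment** (output
always lies within the final layer's $[y_{\min}, y_{\max}]$).

When the circuit input is an inducible promoter, a separately measured
inducer-to-activity transfer table maps inducer concentration onto the
first layer's input axis. Interpolation is monotone piecewise-linear in
log-inducer space; an explicit zero-inducer row is kept as a floor point
one decade below the smallest positive inducer, and queries outside the
tabulated range are refused rather than extrapolated.

# The resource-sharing model

The total dCas9 pool $C_{TOT}$ is conserved between free protein $C_F$
and sgRNA::dCas9 complexes $C_{s_i}$:
$C_{TOT} = C_F + \sum_i C_{s_i}$. Each free sgRNA $s_i$ is transcribed
at rate $\alpha_i$ (M/s), degrades at $\delta_s$ (1/s), and binds free
dCas9 with on/off rates $k_{on}, k_{off}$:

$$\frac{ds_i}{dt} = \alpha_i - \delta_s s_i - k_{on} C_F s_i
  + k_{off} C_{s_i}, \qquad
\frac{dC_{s_i}}{dt} = k_{on} C_F s_i - k_{off} C_{s_i}, \qquad
\frac{dC_F}{dt} = -\sum_i k_{on} C_F s_i + \sum_i k_{off} C_{s_i}.$$

The sum of the $C_F$ and $C_{s_i}$ derivatives is identically zero, so
conservation holds *by construction*; the integrator (`deSolve::lsoda`,
relative tolerance $10^{-9}$, absolute tolerance
$10^{-12} \cdot C_{TOT}$) merely has to not spoil it, and trajectories
are required to keep relative drift below $10^{-6}$. Complexes neither
degrade nor dilute in this model; growth dilution, if wanted, must be
folded into $\delta_s$.

At steady state $s_i = \alpha_i/\delta_s$, and with association
constant $K_1 = k_{on}/k_{off}$ and the composite
$\beta = \delta_s/K_1$ (units M/s),

$$C_{s_1} = \frac{\alpha_1 C_{TOT}}{\beta + \alpha_1 + N\,\alpha_x}$$

for one reporter-targeting sgRNA plus $N$ competing sgRNAs each
transcribed at $\alpha_x$. The competitors are assumed to have no DNA
targets of their own, so no promoter-sequestration term appears.
Fold-repression of the targeted promoter follows a quasi-equilibrium
Shea–Ackers occupancy form

$$\mathrm{fold}(N) = 1 + \left(\frac{C_{s_1}}{K}\right)^{n},$$

with promoter dissociation constant $K$ and occupancy cooperativity
$n$. The general multi-sgRNA steady state
$C_{s_i} = \alpha_i C_{TOT}/(\beta + \sum_j \alpha_j)$ is derived from
the same algebra (the two-sgRNA case is its exact specialization, which
the tests assert), so the $N$-competitor formula above is the
equal-rates instance of the closed form, not an extra approximation.

```{r sharing}
m <- SharingModel(cTot = 1e-6, alpha1 = 7.6e-12, alphaX = 2.3e-11,
                  beta = 3.0e-11, kProm = 1.7e-8, nHill = 0.9)
m58 <- calibrateCtot(m, 58)       # pool sized so a lone gate gives 58-fold
foldVsN(m58, c(0, 4, 8, 16))
minSgRNAsBelowThreshold(m58, 10)  # competitors tolerated above 10-fold
```

## What fold-versus-N data can and cannot identify

Write $R = C_{TOT}/K$, $b = \beta/\alpha_1$, $x = \alpha_x/\alpha_1$.
Then

$$\mathrm{fold}(N) = 1 + \left(\frac{R}{1 + b + N x}\right)^{n}
 = 1 + \left(\frac{q}{1 + p N}\right)^{n},
 \qquad q = \frac{R}{1+b},\; p = \frac{x}{1+b}.$$

The family is invariant under
$(R, b, x) \mapsto (\lambda R,\; \lambda(1+b) - 1,\; \lambda x)$ for any
$\lambda > 0$: only $(q, p, n)$ are identifiable from fold-versus-$N$
measurements. Fixing the rate *unit* (say $\alpha_1$) does **not**
break this ridge, because the ridge lives in the dimensionless ratios.
`fitSharing()` therefore estimates $(q, p, n)$ — a fully identifiable
parameterization — and reconstructs a conventional full parameter
vector only under an explicit *anchoring convention*: the user supplies
$b = \beta/\alpha_1$ (default taken from the dCas9–PhlF
characterization, $3.0\times10^{-11} / 7.6\times10^{-12} \approx 3.95$)
together with fixed $\alpha_1$ and $K$, giving
$x = p(1+b)$ and $R = q(1+b)$. `identifiableCombos()` reports both
blocks for any model, and the test suite asserts that models related by
the ridge transformation predict identical data.

A second, statistical caveat follows from the same algebra. Along the
fitted ridge the solo condition pins $n \log q$ much more tightly than
$n$ and $\log q$ separately, so estimation errors obey
$\delta \log q \approx -\log q \cdot \delta n / n$. With a solo
repression near 60-fold, $\log q \approx 4.5$: a few percent
uncertainty in the cooperativity amplifies to several tens of percent
in $q$ (hence in $C_{TOT}/K$), and similarly, though less strongly, in
$p$. This is a property of the experimental design (competitor counts
up to ~16, multiplicative noise at the few-percent-to-10% level, a few
replicates), not of the optimizer: the package's estimator sits at the
Cramér–Rao bound for this design within measurement error. Users who
need the concentration-scale combinations to better than a few tens of
percent should add an independent constraint (e.g. a measured pool size
from the blot module, converted with `moleculesToMolar()`) rather than
more replicates of the same design. The cooperativity itself is
recovered far more precisely.

## Threshold calculator

`minSgRNAsBelowThreshold()` scans $N = 0, 1, 2, \dots$ and returns the
first count whose predicted fold-repression falls *strictly* below the
threshold; termination is guaranteed because $\mathrm{fold}(N) \to 1$.
"Below" is a strict inequality by convention. Because the pool size
used in published fold-versus-$N$ fits is generally not reported,
`calibrateCtot()` sizes the pool from a measured solo repression
instead; the crossing count then responds monotonically to the pool
size (never earlier with a larger pool) and to the competitor
transcription ratio $\alpha_x/\alpha_1$ (always earlier when
competitors transcribe faster), both of which are asserted in tests.

# Measurement reduction

**Cytometry.** Samples are summarized by the geometric mean
$\exp(\mathrm{mean}(\log \mathrm{events}))$, the natural statistic for
log-normal event clouds. Autofluorescence is subtracted *on geometric
means*, not per event; negative differences clip to a configurable
floor (default 0) and downstream ratios treat 0 as below detection and
raise an error instead of emitting infinities. Non-positive events
(possible after compensation) are dropped with a count by default, or
rejected under the `"error"` policy. Fold-repression is
uninduced/induced; ±sgRNA fold-change is without/with. FCS parsing is
out of scope — events arrive as CSV, exactly the format the generator
emits.

**Immunoblot.** The standard curve is ordinary least squares with a
free intercept (straight-line interpolation with an offset absorbs
membrane background; the data decide whether the intercept is near
zero). Band intensities convert to amounts by inverting the line;
out-of-range intensities are flagged as extrapolation rather than
silently trusted, and negative inverted amounts clip to zero with a
flag. Molecules per cell follow Avogadro bookkeeping through the molar
mass, the fraction of the lysate loaded in the lane, and the cell count
the lysate represents. Molar masses are user inputs. The
molecules-to-molar conversion assumes a 1 fL cell volume by default —
an explicit, configurable assumption, since copy numbers alone carry no
volume.

# ATP accounting

The per-protein budget is
$$\mathrm{cost} = \frac{n_{aa} \cdot c_{mRNA}}{\text{proteins per mRNA}}
 + c_{aa} + c_{transl} \cdot n_{aa},$$
with defaults of 6 ATP per codon of message, 30 proteins per mRNA, and
4 ATP per peptide bond; the amino-acid synthesis term $c_{aa}$ is
signed (some compositions are net ATP producers) and can be supplied
directly or summed from a per-residue table with
`aaNetCostFromComposition()`. The codon count is taken as the protein
length — the convention under which a 207-residue repressor has a
$207 \times 6 = 1242$ ATP message. Full precision is carried
internally ($1242/30 = 41.4$); `roundIntermediates = TRUE` reproduces
display-rounded intermediate values (41) and leads to the same rounded
total:

```{r atp}
proteinAtpCost(costInputs(207, aaSynthesisNetCost = -307))$totalRounded
```

# The synthetic-data generators

The generators are first-class, contract-tested code, not fixtures:
`(ground truth, seed) → data`, and each paired analysis stage must
invert them within stated tolerance. Defaults encode the study
conditions the package models:

* Gate curves: 15 log-spaced inputs over $K \times [10^{-2}, 10^{2}]$,
  3 replicates, multiplicative log-normal noise (CV 10% in noisy
  tests); library mode draws 30 gates with $n \sim U[1.3, 1.8]$ and
  dynamic ranges log-normal around 47-fold.
* Competition data: competitor counts $\{0,1,2,4,7,10,13,16\}$, truth
  rates $\beta = 3.0\times10^{-11}$, $\alpha_1 = 7.6\times10^{-12}$,
  $\alpha_x = 2.3\times10^{-11}$ M/s, $K = 1.7\times10^{-8}$ M,
  $n = 0.9$, pool calibrated to a 58-fold solo repression; noisy values
  floor at 1.
* Blot: linear intensity truth (slope 5 au/ng, intercept 2 au),
  standards at 5–80 ng, a lane consistent with 9600 molecules/cell of a
  160 kDa protein, densitometry noise CV 2% in noisy tests.
* Events: log-normal clouds ($\sigma_{\log} = 0.8$) at an
  autofluorescence background of 50 au, with signal strains offset on
  the geometric-mean scale; $10^5$ events per sample where sampling
  error matters.

The noise model is multiplicative log-normal everywhere because every
downstream metric is a ratio. What the generators deliberately do *not*
emulate: instrument saturation, gating artifacts, day effects between
replicates, promoter-context (roadblock) effects in cascades, and blot
matrix effects. Passing round-trip tests therefore demonstrates
correctness of the estimators under the stated noise model, not
robustness to every failure mode of real data.

# Numerical conventions and problem sizes

Fits use bounded Levenberg–Marquardt with deterministic initialization
(identical inputs give identical outputs); the competition fit seeds
itself from the linearization $1/(\mathrm{fold}-1)$ versus $N$ with
floored points excluded. ODE work uses `lsoda` at the tolerances given
above; steady-state comparisons integrate to $\sim 2000$ relaxation
times of the slowest first-order process. The test suite exercises 50
random kinetic parameter sets for the ODE/closed-form equivalence, 100
seeded trials for each stochastic recovery statistic, and dense
300-point grids for monotonicity properties — sizes chosen so the whole
suite settles the properties it claims while remaining quick to run on
a laptop. All stochastic tests consume explicit seeds.

# Known limitations

* Composition assumes a shared activity unit across layers; gates
  characterized against different reporters need external rescaling.
* The sharing model omits promoter-bound complex accounting, stochastic
  (SSA) simulation, and growth-coupled dilution.
* The concentration-scale identifiable combinations of the sharing
  model are weakly determined by fold-versus-$N$ data alone (see the
  identifiability section); treat reconstructed $C_{TOT}/K$ values as
  order-of-magnitude unless anchored by an independent pool
  measurement.
* The blot module starts from densitometry numbers; image processing is
  upstream and out of scope.
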