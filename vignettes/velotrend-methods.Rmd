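---
title: "Transcription kinetics, trend anomalies and promoter targets: the velotrend model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcription kinetics, trend anomalies and promoter targets: the velotrend model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

velotrend studies how the loss of a transcriptional regulator stalls a
differentiation trajectory, using only spliced and unspliced single-cell
counts from a wild-type (WT) and a knockout-like (KO) sample plus the
regulator's genomic binding intervals. This vignette documents the model,
the tunable parameters, the numerical choices, and what the synthetic
data generator does and does not emulate.

## The two-state kinetic model

Each gene follows the standard transcription/splicing/degradation system

$$\frac{du}{dt} = \alpha(t) - \beta u, \qquad
  \frac{ds}{dt} = \beta u - \gamma s,$$

where $u$ and $s$ are nascent (unspliced) and mature (spliced) mRNA
abundances, $\alpha(t)$ switches between an ON rate $\alpha$ and 0 at a
switch time, $\beta$ is the splicing rate and $\gamma$ the degradation
rate. Within a phase of constant $\alpha$ the system has the closed form
implemented in `kinetics_phase()`; it requires $\beta \neq \gamma$ (the
equal-rate limit needs a different algebraic form, and is rejected with
an explicit message rather than silently regularized). Trajectories are
chained across the switch so they are continuous.

Gene classes: *repression* genes start at the ON steady state
$(\alpha/\beta,\ \alpha/\gamma)$ and switch OFF during the trajectory, so
their nascent signal declines; *induction* genes start silent and switch
ON, so it rises; *steady* genes transcribe constantly. These are the
trend classes the anomaly test later refers to.

## Fitting: alternating least squares with a fixed splicing gauge

`fit_gene_kinetics()` fits the ON-then-OFF curve to each gene's
kNN-smoothed $(M_u, M_s)$ profile by alternating

1. **assignment** — every cell gets the latent time minimizing the
   variance-scaled squared distance to the curve, over a 200-point grid
   refined by local quadratic interpolation of the distance profile (a
   closed-form vertex step on the three neighbouring grid points; a
   per-cell golden-section search would cost one optimizer call per cell
   per iteration for no measurable accuracy gain at the noise levels
   considered here, since earlier continuous assignments are retained
   wherever the new grid is worse);
2. **update** — $(\gamma, t_{\mathrm{switch}})$ by Nelder–Mead least
   squares with $\alpha$ profiled out exactly (the curve is linear in
   $\alpha$ for a zero initial condition).

Both steps can only lower the objective, so it is non-increasing — an
invariant the tests assert per iteration. $\beta$ is fixed to 1: the
phase portrait identifies rates only up to a common rescaling of time,
so the fitted $\gamma$ estimates $\gamma/\beta$ and latent times are in
units of $1/\beta$. Two starts of $t_{\mathrm{switch}}$ (small, and past
the saturation time) guard against the rising-arc/switching-arc
ambiguity; each is probed for two iterations and the better one is run
out (at most `max_iter` = 12 by default, relative tolerance `1e-5`).

The **fit likelihood** rescales the mean Gaussian log-density of the
residuals, with the data's own spread as the unit of scale, to $[0,1]$:
$\exp(-\tfrac{1}{2}(\overline{r_u^2}/\mathrm{sd}(M_u)^2 +
\overline{r_s^2}/\mathrm{sd}(M_s)^2))$. A perfect fit scores 1, a fit no
better than a constant about $e^{-1}$, and any valid fit scores strictly
above 0 — so the driver rule "likelihood > 0" admits every
non-degenerate gene, and the threshold is exposed as a parameter for
stricter choices (at 0.3 the steady genes of the simulation are still
admitted; at 0.9 they mostly are not). All-zero genes, or genes with
signal in fewer than 20 cells, are invalid with likelihood 0.

## Inferred cell time

Latent times are per-gene quantities in each gene's own $1/\beta$ gauge.
`inferred_cell_time()` min-max scales each contributing gene's times to
$[0,1]$ and averages them per cell. Contributing genes are the valid
fits at or above the median fit likelihood (quantile configurable). Two
deliberate choices:

* **Mean, not median, across genes.** With counts of a few molecules the
  per-gene projected time is weakly informative, and genes that are
  silent in a sample contribute a neutral 0.5; the median of such votes
  carries almost no signal, while the mean pools it. The median remains
  available (`aggregate = "median"`).
* **The KO sample is ordered by projection onto the WT-fitted curves**
  (`project_latent_time()`), not by its own fits: a stalled sample
  concentrates most of its cells in one region of expression space and
  its own fits are dominated by that blob. Projection uses unsmoothed
  size-normalized counts, because kNN smoothing leaks neighbouring
  states into the arrested cells' profiles.

## Velocity, transition chain, terminal states, cluster graph

Velocity is $v = \beta M_u - \gamma M_s$ per gene ($\beta = 1$ gauge),
zero exactly on the fitted steady-state line. In the two-sample
workflow the KO field uses the WT-fitted rates (the reference
manifold), and the field is restricted to genes at or above the median
fit likelihood: a gene whose dynamics the fit cannot resolve gets an
essentially arbitrary $\gamma$, and the resulting constant velocity
component — shared across all cells — can drown the genuine signal in
the transition kernel. The cell–cell transition
matrix puts weight $\exp(\cos(v_i, s_j - s_i)/\tau)$ on each kNN edge
(kernel scale $\tau = 0.1$ by default; self-loops excluded unless a row
would be empty; zero-velocity cells transition uniformly). Terminal
scores are the stationary distribution of this Markov chain (power
iteration on the transpose, tolerance $10^{-10}$), averaged per cluster:
the cluster where the random walk accumulates is the trajectory's end
state. The cluster graph reports, per cluster pair, the observed number
of inter-cluster kNN edges over the count expected under random edge
placement, plus the net velocity flux for direction.

## The trend-anomaly rule

For each driver gene, the unspliced series of cells sorted by inferred
cell time is tested in both samples with the Mann–Kendall statistic
($S$, tie-corrected variance, normal approximation with continuity
correction; series shorter than 8 are flagged untestable), and an OLS
slope is taken over positions scaled to $[0,1]$. A gene is **abnormal**
iff the WT trend is significant ($p < 0.01$) and either the Kendall
score changes sign between samples or
$|\text{slope}_{WT}|/\max(|\text{slope}_{KO}|, \varepsilon) > 4$
($\varepsilon = 10^{-6}$ times the WT value range). Abnormal repression
drivers are `repression_anomaly`, abnormal induction drivers
`induction_anomaly`, everything else `unchanged`. Open choices the
procedure exposes: which sample's $p$ gates the rule (WT by default —
the WT series establishes the trend the KO may deviate from; `ko` and
`both` available), and whether "the trend changes" means sign reversal
(default) or loss of significance.

The series values are **size-normalized, unsmoothed** unspliced counts.
Smoothed moments would be the more obvious choice, but neighbour-shared
smoothing autocorrelates adjacent cells and inflates the Mann–Kendall
significance far beyond its nominal level (with 200 cells and 30
neighbours, about two thirds of *steady* genes reach $p < 0.01$ on
smoothed series, versus a controlled rate on raw series); smoothed
values can still be passed to `trend_calls()` explicitly.

No multiple-testing correction is applied across genes, matching the
procedure the rule comes from.

## Peak annotation and the motif grammar

Peaks are categorized by their midpoint with precedence proximal
promoter (within ±500 bp of a TSS, strand-oriented, half-open) >
promoter (further upstream, to 2000 bp by default — the upstream bound
is not fixed by the category's definition and is configurable) > exon >
intron > intergenic (assigned to the nearest TSS). Midpoint assignment
keeps the five categories exclusive and exhaustive so the fractions are
well defined; annotators that use any-overlap rules will differ in
detail, so printed category percentages of any particular study are a
mechanism check, not a reproduction target.

The motif grammar consists of the degenerate heptamer `HRGAAYV`
((T/A/C)(A/G)GAA(C/T)(G/C/A)), the octamer `GAMSCKYC`
(GA(A/C)(C/G)C(T/G)(T/C)C), and heat-shock elements: tandem arrays of at
least three nGAAn 5-mers at period 5 whose GAA cores alternate
orientation, with a configurable budget of units carrying one core
mismatch ("degenerate version"). Scanning is IUPAC-aware on both strands
(reverse hits reported at forward coordinates), `N` never matches, and
the scanner is held to exact agreement with an independent
regular-expression oracle in the tests. Position-weight-matrix learning
(de novo discovery) is out of scope; declared patterns are scanned.

## The synthetic data generator

`simulate_dataset()` emulates: two samples of cells on a latent time in
$[0,1]$; per-gene two-state kinetics with class-specific switch times
(repression switches early, 0.10–0.35; induction mid, 0.25–0.60);
Poisson (or negative binomial) counts around capture-scaled
expectations (capture efficiency 0.5, giving nascent counts of a few
molecules — the sparse regime the methods must survive); cluster labels
from time breakpoints (three stages at 1/3 and 2/3); and a knockout
perturbation in which cells past the arrest time (0.45 by default, just
past the first stage boundary) stall: perturbed ("frozen") repression
genes keep transcribing ON indefinitely, frozen induction genes never
switch on, and all other genes hold their arrest-time state. This
reproduces the phenomenology of interest: a dominant aberrant cluster
branching off the early stage, a small normal mid-stage population, no
late-stage cells in the KO, sustained high nascent signal at perturbed
repression targets, and terminal-state mass on the arrest cluster.

Default study conditions: 600 genes (240 repression, 210 induction, 150
steady), of which 80 repression and 40 induction genes are frozen — a
minority of the drivers, as direct regulator targets are in real data;
if frozen genes dominated, no ordering of the KO sample could be
recovered from the data at all. 500 cells per sample. Latent times are
uniform by default (a beta density is available) because the true stage
occupancy is unknown; `genes_detected` and `mito_fraction` in the cell
metadata are drawn independently of the kinetics purely to exercise QC.

What the generator does **not** emulate: read-level noise (no FASTQ),
doublets, ambient RNA, batch effects, mitochondrial biology (QC fields
are synthetic), gene–gene correlation beyond the shared latent time, and
any feedback of the regulator on non-target genes. Passing tests
therefore show that the statistical machinery recovers planted structure
under sparse counts — not that real tissue obeys the two-state model.

The toy genome lays one gene per 4 kb slot on a uniform-background
contig, alternating strands, two exons per gene, with peaks (500 bp,
centred within ±300 bp of the TSS) planted on a chosen gene subset and
at least one motif instance written inside each peak; every planted
motif is recorded in a ledger the scanner must recover exactly.

## Numerical choices and degenerate inputs

* Equal splicing/degradation rates: rejected by name (`beta == gamma`).
* Fitted $\gamma$ passing through 1 during optimization is nudged by
  $10^{-6}$ to stay off the degenerate closed form.
* Ties in cell ordering are broken by cell index (stable).
* QC bounds are read literally as strict survival inequalities
  (200 < genes < 8500, mito < 20%).
* Transition-matrix rows with no admissible neighbour get a unit
  self-loop; power iteration warns with its residual if it fails to
  converge within 2000 iterations.
* Every stochastic stage takes a seed derived deterministically from
  one master seed, and rerunning a configuration reproduces every
  output exactly.

## Problem sizes

The bundled analysis scripts run a half-scale study (300 genes, 300
cells per sample) so the workflow replays in minutes; the acceptance
script and the test suite run the stated conditions of each check — the
full 600-gene / 500-cell default for planted-anomaly recovery, 500
genes / 200 cells for the type-I control, 50 noiseless genes for
parameter recovery. These sizes are the package's chosen study design.
The recovery assessment uses two-phase (plateau-then-decay)
trajectories: a decay segment is what expresses a degradation rate, and
for purely rising arcs with free latent times the $(\alpha, \gamma)$
objective is nearly degenerate (the arcs differ only at second order
near the origin), so tight recovery there reflects the data design, not
the fitter.

## Known limitations

* The EM-style fit is a simplified scheme with a single ON-then-OFF
  topology; genes with multiple switching events or time-varying rates
  are outside the model.
* Latent-time aggregation assumes most contributing genes share one
  trajectory; a sample dominated by perturbed genes cannot be ordered.
* The Mann–Kendall normal approximation is used at all series lengths;
  the exhaustive oracle in the tests covers the short-series regime
  where it is weakest.
* Driver "direction" is a global label from the fitted trend's sign; a
  gene that rises then falls within the observed window is labelled by
  its net fitted slope.
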