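---
title: "Cross-reactivity graphs and deconvolution of multiplex sandwich immunoassays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-reactivity graphs and deconvolution of multiplex sandwich immunoassays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsmi)
```

## The assay and the problem

A fluorescence sandwich microarray immunoassay (FSMI) prints capture
antibodies as replicate spots on a slide; antigens in the sample are bound
by the capture antibody and revealed by a fluorescent tracer antibody,
forming a sandwich. Panels built from polyclonal antibodies — such as
biosensor chips targeting perchlorate-reducing bacteria for environmental
monitoring and planetary exploration — are sensitive but cross-reactive:
an antibody raised against one strain's whole-cell lysate will often bind
material from related strains or from that strain's exopolysaccharide
fraction. A bright spot therefore does not, by itself, demonstrate that
the spot's cognate antigen is in the sample.

This package treats cross-reactivity as structure rather than noise. The
chip's cross-reactions are measured once, organised into a matrix and a
directed graph, and then used to *deconvolute* every multiplex
measurement, separating true detections from cross-reactions — including
cross-reactions from organisms that have no antibody on the chip at all.

## Quantification

Spots are printed in triplicate (`slide_layout()` defaults; at least two
replicates are required) and summarised per antibody by the replicate
**median**, which tolerates one damaged spot. The statistic is a package
choice: robust, standard for spot arrays, and permutation-invariant. The
replicate coefficient of variation is recorded and flagged above 0.25;
intensities at or above 65535 a.u. are flagged as saturated (16-bit
scanner convention).

The field background `B` is the pooled median over all blank spots — BSA,
protein printing buffer and pre-immune antiserum spots. Pooling all three
blank roles is a package choice; the per-antibody pre-immune medians are
retained on the profile for diagnostics but are not subtracted
individually. A signal is **positive** only when it strictly exceeds
`2.5 * B`; a tie is negative.

Within-chip negative controls (a buffer-only incubation, or a
heat-treated aliquot in which organics are destroyed so that residual
signal reflects mineral-particle binding) are removed by per-antibody
subtraction, clipped at zero: a fluorescence profile is non-negative by
convention. Whether the positivity rule is applied before or after
control subtraction is a protocol choice made by the calling code; the
packaged workflow and benchmark subtract first, which also removes the
additive background bias that would otherwise propagate through the
deconvolution (see below).

## The cross-reactivity matrix and the antibody graph

Each antibody's cognate immunogen is assayed alone at its working
concentration and revealed with the full tracer mix. From the assay of
immunogen *j*, the matrix column

\[ G_{ij} = \frac{F_i - B}{F_j - B}, \qquad G_{jj} = 1, \]

using background-subtracted signals, with `G_ij = 0` whenever spot *i*
fails the positivity rule in that assay. Normalising with
background-subtracted values is a package choice (the source only fixes
the normalisation result, the unit self-loop). After gating, off-diagonal
entries below 0.01 are zeroed: at that level the ratio is dominated by
background estimation error. Because both numerator and denominator are
background-subtracted signals from the same assay, `G` is invariant under
rescaling of a panel assay's fluorescences.

Antibodies are pruned before matrix construction when their cognate
self-signal fails positivity or when panel metadata flags them as poor
performers; the packaged 24-antibody panel flags eight (four EPS
antibodies without self-signal and four anti-protein antibodies that
capture their purified targets but expose no free epitope to the tracer),
leaving the 16-antibody chip that all downstream fixtures use.

The **antibody graph** has one node per retained antibody and a directed
link *j → i* with weight `G_ij` for every positive off-diagonal entry:
the immunogen of *j* lights the spot of *i*. Nodes with out-going links
are **type A** (their immunogen betrays itself on other spots); nodes
without are **type B**.

The packaged 16-node, 28-link reference topology is a reconstruction: the
published graph is reported as a figure, not as numbers. Every
cross-reaction named in the accompanying narrative is present (the
anti-*Azospira* lysate/EPS triangle, the *Dechloromonas* and *Arcobacter*
lysate–EPS partner links, the within-order links from the
anti-*Propionivibrio* antibody, the weak anti-*Shewanella* →
anti-*Ideonella* reaction, and the five strictly self-reactive type-B
antibodies); the remaining weak links and all numeric weights are
synthetic choices at the stated scale.

## Deconvolution

The fluorescence of one spot is modelled as the sum of the contributions
of all antibodies that cross-react with it:

\[ F_i = \sum_j G_{ij} F'_j , \]

and the deconvoluted signal `F'` solves `G F' = F`. `F'` lives in
fluorescence units because `G_jj = 1`, and may legitimately be
**negative**: a spot dimmer than its in-array cross-reactors predict.

Numerics: the system is solved by LU factorisation. The SVD condition
number is always computed; at or beyond `1e8` (or exact singularity) the
solver switches to the minimum-norm least-squares solution via the SVD
pseudoinverse (singular values below `max(dim) * eps * d_max` are
dropped) and sets a flag with a warning — field data must always produce
a report, never an exception. The residual `||G F' − F||` is attached to
every report.

## Presence codes

With `theta_pos = 2.5 * B` and `theta_dec = 0.5 * theta_pos`, each
antibody *i* receives exactly one code:

| condition | code | meaning |
|---|---|---|
| `F_i <= theta_pos` | **I** | cognate antigen absent |
| `F_i > theta_pos`, `F'_i <= theta_dec` | **II.a** | spot explained by in-array cross-reactors; a related antigen is present |
| `F'_i > theta_dec`, type B | **III** | cognate (or close relative) present |
| `F'_i > theta_dec`, type A, consistency holds | **III** | as above |
| `F'_i > theta_dec`, type A, consistency fails | **II.b** | signal from a relative certainly *not* on the chip |

The **consistency check** operationalises the argument "were this antigen
really present, it would light its partners more strongly than it does":
for every out-link *i → k* whose expected signal `G_ki * F'_i` itself
exceeds `theta_pos`, the observed `F_k` must reach at least half the
expectation (`consistency_tolerance = 0.5`). Expected signals at or below
`theta_pos` are not checked — an undetectably small cross-reaction cannot
fail a node.

Three of these constants are package choices where the source is silent:
`theta_dec = 0.5 * theta_pos` (a deconvoluted value below half the
positivity threshold is "approximately zero" on the same scale the
positivity rule uses); the consistency tolerance of 0.5 (a true positive
with 10% spot noise essentially never dips to half its expectation, while
a spurious signal lacking its partner misses it by far); and the rule
that the exact sign-code table — not reprinted in the source — is
reconstructed as the decision tree above, which reproduces every
published per-antibody code of the two showcase samples shipped as
regression fixtures (`demo_reactor_sample()`, `demo_sediment_sample()`).
Those fixtures' fluorescence vectors are themselves synthetic: bar
heights were never printed, so each fixture fixes a deconvoluted vector
`F'` and publishes `F = G F'`, hand-constructed so the published codes
come out exactly. Where the source labels some antibodies jointly as
"A.II.a or B.II", type-B nodes here receive only II.a — a type-B node has
no out-links, so the II.b branch is unreachable for it by construction,
and no finer B-side subdivision is invented.

## Calibration

The limit of detection of an antibody is the lowest tested concentration
of a serial dilution whose cognate signal passes the positivity rule,
reported as a strict decade bound (`"<10^3"`), matching the convention of
published LOD tables; a series that never passes is "not detected". An
interpolated LOD would pretend to more precision than a decade-spaced
titration supports. Response curves are fitted with the two-parameter
Langmuir binding model plus baseline, `F(c) = baseline + Fmax * c / (c +
K)` — deliberately the same functional form the simulator generates, so
fit and simulation are mutually consistent; a four-parameter logistic
would add a slope parameter the generative model does not have. Working
tracer concentrations are chosen as the smallest concentration reaching
90% of the plateau signal, with a flag instead of a number when the
titration is still rising more than 10% per step at its top.

## The synthetic-data generator

The simulator emulates: triplicate spots; blank (BSA, printing-buffer,
pre-immune) and fluorescent-frame control spots; saturating Langmuir
binding per antibody–antigen pair; cross-reactive binding encoded by a
relative-affinity matrix `R` (on-chip columns of the reference universe
equal the reference topology, so the implied chip matrix is recovered
exactly by the pipeline); buffer-only and heat-treated controls (heat
ablates the biological term; an optional mineral-binding term survives
it); and multiplicative lognormal spot noise, unit-mean with CV 10% by
default — the standard noise shape for fluorescence scanners. Background
is 100 a.u. and saturation signals 5000 a.u. (50× background) by
default; half-saturation constants are spread over `1e3`–`3e4` cells/mL
so that simulated LOD decades span the published range. All generators
are deterministic under a fixed seed.

Two **off-chip relative** antigens bind one lysate antibody each
(strongly) while leaving that antibody's expected cross-reaction partners
dark — exactly the configuration the consistency check converts into code
II.b.

What a green test does *not* establish: the generator draws independent
lognormal noise per spot and a clean Langmuir response; real fields show
spatial artefacts, carry-over, hook effects at extreme antigen excess and
batch-to-batch printing variation, none of which are modelled. Matrix
recovery to `1e-6` holds at saturation with zero noise; it is a
correctness check of the estimator, not a statement about experimental
reproducibility.

## Recovery benchmark and a known limitation

`recovery_benchmark()` spikes random subsets of 3–8 cognate antigens at
saturation, simulates the assay and a buffer-only control at 10% CV,
subtracts the control, classifies, and scores code III against ground
truth. At cognate signals of 10× background it recovers presence/absence
for ≥ 95% of antibody–sample pairs over 100 seeds.

The stated signal level matters: `theta_dec` is an *absolute* threshold
(half of `2.5 * B`), while the noise on a deconvoluted value scales with
the bright signals feeding it. At much larger dynamic ranges (e.g. 50×
background) the noise on cross-lit, antigen-absent spots increasingly
overruns the fixed threshold and II.a calls flip to false III. A
signal-scaled `theta_dec` would remove this, but would depart from the
fixed-threshold semantics of the published decision rule, so the package
keeps the absolute threshold and documents the operating range instead.
Misclassifications concentrate, in both directions, on densely
cross-linked antibodies (the *Dechloromonas* block), where deconvolution
must subtract several large correlated terms.

## Degenerate inputs and tie-breaks

* Positivity ties (`F == 2.5 B`) are negative; consistency-check
  expectations exactly at `theta_pos` are not checked.
* Negative net signals after control subtraction are clipped to zero;
  deconvoluted signals are never clipped.
* A singular or ill-conditioned `G` yields the minimum-norm solution plus
  a warning and flag, never an error.
* An empty retained set after pruning, a missing replicate group, absent
  control spots, panel mismatches and malformed table lines are all hard
  errors that name the offending antibody, field or line.
* Flat dilution series are reported as `Fmax = 0` and flagged rather than
  fitted; non-converging fits fall back to Nelder–Mead and flag failure.

## Limitations

* `G` is a point estimate; no uncertainty is propagated into `F'` or the
  codes, matching the deterministic published method.
* One immunogen concentration (the curve maximum) defines each matrix
  column; averaging over concentrations is available but not default.
* No inter-slide normalisation or batch correction.
* The reference topology's weights are synthetic reconstructions at the
  published scale; conclusions that depend on individual weight values
  rather than the topology should not be drawn from the packaged
  fixtures.
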