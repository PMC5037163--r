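---
title: "Quantifying colocalization in dual-labeled EM point patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying colocalization in dual-labeled EM point patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emcoloc)
library(ggplot2)
```

## The problem

In immunogold electron microscopy two molecular targets are labeled with
colloidal gold particles of distinct sizes, and each detected particle is
reduced to a point: its centroid in the section plane.  Unlike
fluorescence microscopy, where colocalization is the overlap of pixel
signals between channels, nothing ever "overlaps" in an EM point
pattern — two gold particles are always at some nonzero distance.
Colocalization must therefore be defined through distance: a particle of
type A *colocalizes* with a particle of type B when their Euclidean
distance lies in a chosen band $[r', r'')$, and such a pair is a
*colocalizing pair*.  The band is the key scientific input; it is chosen
from the data with the pair cross-correlation analysis described below,
not fixed a priori.

`emcoloc` implements a three-stage coefficient system on top of this
definition, a pair cross-correlation function (PCCF) with Monte-Carlo
envelopes under complete spatial randomness (CSR) for choosing the band,
pixel-overlap Manders coefficients for side-by-side comparison with
fluorescence data, and a synthetic generator of the point processes the
statistics assume.

## The coefficient system

For an image stack $i = 1, \dots, k$ with $n_i^A$ and $n_i^B$ particles
per image:

**Stage 1 — frequencies.** The average absolute particle number
$CC_1^{abs} = \frac1k \sum_i (n_i^A + n_i^B)$ and the average per-image
proportions $CC_1^{rel(A)} = \frac1k \sum_i n_i^A/(n_i^A + n_i^B)$ (and
likewise for B).  These carry no spatial information but are required to
interpret the later stages: a high colocalization fraction of a very
scarce label means something different from the same fraction of an
abundant one.

**Stage 2 — relative aggregated colocalization.**
$CC_2^A = \frac1k \sum_i n_i^{colA}/n_i^A$, the average fraction of A
particles having at least one B particle within the band (and
symmetrically $CC_2^B$).  The two are *not* complementary: they answer
different questions and in general do not sum to one.

Combining stages 1 and 2 gives four summary coefficients partitioning
the average image, e.g.
$CC^{coloc}_{A/(A+B)} = CC_1^{rel(A)} \cdot CC_2^A$ and
$CC^{non\text{-}coloc}_{A/(A+B)} = CC_1^{rel(A)} \cdot (1 - CC_2^A)$.
These satisfy five exact identities (they sum to 1; each label's pair
sums back to its stage-1 proportion; each stage-2 value is recoverable
as a ratio).  `verify_identities()` reports the residuals; on a clean
pipeline they are zero to floating-point precision, so the identity suite
doubles as an end-to-end self-check.

**Stage 3 — relative density of colocalization.**
$$CC_3^{B/A} = \frac1k \sum_i \sum_j \frac{1}{w(x_{ij}^A)}
  \frac{\sum_q I\bigl(r' \le d(x_{ij}^A, x_{iq}^B) < r''\bigr)}
       {n_i^{colA}\, n_i^B},$$
the fraction of all B particles paired with an *average colocalizing* A
particle.  With unit weights $CC_3^{B/A} \in [0,1]$, reaching 1 exactly
when every colocalizing A is paired with every B in its image.

## Worked example

The packaged `worked_example()` is a single 200 × 200 nm image with four A
and three B particles and band $[0, 50)$ nm, constructed so that the
pair structure is A2–B1, A2–B3, A3–B1, A4–B1:

```{r}
p <- worked_example()
fit <- em_coloc(p$particles, p$band)
glance(fit)
verify_identities(fit)
```

Three of four A particles colocalize ($CC_2^A = 3/4$), two of three B
($CC_2^B = 2/3$), and the densities are $CC_3^{B/A} = (2+1+1)/(3\cdot3)
= 4/9$ and $CC_3^{A/B} = (3+1)/(2\cdot4) = 1/2$.  Only the adjacency
structure matters for the coefficients, so the particular coordinates
are a free construction; they are placed so that no pair distance comes
within 1% of the band boundary, keeping the example robust to any
floating-point perturbation.

A note on the non-colocalizing fractions: they are defined as
$CC_1^{rel} \cdot (1 - CC_2)$, which for this example gives $1/7$ for
both labels and makes the four summary coefficients sum to one.  (The
seemingly natural alternative $CC_2^A \cdot (1 - CC_1^{rel(A)})$ breaks
the sum-to-one identity and is not a partition of the average image.)

## Conventions and numerical choices

* **Half-open band.** A pair at exactly $r'$ colocalizes; a pair at
  exactly $r''$ does not.  The comparison is exact floating point, with
  no epsilon: coordinates are measurements, and exact ties are a
  measure-zero event not worth a tolerance that would blur the
  definition.
* **Averaging.** All coefficients are unweighted means of per-image
  ratios (an "average image" reading), never ratios of pooled counts.
  Pooling would let particle-rich images dominate, which is exactly what
  the per-image normalisation is there to prevent.
* **Undefined per-image ratios.** An image with $n_i^A = 0$ has no
  $CC_2^A$ ratio; such images are excluded from that coefficient's
  average and the effective image count is recorded (and reported in the
  output).  Excluding is preferred to fabricating $0/0 = 0$, which would
  bias the average toward zero.  If *every* image is excluded the
  coefficient is undefined and the package raises an error rather than
  returning a silent zero.  $CC_3$ differs by construction: an image
  with no colocalizing A contributes a genuine zero term while staying
  in the outer $1/k$.
* **Units.** Everything is in nm.  Pixel tables must be read with an
  explicit `scale` (nm per pixel); there is no silent default because EM
  and FM pixel sizes differ by orders of magnitude.
* **Labels.** Exactly two categories; any unmapped label in an input
  table is an error, never silently dropped (dropping would bias the
  stage-1 proportions).

## Edge correction

Particles near the image boundary lose part of their distance annulus
outside the window, deflating their neighbour counts.  The optional
weight (`edge = "annulus_fraction"`) is the standard isotropic local
correction: the fraction of the annulus area inside the window,
$w(x) = |A(x, r', r'') \cap W| / \pi(r''^2 - r'^2)$, computed by exact
circle–rectangle intersection geometry.  A deterministic 3600-point
angular quadrature of the same quantity is kept as an independent
cross-check (the two agree to $10^{-6}$ in the tests; a Monte-Carlo area
oracle agrees to $10^{-3}$).

The default for the coefficients is **no correction**: the worked
example and the identity system are defined on unweighted counts, and
weighted $CC_3$ values are reported exactly as the formula yields them,
without renormalisation, so they can exceed the unweighted value by at
most the factor $\max(1/w)$ (tested on edge-hugging patterns).  In the
PCCF the weighting has a sharper role: weighting each pair by $1/w$
makes the per-bin estimator exactly unbiased under CSR, whereas the
uncorrected estimator drifts below 1 at distances comparable to the
window size.

## Choosing the band: PCCF with CSR envelopes

For each distance bin the PCCF divides the observed A–B pair count by
its CSR expectation $n_i^A n_i^B \pi(r_2^2 - r_1^2)/|W|$, averaged over
images; $g > 1$ means more pairs at that distance than independence
predicts.  Significance is assessed with a Monte-Carlo envelope: B
particles are re-randomised uniformly (A held fixed, so each pattern's
own clustering is conditioned on — the null is *no association*, not
*no structure*), and per-bin empirical quantiles over `n_sims`
simulations bound the band.  With 999 simulations at level 0.95 the
bounds are the 25th and 975th order statistics; with the minimum 19
simulations they are the per-bin min and max.  Envelopes are
**pointwise**, not simultaneous: under CSR about 5% of bins
individually poke outside, and `significant_bands()` therefore asks for
*runs* of bins with $g$ strictly above the upper bound.  Global
(simultaneous) envelopes are deliberately out of scope.

Defaults are 25-nm bins to 500 nm, matching the granularity at which
immunogold distance bands are usually reported; both are overridable.
All randomisation takes a mandatory integer seed and is bit-reproducible
from it; the package scopes the seed locally (`withr`), so user RNG
state is never disturbed.

```{r, fig.width = 6, fig.height = 3.5}
linked <- simulate_patterns("linked", link_band = distance_band(25, 75),
                            n_images = 21, seed = 11)
res <- pccf(linked, r_max = 300, n_sims = 199, seed = 12)
autoplot(res)
significant_bands(res)
```

## The synthetic generator

`simulate_patterns()` supplies the processes the statistics assume:
independent homogeneous Poisson labels (`"csr"`, the null), a linked
pair process (`"linked"`: each B is, with some probability, placed
uniformly in an annulus around a random A parent — the alternative with
a known true band), and a bivariate Thomas cluster process (`"thomas"`:
both labels are Gaussian offspring of shared Poisson parents —
aggregation without a sharp distance scale).  Defaults emulate a typical
immunogold acquisition: 21 images of 2000 × 2000 nm with on average 14 A
and 13 B particles per image.  Linked positions rejected by the window
are re-drawn so the annulus distance structure is preserved exactly;
with link probability 0 the linked sampler *is* the CSR sampler, so the
two are seed-identical by construction.

What the generator does not emulate — and hence what passing tests do
not certify about real data: section-thickness projection effects,
antibody labeling efficiency differences between targets, steric
exclusion between gold particles (a soft-core at very short distances),
and detection errors near image borders.  The coefficients are defined
on the observed pattern regardless; these effects change interpretation,
not arithmetic.

## Problem sizes used in the checks

The statistical checks run at sizes chosen to make their expectations
sharp while staying desk-scale: the CSR mean-of-$CC_2$ check uses 200
images of 100 + 100 expected particles against the Poisson
void-probability form $1 - \exp(-\lambda_B \pi r''^2)$ (agreement within
0.03, with the small edge-effect deficit expected below the closed
form); envelope coverage uses 999 simulations over 20 bins; band
recovery uses 20 independent linked stacks at the generator defaults
with 999-simulation envelopes each; and the brute-force oracle
comparisons run 1000 random instances of up to 50 particles per label.

## Limitations

* Two labels only; multi-type extensions need a different definitional
  scheme.
* 2-D in-plane distances; no account of section thickness or 3-D
  geometry.
* Rectangular windows only (the exact edge geometry relies on it).
* The coefficients are descriptive averages and are sensitive to
  outlier images in small stacks; robust variants are not implemented.
* No statistical test comparing coefficient values between experimental
  conditions is provided.
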