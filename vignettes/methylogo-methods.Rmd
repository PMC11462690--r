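---
title: "Methylation-aware sequence logos: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-aware sequence logos: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylogo)
```

This vignette documents the statistical model behind the package, the
choices made where the design was genuinely open, and what the synthetic
data used for validation does and does not emulate.

## The information decomposition

A set of `n` aligned, equal-length binding sites is summarised by a PWM
motif model $M$: independent per-position base probabilities $p_i(b)$.
Every track height is a Kullback–Leibler relative entropy (base-2
throughout, so heights are in bits) between $M$ and a background model.

**Sequence track.** Against a zero-order background $q$, the relative
entropy decomposes into one term per position,
$h_i = \sum_b p_i(b)\,\lg\frac{p_i(b)}{q(b)}$ with $0 \lg 0 = 0$, and each
letter within the column gets the fraction $p_i(b)$ of the column height —
the classical logo semantics (relative letter height = frequency, column
height = information).

**Dimer track.** Mammalian genomes are strongly CpG-depleted, which a
zero-order background cannot express. Rather than re-basing the sequence
track on a first-order (Markov) background $B_1$, the display keeps the
familiar sequence track and adds the *difference*
$D(M\|B_1) - D(M\|B_0)$ as a separate track. When $B_1$ emits its first
base from the zero-order marginal $q$ and $q(b\,|\,a) = q(a,b)/q(a)$, this
difference is exactly

$$\sum_{j=0}^{L-2} \sum_{a,b} p_{j,j+1}(a,b)\,
  \lg\frac{q(a)\,q(b)}{q(a,b)},$$

one signed bar per adjacent pair, where $p_{j,j+1}$ are the empirical
adjacent-pair joints of the sites. A positive bar means the sites use
dimers the background under-represents (for CpG-containing motifs,
essentially always the CG step). Two dashed reference lines mark the
extrema of $\lg\frac{q(a)q(b)}{q(a,b)}$ over the 16 ordered dimers — the
theoretically attainable bar range under that background. The test suite
verifies the decomposition against exhaustive enumeration of all $4^L$
sequences for random motifs and backgrounds to $10^{-9}$ bits.

**Methylation track.** Cytosine methylation propensity depends strongly on
the downstream one or two bases — CG, CHG, CHH context (H = A/C/T),
classified strand-relative from the *genomic* flanking sequence (a
site-final cytosine's context may depend on bases beyond the motif, which
is why the site matrix always carries a flank of at least 2 bp). Position
$i$ of the motif contributes, for each of the 6 strand × context classes,

$$P(\mathrm{ctx}, s\,|\,i)\; \cdot\;
  \mathrm{KL2}\!\left(m_{i,\mathrm{ctx},s} \,\|\, m_{bg}(\mathrm{ctx})\right),$$

where $P(\mathrm{ctx},s|i)$ is the fraction of sites carrying such a
cytosine there, $m_{i,\mathrm{ctx},s}$ the mean merged WGBS level of those
cytosines, $m_{bg}$ the background probability of methylation in that
context, and $\mathrm{KL2}(p\|q) = p\lg\frac{p}{q} +
(1-p)\lg\frac{1-p}{1-q}$. The multiplicative $P(\mathrm{ctx},s|i)$ term
bounds the influence of rare contexts, making the track robust to
small-sample noise in $m$. Reverse-strand components draw downward;
magnitudes are non-negative.

The total information of a logo is the sum of all sequence columns, dimer
bars and methylation components — the quantity a reader estimates by
visually adding up the display.

## Data processing

* **Replicate merging.** A cytosine enters the methylation table when its
  read depth exceeds four (i.e. depth ≥ 5) in a replicate; its merged level
  is the unweighted mean over the replicates in which it passed. A site
  passing in only one replicate is kept with that replicate's level; the
  stricter both-replicates rule is available (`require_all = TRUE`).
  Averaging is unweighted, not depth-weighted, treating each replicate as
  one measurement.
* **Methylation probabilities as means of beta-valued calls.** WGBS levels
  are fractions; the probability that a cytosine class "is methylated" is
  taken as the mean level of the class, treated as a Bernoulli parameter
  inside KL2.
* **Backgrounds.** Base and dimer frequencies are counted over both strands
  of the covered sequence (each dimer together with its reverse
  complement), never across region boundaries, skipping windows containing
  N. Consequently all background quantities are strand-pooled estimands:
  for example, a forward-strand chain with $q(G|C) = 1/16$ and stationary
  $\pi_C \ne \pi_G$ yields a pooled CpG conditional of
  $\frac{\pi_C/16}{(\pi_C+\pi_G)/2}$, which is what the estimator (and the
  recovery tests) converge to. Context methylation backgrounds pool both
  strands per context over the region set. Promoter regions default to
  TSS −1000..+200 bp, mirrored base-for-base on the minus strand.
* **Coordinates.** 0-based half-open everywhere internally; BED input is
  taken as 0-based half-open, 1-based TSS tables are converted at the
  reader boundary. Minus-strand sites are reverse-complemented into motif
  orientation, with methylation lookups performed genome-strand-aware.

## Parameters and numerical choices

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `min_depth` | 5 | per-replicate read-depth filter ("greater than four") |
| `flank` | 10 bp | site-matrix flank; must be ≥ 2 for context lookup |
| `pseudocount` (motif) | 0.5 per cell | avoids $\lg 0$ in the PWM and pair joints; negligible at realistic `n` |
| `pseudocount` (background) | 1 per cell | same role for genome-scale counts |
| clamping `eps` | $10^{-4}$ | probabilities entering KL2 are clamped to $[\epsilon, 1-\epsilon]$ so saturated methylation gives finite heights |
| `window` (profile) | 500 bp | flanking half-width of the profile display |
| `upstream`/`downstream` | 1000 / 200 bp | promoter window around the TSS |

Two further choices deserve note:

* The bundle's zero-order model is the *strand-symmetrised* marginal of its
  dimer joint, $(\text{row} + \text{column~marginal})/2$. Raw row marginals
  carry one-base region-edge asymmetries ($q(A) \ne q(T)$ at order
  1/#dimers), which would break the exact mirror symmetry of all tracks
  under reverse complementation of the site set — an invariant the package
  maintains to $10^{-12}$ and tests. Deriving both models from the same
  counts also keeps the dimer decomposition exact up to edge effects.
* Contexts classified as UNDEFINED (downstream bases off-chromosome or N)
  are excluded from both numerator and denominator of
  $P(\mathrm{ctx},s|i)$; classes with positive context probability but no
  surviving methylation observation are skipped with a warning rather than
  imputed.

In the flanking profile, the "entropy" row is the context-probability
weighted divergence $P_{ctx}(d)\cdot\mathrm{KL2}$ by default, matching the
track formula; `weighted = FALSE` gives the unweighted divergence.

## Rendering

Figures are assembled as a primitive scene and written as SVG by a
deterministic writer: fixed number formatting and sequential ids make
byte-identical output for identical inputs, and every bar, glyph and
shading rectangle carries both its geometry and its source value in
`data-*` attributes, so the figure is machine-checkable (the tests read the
SVG back and verify each height to $10^{-6}$ axis units). Letters are
package-defined unit-box outlines (no font dependency); glyph shading is a
path-clipped rectangle from the baseline up to the observed methylation
fraction, with most-probable-letter-on-top stacking. The same scene can be
replayed onto `pdf()`/`png()` devices; there the shading falls back to an
overlay rectangle because base devices lack path clipping — SVG is the
reference output.

## What the simulations emulate — and what they do not

The generator produces genomes from zero- or first-order chains (default: a
CpG-depleted chain, C→G transitions divided by 5, roughly uniform
elsewhere), plants non-overlapping sites (exact consensus or PWM draws,
random strands, with a 2×flank exclusion margin so context windows never
collide), and simulates call-level WGBS: for each cytosine the observed
level is Binomial(depth, true)/depth per replicate, with per-context true
levels (defaults CG 0.8, CHG 0.05, CHH 0.02, typical of mammalian somatic
cells) and optional overrides inside planted sites (default: hypo-methylated
site CpGs at 0.05). Depth defaults to a fixed 30, realistic for modern
WGBS; a Poisson option exists.

This validates the statistical machinery — estimator consistency, the
information decomposition, strand bookkeeping, end-to-end signal
localisation — but deliberately does not emulate: read-level bisulfite
conversion errors or mapping bias, copy-number or repeat structure,
correlated methylation along the genome, cell-type heterogeneity (which
attenuates observed correlations between binding and methylation), or
motif alignment uncertainty (sites must arrive pre-aligned at equal
length). Passing tests therefore certify the computation, not the
biological fidelity of any particular dataset.

Validation problem sizes were chosen to exercise asymptotics while staying
desk-scale: brute-force oracle checks enumerate all sequences for motifs up
to length 5; parameter recovery uses a 1 Mb genome at depth 30 (standard
errors well below the ±0.02 assertions); end-to-end localisation uses
100–120 kb genomes with 120–200 planted sites.

## Known limitations

* Backgrounds stop at first order; trimer and higher-order tracks are out
  of scope.
* 5-hydroxymethylcytosine is indistinguishable from 5mC in standard
  bisulfite data and is not modelled separately.
* The dimer track shows bars, not letter glyphs, between positions.
* Background models are global over the chosen region set; per-site
  tailored backgrounds are not implemented.
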