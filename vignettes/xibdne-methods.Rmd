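---
title: "Estimating sex-specific effective population sizes from X-chromosome IBD segments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating sex-specific effective population sizes from X-chromosome IBD segments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xibdne)
library(dplyr)
```

## The problem

Identity-by-descent (IBD) segments — haplotype stretches that two individuals
co-inherit from a common ancestor — carry a clock: segments from recent
common ancestors are long, segments from distant ancestors short, because
each intervening meiosis can place a crossover that trims them. The length
spectrum of detected IBD segments therefore encodes the recent effective
population size (Ne), generation by generation, over roughly the past
hundred generations.

Autosomal IBD-based Ne estimation is established; `xibdne` extends it to the
X chromosome. The X is the interesting case because females carry two copies
and males one, so the X responds more strongly to female demography than to
male demography. Comparing an X-chromosome Ne trajectory with an autosomal
one separates the female effective size $N_{g}^{f}$ from the male effective
size $N_{g}^{m}$ at every generation $g$ — a time-resolved picture where
older approaches give one genome-wide average.

## The X-chromosome coalescent model

**Carrier-sex chain.** A haplotype carried by a female received it from
either parent with equal probability; a haplotype carried by a male came
from his mother. So the probability $p_g$ that the ancestor of a sampled X
haplotype $g$ generations back is female obeys $p_{g+1} = 1 - p_g/2$, with
closed form

$$p_g = \tfrac{2}{3}\bigl(1 - (-\tfrac12)^g\bigr) + (-\tfrac12)^g\,p_0 ,$$

converging to $2/3$. When the sample itself has equal numbers of females and
males, $p_0 = 2/3$ and the chain sits at its fixed point in every
generation. This is why the pipeline *balances* the sexes by randomly
removing individuals of the overrepresented sex (`balance_sexes()`): it pins
the female-meiosis fraction at exactly $2/3$ with no demographic assumption.

**Segment lengths.** On the sex-averaged genetic map (female-specific cM
times $2/3$; `to_sex_averaged()`), only female meioses recombine, at rate
$3/2$ per Morgan. Of the $2g$ meioses on an inheritance path to a common
ancestor at generation $g$, the number of female ones is
$F \sim \mathrm{binomial}(2g, 2/3)$, and given $F$ the segment length is
exponential with rate $3F/2$ (`x_length_pdf_exact()`, conditioned on
$F \ge 1$: a path without female meioses never recombines and spans the whole
chromosome — that corner case is isolated there and nowhere else).
Replacing $3F/2$ by its mean gives the exponential($2g$) model
(`x_length_pdf_approx()`) used for fitting, the same form used on autosomes.
`compare_length_models()` shows the two agree closely (two-sample KS
distance below 0.05) for $g > 1$ and visibly less well at $g = 1$.

**Coalescence rates.** With female and male effective sizes $N^f$ and
$N^m$, a pair of X lineages coalesces in one generation with probability
$(2/3)^2/(2N^f) + (1/3)^2/N^m$, while an autosomal pair has
$(1/2)^2/(2N^f) + (1/2)^2/(2N^m)$. Defining chromosome-specific sizes as
half the inverse conditional coalescence probability gives

$$N^X = \frac{9 N^f N^m}{2 N^f + 4 N^m}, \qquad
  N^A = \frac{4 N^f N^m}{N^f + N^m},$$

with ratio $\alpha = N^X / N^A = 9(N^f + N^m) / (8(N^f + 2N^m))$ strictly
between $9/16$ and $9/8$, equal to $3/4$ when the sexes match. Inversion
gives the estimators

$$N^f = \frac{2 N^X N^A}{9 N^A - 8 N^X}, \qquad
  N^m = \frac{2 N^X N^A}{16 N^X - 9 N^A}.$$

Estimation error can push $N^X/N^A$ outside $(9/16, 9/8)$, making a
denominator non-positive; `sexes_from_nx_na()` reports such generations as
undefined (`NA`), never as negative sizes. The two-sex Wright–Fisher
simulator (`single_locus_coalescence()`) validates both coalescence formulas
by direct Monte-Carlo: lineage pairs are propagated through an explicit
two-sex population and the empirical conditional coalescence frequency is
compared with $1/(2N^X)$ and $1/(2N^A)$.

## Preprocessing adjustments for X data

`prep_ibd`-stage functions implement the adjustments X data need before
spectrum fitting:

1. **Haploid-male deduplication** (`dedup_diploid_males()`): if male X
   genotypes were coded homozygous-diploid, detected segments are duplicated
   across the phantom second haplotype; dropping every record where a male
   participates with haplotype 2 keeps exactly one copy.
2. **Sex-averaged map** (`to_sex_averaged()`): multiply female-specific cM by
   $2/3$ (3 cM female-specific = 2 cM sex-averaged). Pseudoautosomal regions
   and regions outside the map must be excluded upstream.
3. **Sex balancing** (`balance_sexes()`), as above.
4. **Haplotype-pair count** (`npairs_x()`): with $n_f$ females and $n_m$
   males the analysable cross-individual haplotype pairs number
   $2n_f(2n_f-2)/2 + n_m(n_m-1)/2 + 2n_f n_m$.
5. **Close-relative removal** (`remove_relatives()`): parent–offspring and
   sibling pairs, identified from pedigree or autosomal analysis (the X alone
   cannot), have their segments removed; the pair count drops by 4, 2, or 1
   for female–female, female–male, male–male pairs — the number of
   cross-haplotype pairs each relative pair contributed.
6. **Equal-cM splitting** (`split_into_pieces()`): the X is cut into 6 pieces
   of equal genetic length, relabelled as separate chromosomes, so that
   confidence intervals can be bootstrapped over "chromosomes". Segments
   crossing a boundary are split, with lengths recomputed from the map so
   subsegment lengths sum exactly to the original. Subsegments that fall
   below the 2 cM threshold after splitting are retained in the file; the
   spectrum builder applies the threshold uniformly. Whether lengths should
   be map-recomputed or prorated linearly in bp is not observable from the
   output format; map recomputation is used.

## The spectrum-matching estimator

`observed_spectrum()` bins segment lengths at or above the threshold
$u$ (default 0.02 Morgans = 2 cM) into equal-width bins (default 0.05 cM)
plus an open tail. Under the exponential($2g$) model, pairs coalescing at
generation $g$ contribute about $2gL$ segments across a map of length $L$,
each exceeding length $x$ with probability $e^{-2gx}$, so the expected count
in bin $[a, b)$ is

$$E_{[a,b)} = n_{\text{pairs}} \sum_{g} q_g \, 2 g L \,
  (e^{-2ga} - e^{-2gb}),$$

with $q_g$ the coalescence mass implied by the trajectory
(`coalescence_distribution()`). Chromosome-end effects are ignored — the
simplest model consistent with the length clock. The generation sum runs to
a constant-size tail at $g = 500$ (configurable `g_tail`) so essentially all
mass above the threshold is covered; the tail depth is this package's
choice.

`fit_ne()` finds the trajectory minimising the Poisson deviance between
observed and expected counts, with three structural choices:

- **Smoothing.** $\log N_g$ is piecewise-linear over knots every
  `smooth_window` = 8 generations, the smoothing interval conventional for
  this family of estimators.
- **Curvature penalty.** The deviance alone is nearly flat along directions
  that oscillate the knots against each other (adjacent generations have
  almost identical length kernels), so the objective adds
  $\lambda \sum_k (\Delta \text{slope}_k)^2$ on the knot values of
  $\log N$, with $\lambda$ = `smooth_penalty` (default 3) per 1,000 observed
  segments. Scaling with the count keeps the penalty-to-information ratio,
  and hence the effective smoothing bandwidth, stable from thousands to
  hundreds of thousands of segments. The penalty is the package's own
  regularisation choice; it biases sharp corners of the true trajectory
  toward their chords (see Limitations).
- **Initialisation and optimisation.** A constant-size moment match of the
  total count (monotone in $N$, solved by bisection) starts an L-BFGS-B
  search over the knot values; the fit is deterministic given the
  configuration. A spectrum with a single informative bin degrades to the
  constant-size match with a warning; an empty spectrum is an error.

For generations more recent than `gmin`, the growth rate of the first
estimable window is extrapolated toward $g = 0$ and flagged; those values
are not data-constrained. `gmin` defaults to 2 for real data (close
relatives removed explicitly) and should be 1 for simulated data with
independently generated chromosomes.

`bootstrap_ne()` resamples chromosomes (for the X: the 6 equal-cM pieces)
with replacement, recomputing the analysed map length per replicate, and
refits. `sexne_with_ci()` then transforms the X and autosomal trajectories
into female and male ones, pairing the $n$-th bootstrap replicate of each
and taking the 2.5th/97.5th percentiles (linear interpolation between order
statistics) as an approximate 95% interval. Replicates whose transform is
undefined at a generation are excluded from the percentiles rather than
clamped — negative sizes are not meaningful — and their count is reported
per generation so downstream users can judge the interval.

## The synthetic-data engine

`uk_like_model()` encodes the four-stage growth scenario used for
validation: constant total size 3,000 until 300 generations ago, then
continuous exponential growth at 1.4%/generation to generation 60, 6% to
generation 10, and 25% in the most recent 10 generations, reaching about 21
million at sampling. Growth is interpreted as continuous,
$N(t) = N_0 e^{rt}$: that reproduces the ~21 million figure, whereas
per-generation discrete compounding gives about 14.5 million and was
rejected. The female share defaults to one half and is adjustable.

Three simulators serve different validation layers:

- `single_locus_coalescence()` — genealogy only; the oracle for the
  coalescence-rate formulas above.
- `sample_ibd_spectrum()` — the generative twin of the expected spectrum:
  per generation, Poisson counts with the model's mean, lengths $u$ plus an
  exponential($2g$) excess truncated at the map length. Used for estimator
  recovery tests. When $u \ge L$ it emits nothing (no segment of length
  $\ge u$ fits), the one place finite map length enters.
- `forward_wf_ibd()` — a desk-scale forward haplotype-dropping simulator
  with founder-ancestry painting: female X meioses place Poisson($3L/2$)
  crossovers (sex-averaged scale), male X transmissions are intact, sons
  receive no paternal X; autosomes recombine at Poisson($L$) in both sexes.
  IBD is read off as maximal intervals of shared founder colour. Crossovers
  follow the Haldane (no-interference) model. Segments reaching the founder
  generation are truncated by construction, so runs should span clearly more
  generations than the typical pair TMRCA of interest.

What the generator deliberately does *not* emulate: mutation, genotyping or
phasing error, gene conversion (present in some forward-simulation studies
but absent from the estimation model), linkage-map heterogeneity beyond the
supplied map, and biobank-scale sample sizes. Passing recovery tests on
these synthetic data therefore demonstrates correctness of the estimator
under its own model assumptions, not robustness to detection artifacts in
real IBD calls.

## Numerical choices

- Internal lengths are Morgans; cM appears only at I/O boundaries
  (factor exactly 100).
- bp coordinates are 1-based and segment intervals closed, matching the
  hap-ibd output convention; map interpolation is linear in bp.
- Map spans are hard preconditions: interpolating or splitting outside the
  map errors rather than extrapolating.
- Percentiles use the default linear interpolation of order statistics
  (`stats::quantile` type 7).
- Bootstrap replicate $r$ derives its seed as `seed + r`; all simulators
  take explicit integer seeds and are bit-reproducible.
- Default problem sizes in the test-suite recovery studies: $10^6$ haplotype
  pairs, an X of 1.2 sex-averaged Morgans in 6 pieces, 5 autosomes of 1
  Morgan, 80 bootstrap replicates by default (the replicate count is a
  package choice), trajectories over generations 1–100.

## Known limitations

- **Corner resolution.** Near an abrupt change in growth rate the length
  spectrum cannot localise the change: kernels at neighbouring generations
  overlap, so the effective resolution is roughly $\pm 30\%$ of $g$, and the
  8-generation smoothing plus curvature penalty bias sharp corners toward
  their chords. In UK-like recovery runs at $10^6$ pairs the autosomal fit
  overshoots truth by up to ~50% right at the change point at generation 10,
  decaying to a few percent by generation 25. Errors of this kind are
  amplified by the sex-specific inversion ($\partial \log N^f$ responds with
  factors $+3/-2$ to $\log N^X/\log N^A$, $\partial \log N^m$ with $-3/+4$),
  which is why sex-specific estimates near growth-rate change points should
  be read qualitatively only — and why sex-specific trajectories should
  never be used to test hypotheses about sex differences over short windows.
- **Edge effects** (chromosome ends) are ignored in the expected spectrum;
  for maps much longer than the threshold this is a percent-level effect.
- **Very recent generations** ($g <$ `gmin`) are pure extrapolation.
- The estimator assumes the input segments are true IBD segments; detection
  power and phasing quality on real data enter upstream of this package.
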