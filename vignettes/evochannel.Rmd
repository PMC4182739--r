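---
title: "Codon evolution across reading frames: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon evolution across reading frames: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evochannel)
```

This vignette is the package's account of the science it implements: the
substitution model, the reading-frame projection, the selection and
information measures built on it, the choices made where the design was
genuinely open, and what the verification machinery does and does not show.

## The codon substitution model

The protein-coding reading frame (+1) evolves under the Goldman–Yang M0
model: a continuous-time Markov chain on the 61 sense codons with rates

$$q_{xy} = \pi_y \,\kappa^{[\text{transition}]}\,\omega^{[\text{nonsynonymous}]}$$

for codons differing at exactly one nucleotide position, and zero otherwise.
Changes into stop codons are excluded: inside a functional protein a
nonsense substitution is lethal. The three parameters are

* `kappa` ≥ 0 — transition/transversion rate ratio (A↔G, C↔T count as
  transitions). Unitless; 1 means no transition bias; bacterial data
  typically sit between 1 and 5. Default 1.
* `omega` ≥ 0 — the dN/dS ratio: ω < 1 purifying, ω = 1 neutral, ω > 1
  adaptive selection. Default 1.
* `usage` — the equilibrium codon distribution π, usually estimated from the
  annotated CDS of a genome (`codon_usage_from_cds()`). The M0 chain is
  reversible with stationary distribution π.

The generator is rescaled so that one time unit equals one expected
nucleotide substitution per codon,
$\sum_x \pi_x(-q_{xx}) = 1$; the evolutionary channel at time $t$ is
$P(t) = e^{Qt}$. Codon sites are assumed independent and stationary — the
channel is discrete and memoryless.

## Projection into the six reading frames

Every codon of an alternative frame lies inside a 6-nucleotide window formed
by two adjacent +1 codons, so the di-codon process is the minimal context:
two independent copies of the chain with Kronecker-sum generator
$Q \oplus Q = Q \otimes I + I \otimes Q$ on the $61^2$ ordered sense pairs
and stationary distribution $\pi \otimes \pi$. The window positions read by
each frame are fixed by convention (`frame_subcodon()`): +1 → 1–3, +2 → 2–4,
+3 → 3–5, and the reverse-complement of 4–6, 3–5, 2–4 for −1, −2, −3. Under
this convention the first and second codon positions of the +1 codon fall
onto the second and first positions of the −2 codon — the structural reason
frame −2 is special. The convention is pinned independently by the exact
reproduction of the degrees-of-freedom table (below).

The frame-f generator marginalises the di-codon generator onto the frame's
sub-codon. For frame states $x \neq y$:

$$q^f_{xy} \;=\; \sum_{d \,\ni\, x} \frac{(\pi\otimes\pi)(d)}{\pi^f(x)}
   \sum_{d' \,\ni\, y} Q^{\oplus}_{dd'},$$

i.e. the flank context is averaged under its conditional stationary
distribution given the observed sub-codon — the only weighting consistent
with the stationarity assumption. The projected process is then treated as
Markov in its own right. Frames ±1 live on 61 states (frame −1 excludes the
reverse complements of the stops: TTA, CTA, TCA), frames ±2/±3 on the full
64-codon container; container states without stationary support keep zero
rows and are flagged `unreachable`.

Two facts make the construction self-checking: the frame marginal of
$\pi \otimes \pi$ is automatically stationary for $Q^f$, and frame −1 is a
pure relabelling, $q^{-1}_{xy} = q_{\mathrm{rc}(x)\mathrm{rc}(y)}$. Both are
asserted in the tests, together with a brute-force oracle that builds the
explicit 3721-state generator with loops and marginalises it state by state;
the optimised sparse-matrix projection agrees with it to 10⁻¹⁰.

**A caveat on dynamics.** The exact law of a frame sub-codon transition over
a finite horizon is the flank-averaged *product channel*
(`project_transition_matrix()`), not $e^{Q^f t}$: projection and
exponentiation do not commute because the frame process is not exactly
Markov. The discrepancy is second order in $t$ (measured at ≲ 0.01 per entry
for horizons up to 0.2 substitutions/codon and growing roughly quadratically),
and the Monte-Carlo suite tests each representation against its own
prediction. All rate-based quantities (ω^f, stationary distributions) are
unaffected.

## Selection pressure per frame

Following the standard dN/dS construction, substitution fluxes are split by
synonymity: $\rho_S = \sum_{x\neq y,\, aa_x = aa_y} \pi^f_x q^f_{xy}$ and
$\rho_N$ likewise over amino-acid-changing pairs. Site proportions come from
an M0-form reference matrix with ω = 1, the frame's own π^f, and the shared
κ (the nucleotide-level transition bias is a property of the mutation
process, identical in all frames). Then
$d_N = \rho_N/\rho_N^{\mathrm{ref}}$, $d_S = \rho_S/\rho_S^{\mathrm{ref}}$,
and $\omega^f = d_N/d_S$; time and all scaling factors cancel, and on frame
+1 the input ω is recovered to 10⁻¹⁰ — an identity the tests assert across
ω ∈ [0, 3].

The one genuine modelling judgment is stop handling on 64-state frames: the
stop label is treated as a 21st symbol, stop↔stop counted synonymous,
stop↔amino-acid nonsynonymous, and the reference matrix keeps stop
transitions (an alternative-frame codon is not constrained to a functional
protein, so nonsense moves are ordinary events there). This keeps the flux
partition exhaustive. The frames ±1 use their 61-state spaces, where the
question does not arise.

## Information measures

The amino-acid channel at time $t$ removes stop rows and columns from
$P^f(t)$, renormalises, and pools codons within each amino acid by their
conditional stationary weights $\pi^f_x / \sum_{x' \in a} \pi^f_{x'}$.
Two summaries are computed in bits:

* conditional entropy with uniform weighting over the 20 amino acids,
  $H^f(Y|X) = \tfrac{1}{20}\sum_a H(Y|X=a)$ — the genetic noise accumulated
  after time $t$, bounded by $\log_2 20 \approx 4.32$;
* mutual information with uniform input, $I^f = H(Y) - H(Y|X)$ — the
  similarity retained between ancestral and descendant sequence, equal to
  $\log_2 20$ at $t = 0$ and decaying monotonically.

The *half-information time* is the $t$ at which $H^f$ crosses
$\log_2(20)/2$, found by bisection on $[0, 20]$ to 10⁻⁴ (the entropy is
continuous and increasing on the bracket, which the bisection verifies by
checking the sign at both ends). The threshold stays at $\log_2(20)/2$ even
if a frame's realised alphabet is smaller; `reduced_alphabet = TRUE` gives
the alternative. If a frame drops amino acids entirely (possible with
zero-frequency codons in the usage), the channel shrinks and the reported
alphabet is flagged.

Reported half-information times are the continuous bisection crossings
rounded to one decimal. Note the reported value is sensitive to this
convention: reading the first point of a coarse time grid (step 0.1) where
the threshold is exceeded systematically reports the next grid point up,
a difference of up to 0.1 for crossings just past a grid point. The
acceptance suite documents where published one-decimal values sit relative
to our crossings.

## Degrees of freedom of the genetic code

For an ordered pair $(A_1, A_2)$ of frame +1 symbols, `encodable_set()`
enumerates all di-codons translating to the pair and collects the distinct
translations of the frame's sub-codon. `mean_degrees_of_freedom()` averages
the set size over all pairs. The default conventions — pairs drawn from the
21-symbol alphabet (20 amino acids *plus the stop label*), stop also counted
as a distinct encodable symbol, ordered pairs, mean rounded half-up to two
decimals — reproduce the reference values 2.94/2.93/2.67/1.59/3.12 for
frames +2/+3/−1/−2/−3 exactly, which is what fixes them as defaults; flags
expose the nearby variants (`include_stop_pairs`, `count_stop`). The
enumeration is exhaustive and is its own oracle; the tests re-run it with a
permuted loop order and compare.

## Synthetic data and verification scales

The package verifies itself on synthetic inputs generated in code:

* `dirichlet_codon_usage()` draws usage vectors from a symmetric
  Dirichlet(α = 2) — dispersion comparable to real genome codon usage
  (frequencies spreading roughly an order of magnitude), without the
  GC-skew or amino-acid-composition structure of a real genome.
* `synthetic_cds_fasta()` plants an exact codon composition, so usage
  extraction can be checked against ground truth.
* `synthetic_codon_channel()` exponentiates a random reversible generator on
  64 codons — an empirical-matrix stand-in with known provenance.
* For a realistic usage, `ecoli_codon_usage()` computes codon usage at run
  time from the 999 Escherichia coli coding sequences shipped with seqinr.
  This is a genuine E. coli K-12 gene sample, not a genome-wide table from a
  specific strain; strain- and sample-level usage differences shift
  third-decimal frequencies and can move time-like summaries by a few
  hundredths.

Monte-Carlo verification uses sequences of 2×10⁵ codons (total-variation
agreement of empirical frame frequencies with π^f within 3σ sampling bounds,
which at this length is ≈ 0.054) and 10⁵ codons for the per-transition
binomial checks with disjoint windows. These lengths give 3σ discrimination
while keeping the default test run fast. Passing these tests shows the
analytic projections agree with the stochastic process they summarise; it
does not validate the biological assumptions (site independence,
stationarity, a single global ω) against real alignments.

## Numerical choices

* Matrix exponentials use `Matrix::expm` (scaling-and-squaring Padé); the
  tests cross-check against an independent truncated-uniformization series
  to 10⁻⁶ and assert row-stochasticity to 10⁻⁸.
* Stationary distributions solve $\pi Q = 0$, $\sum \pi = 1$ as a
  constrained least-squares problem via QR; rank deficiency raises a
  non-ergodicity error, residuals above 10⁻⁸ warn, and entries below zero
  (numerical noise) are clipped at −10⁻⁸ tolerance.
* Generators carry their state labels in dimnames everywhere; the codon
  order is fixed lexicographic and written into all output headers, so state
  identity can never drift silently.
* Degenerate inputs: usage with mass on stops is an error; zero-frequency
  codons are allowed (no pseudocounts) with an optional `floor`; ω = 0
  models still scale to unit flux; d_S = 0 reports ω^f = ∞ explicitly;
  CDS lengths not divisible by three warn and truncate; ambiguity codes are
  skipped, never imputed.

## Known limitations

* The projected frame processes are treated as Markov; this is exact for
  rates and stationary behaviour but approximate for finite-time transition
  laws (see the caveat above).
* Joint selection on two frames at once (a gene pair both under purifying
  selection) is out of scope — the model asks what frame +1 selection alone
  implies elsewhere.
* No indels, no rate heterogeneity across sites, no site classes beyond the
  single global ω, and only the standard genetic code (bacterial table 11 is
  codon-identical to table 1).
* A conserved alternative frame is a statistical statement about the
  channel, not evidence that the frame is translated or functional.
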