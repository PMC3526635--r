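---
title: "Structural-neighbor profiles: model, algorithm and design notes"
author: "rnaprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural-neighbor profiles: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaprof)
```

## The model

A secondary structure on an RNA sequence of length $n$ is a set of base
pairs $(i, j)$, $i < j$, drawn from the six Watson-Crick and wobble
combinations (A-U, C-G, G-U), with no position in two pairs, no crossing
pairs (pseudoknots are excluded), and at least $\theta$ unpaired nucleotides
inside every hairpin-closing pair ($j - i > \theta$, default $\theta = 3$).
Each structure $S$ has a free energy $E(S)$ and Boltzmann weight
$e^{-E(S)/RT}$; the partition function $Z$ is the sum of the weights.

Fix a reference structure $S^\ast$ and let $d(S, T)$ be the base-pair
distance — the size of the symmetric difference of the two pair sets.  The
package computes the structural profile
$$p(k) \;=\; \frac{Z_k}{Z}, \qquad
Z_k \;=\; \sum_{S:\, d(S, S^\ast) = k} e^{-E(S)/RT},$$
the Boltzmann probability that a structure of the ensemble lies at distance
exactly $k$ from the reference.  With the empty reference, $d(S, \emptyset)
= |S|$ and the profile is the distribution of the number of base pairs per
structure.  Two consequences used throughout:

* **Support bound.**  $d(S, S^\ast) \le |S| + |S^\ast|$, and no structure
  has more than $\lfloor (n - \theta)/2 \rfloor$ pairs, so every reachable
  distance satisfies $k \le |S^\ast| + \lfloor (n-\theta)/2\rfloor < n$
  (`max_distance_bound()`).  The bound is verified against the enumeration
  oracle in the tests.
* **Zero class.**  The only structure at distance 0 is $S^\ast$ itself, so
  $Z_0 = e^{-E(S^\ast)/RT}$ exactly.

## The algorithm

The generating polynomial
$Z(x) = \sum_S e^{-E(S)/RT}\, x^{d(S, S^\ast)}$ has real non-negative
coefficients $Z_k$ and degree below $n$.  Evaluating it at the $m$-th roots
of unity $\omega^j = e^{2\pi i j / m}$, $m$ at least the degree bound plus
one (default $m = n$), determines the coefficients through the inverse
discrete Fourier transform
$$Z_k \;=\; \frac{1}{m}\sum_{j=0}^{m-1} Z(\omega^j)\, \omega^{-kj}.$$

Each evaluation is an interval dynamic program in the complex field.  For
the Nussinov-Jacobson model (energy $\varepsilon$ per pair) a single matrix
suffices:
$$\hat Z_{i,j}(x) = x^{b_0}\,\hat Z_{i,j-1}(x)
 \;+\; \sum_{l}\; e^{-\varepsilon/RT}\; x^{b(l,j)}\;
 \hat Z_{i,l-1}(x)\,\hat Z_{l+1,j-1}(x),$$
with base case 1 on intervals of width $\le \theta$, the sum running over
admissible pairs $(l, j)$.  The exponents are the distance increments of
each decomposition step, computed from a precomputed table of reference
pair counts $|S^\ast_{[i,j]}|$:

* leaving $j$ unpaired loses the reference pair ending at $j$ inside the
  interval, if any: $b_0 = |S^\ast_{[i,j]}| - |S^\ast_{[i,j-1]}|$;
* introducing $(l, j)$ loses every reference pair that straddles the split
  and adds one for a novel pair (net zero for re-creating a reference
  pair):
  $b(l,j) = |S^\ast_{[i,j]}| - |S^\ast_{[i,l-1]}| - |S^\ast_{[l+1,j-1]}|
  + 1 - 2\,[(l,j) \in S^\ast]$.

Both increments are exposed (`pair_distance_increment()`,
`unpaired_increment()`) and property-tested against brute-force restricted
distances.  For the nearest-neighbor model the same bookkeeping is attached
to a McCaskill-style decomposition with four tables — closed ($ZB$),
multiloop part with one ($ZM1$) or at least one ($ZM$) helix, and the
exterior — each recursion step carrying $x^\Delta$ where $\Delta$ counts
the reference pairs made unrepresentable plus one per introduced
non-reference pair.  Because the oracle and the dynamic program share one
energy function (see below), exhaustive enumeration pins the bookkeeping
exactly; the test suite requires total-variation agreement at $10^{-8}$
(Nussinov) and $10^{-6}$ (Turner) on seeded random instances, and observes
$\sim 10^{-14}$.

Three implementation points matter for stability and speed:

* **Normalization before the transform.**  Partition-function values grow
  so fast with $n$ that interpolating the raw polynomial is hopeless;
  dividing all evaluations by $Z = Z(1)$ keeps every value on the unit
  scale, and the recovered coefficients are directly the probabilities
  $p(k)$.
* **Conjugate symmetry.**  Real coefficients imply
  $Z(\bar x) = \overline{Z(x)}$, so only $j = 0, \dots, \lfloor m/2
  \rfloor$ are evaluated by the dynamic program and the rest are filled by
  conjugation (`half_evaluation = TRUE`, the default; the tests confirm the
  shortcut is exact to $10^{-12}$ total variation).
* **Space reuse.**  One $O(n^2)$ table is allocated per evaluation point
  and reused, so the whole computation is $O(n^4)$ time and $O(n^2)$
  space.  A per-point parallel map would be trivially correct (the points
  are independent) but is not enabled by default; serial evaluation keeps
  results bit-identical across platforms.

## Energy models and parameters

`nussinov_model(epsilon = -1, RT = 0.6163)` scores $\varepsilon$ per pair,
in kcal/mol; $RT$ defaults to $0.0019872 \times 310.15$ kcal/mol (37 °C)
and both are configurable ($RT = 1$, $\varepsilon = -1$ gives
hand-checkable numbers, used in the examples).

`turner_model()` scores the unique loop decomposition: stacks keyed by
outer/inner pair type, hairpin / bulge / internal initiation tables with
Jacobson-Stockmayer extrapolation $1.75\,RT_{37}\ln(s/s_{\max})$ beyond the
largest tabulated size, an internal-loop asymmetry penalty (0.5 kcal/mol
per unit, capped at 3.0), and an affine multiloop $a + b\cdot\text{branches}
+ c\cdot\text{unpaired}$ with $a = 3.4$, $b = 0.4$, $c = 0$ kcal/mol.  The
table ships as a versioned plain-text file
(`inst/extdata/turner_params.txt`, overridable via `param_file` or the
`params` list).  Dangles, coaxial stacking, special hairpin bonuses and
temperature rescaling are deliberately out of scope: the package's
correctness surface is *self-consistency* — the dynamic program, the Zuker-
style MFE folder and the enumeration oracle all consume the identical
energy function — not bit-compatibility with any particular parameter
release.  Two conventions close the model: hairpins smaller than the table
minimum and interior loops larger than `max_internal` (default 30 nt) get
$E = +\infty$, i.e. zero weight, identically in the dynamic program and in
`turner_energy()`, so the two routes always describe the same ensemble.

## Numerical choices

* The inverse transform is `stats::fft` divided by $m$; the contract is the
  Vandermonde-inverse formula, not a particular FFT radix.
* The recovered coefficients must be real up to round-off.  An imaginary
  residual above $10^{-6}$, or pre-rounding mass differing from 1 by more
  than $10^{-6}$, raises a hard error (CLI exit code 3): those signal a
  bookkeeping or symmetry bug, never legitimate output.  Observed residuals
  are $\sim 10^{-16}$.
* Tiny negative coefficients in $(-10^{-\text{digits}}, 0)$ are clamped to
  zero; the vector is renormalized only if the clamped mass exceeds
  $10^{-\text{digits}}$.  Printed probabilities are reported to `digits`
  decimal places (default 6); the full-precision vector is kept alongside
  (`profile_probabilities()`) and all statistics use it.
* **Accuracy is absolute, not per-class.**  The transform recovers each
  $p(k)$ with error on the order of machine epsilon *relative to the whole
  distribution* (i.e. relative to $Z$ after normalization).  Classes with
  $p(k)$ near 1 are therefore accurate to $\sim 10^{-15}$ relative, but a
  class with $p(k) = 10^{-14}$ carries no correct significant digits: even
  exact evaluations rounded to double precision bound the relative error of
  a coefficient by $\varepsilon_{\text{mach}} / p(k)$.  This matters for the
  $Z_0$ identity: with references drawn uniformly from the ensemble under
  the nearest-neighbor model, $p(0)$ can be $10^{-14}$, and the identity
  $p(0) Z = e^{-E(S^\ast)/RT}$ then holds to $\sim 10^{-16}$ *of $Z$* but
  not to any fixed relative precision.  The integer-distance dynamic
  program, which never leaves real arithmetic, satisfies the identity to
  $10^{-12}$ relative and is the route to use when tiny classes must be
  resolved.
* MFE tie-breaks: candidate pairings are scanned in ascending 5' index and
  the first optimum is taken, so folds are deterministic.

## Validation oracles

`enumerate_structures()` generates the complete ensemble (default cap
$n \le 30$) by interval recursion; its count is checked against the
independent counting recurrence $N_{i,j} = N_{i,j-1} + \sum_l
N_{i,l-1} N_{l+1,j-1}$.  `exact_profile()` computes $p(k)$ by direct
summation; `rnabor_integer_dp()` runs the integer-distance recursion with
truncated coefficient vectors (the polynomial-expansion route the complex
evaluation avoids — exact, but quartic-plus in time).  The acceptance tests
demand pairwise total-variation agreement of all three routes on 100 seeded
Nussinov instances ($n \in [8, 25]$) and 50 Turner instances
($n \in [8, 20]$), with references drawn uniformly from the enumerated
ensemble; unit tests additionally compare the dynamic program against naive
ensemble summation at random points on the unit circle and against an
independent McCaskill-style partition function (no distance bookkeeping) at
$x = 1$ for $n$ up to 60.

## The synthetic generator, and what passing tests do not show

`random_rna()` draws i.i.d. nucleotides (uniform by default), matching the
0th-order random-sequence benchmarks the profile method is normally
evaluated on.  `embed_hairpin()` splices a perfectly complementary
stem-loop (arms drawn uniformly, loop $\ge \theta$) into a random
background, with its dot-bracket target — a synthetic positive control for
`window_scan()`.  `dinucleotide_shuffle()` implements the Altschul-Erikson
algorithm (uniform last-edge arborescence toward the final nucleotide, then
random edge orders, then the Eulerian walk), preserving the exact
dinucleotide multiset and both terminal nucleotides; the bundled TPP
riboswitch aptamers (`tpp_aptamers()`) serve as realistic shuffle inputs.

These generators emulate composition, not biology: uniform i.i.d. sequences
have no conserved structure, no GC-content gradients and no evolved
anti-correlation between neighboring helices.  Consequently the
moving-window control is *hard* in a way real scans are not: a 5-bp stem
defines only a 14-nt target, and among $\sim 100$ random 14-mers per
replicate some are fully compatible with the target pairs and — when
GC-rich — thermodynamically better hosts for it than an embedded stem whose
uniformly drawn arms happen to be A/U-rich.  In those replicates the scan's
global minimum genuinely lies at the background site (the exhaustive oracle
agrees with the scan values to $10^{-15}$), so the localization rate of the
stem-5 control sits near 80%, not near 100%; the tests record this
behavior.  Localization power grows quickly with target size and stability
— the regime of real applications, where the target is a full riboswitch
or expression-platform structure tens of pairs long — but users scanning
for small, weakly stable hairpins should expect chance-compatible
background sites.  The scan uses the nearest-neighbor model by default; the
Nussinov model's flat energies leave window ensembles too diffuse to
localize even strong stems.

## Problem sizes and limitations

The test suite works at desk scale by design — enumeration-backed instances
at $n \le 25$, partition-function cross-checks at $n \le 60$, scans on
120-nt backgrounds — chosen so the complete three-route validation runs
comfortably on one core.  The implementation itself is pure R; profiles of
a ~100-nt sequence under the nearest-neighbor model take on the order of a
minute, and the $O(n^4)$ total cost makes several hundred nucleotides the
practical ceiling.  The method recovers the distance *distribution* only:
it cannot exhibit a minimum-energy structure per distance class, nor sample
structures from a class — both need different machinery.  Pseudoknots,
modified nucleotides and consensus (alignment-level) structures are out of
scope, as are Lagrange-interpolation and Gaussian-elimination coefficient
recovery, which are numerically unstable for exactly the reasons the
roots-of-unity formulation avoids.
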