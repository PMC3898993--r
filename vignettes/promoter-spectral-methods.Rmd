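---
title: "Spectral methods for promoter structure: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral methods for promoter structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promspec)
```

This vignette documents the science inside promspec: the two models, what
their parameters mean and why the defaults are what they are, what the
synthetic-data generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## 1. Clustering by whole-sequence similarity

### Model

Promoters are compared as whole sequences with affine-gap alignment.
The working hypothesis is that structural families of promoters (for
instance compositionally biased ones, or families sharing interspersed
repeats) produce systematically higher alignment scores within a family
than between families, even when no single positioned motif is shared.
The pairwise score matrix is turned into a graph, and graph clusters are
read off the spectrum of the symmetric normalized Laplacian
`L_sym = I − D^(−1/2) W D^(−1/2)`: if the graph had `K` disconnected
blocks, 0 would be an eigenvalue of multiplicity `K`; for a perturbed
block structure the first `K` eigenvalues stay near zero and the
`(K+1)`-th jumps, so `K` is chosen at the largest gap
(`eigengap_k()`, ties toward smaller `K`). Assignment uses k-means on the
row-normalized matrix of the first `K` eigenvectors.

### Parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `match`, `mismatch` | +5 / −4 | the standard nucleotide (EDNAFULL) scores used by EMBOSS aligners |
| `gap_open`, `gap_extend` | 20 / 0.5 | a high opening and low extension cost: long gaps are tolerated once opened, which rewards sequences sharing long blocks (e.g. a transposon copy) and sharpens the eigengap. A run of `g` gaps costs `gap_open + g·gap_extend`, the EMBOSS dialect, verified in the test suite against exhaustive alignment enumeration |
| `end_gaps_free` | TRUE | semiglobal alignment, as in EMBOSS needle's default: promoters are windows, terminal overhangs are not evidence of dissimilarity |
| threshold θ | reshuffle null | mean all-vs-all score of per-sequence reshuffles. Reshuffling keeps length and composition, so compositional similarity alone also exists under the null; what survives thresholding is *positional* structure plus above-average compositional affinity |
| `adjacency_norm` | `"max"` | retained scores divided by the largest retained off-diagonal score, mapping weights into (0, 1]. The choice only rescales `W` and is provably irrelevant to `L_sym` up to nothing at all (the normalization cancels in `D^(−1/2) W D^(−1/2)`); it matters only for reading edge weights. Options `minself`/`none` are provided |
| k-means `tol`, `restarts` | 1e-6 / 50 | Lloyd iterations stop when no centroid moves more than `tol`; 50 random restarts, best inertia kept, all under one seed |
| `k_max` | 15 | the eigengap is searched among the first 15 eigenvalues |

Isolated nodes (no edge above θ) are excluded from the Laplacian and
reported unassigned rather than forced into a cluster: a promoter that
aligns no better than reshuffled sequences carries no evidence.

One open point was whether k-means should run on all first `K`
eigenvectors (including the near-constant one) or on `K − 1` of them.
We follow the standard recipe and keep all `K`; the constant direction
contributes (nearly) nothing after row normalization.

## 2. Regular sequences from the harmonic Peyrard–Bishop chain

### Model

In the W/S binary code (A,T → W; C,G → S) the promoter becomes a chain of
oscillators with potential energy

$$V(y) = \sum_{n=2}^{L} \frac{k}{2}\left(1 + \rho e^{-\alpha(y_n+y_{n-1})}\right)(y_n-y_{n-1})^2
      + \sum_{n=1}^{L} D_n\left(e^{-a_n y_n}-1\right)^2 ,$$

where `y_n` is the hydrogen-bond stretching of base pair `n`. At the
ground state `y = 0` the harmonic approximation keeps the Hessian only:
symmetric tridiagonal, off-diagonal `−k(1+ρ)`, diagonal
`(neighbours)·k(1+ρ) + 2 D_n a_n²`. Note `α` multiplies terms that vanish
at `y = 0`, so it never enters the Hessian; it is kept for the
full-potential oracle used in the tests.

The physics of detection is Anderson localization in a dichotomic chain:
the W and S on-site frequencies differ by `2D_S a_S² − 2D_W a_W² ≈ 5.4`
eV/Å², far more than the inter-site coupling `k(1+ρ) = 0.075`, so modes
localize on short same-class structures in aperiodic background. Ordered
tracts behave differently: a homopolymer run is a clean potential well
with sinusoid-like confined modes; periodic tracts (e.g. the WSSWSSW of
AGGAGGA) and palindromic tracts are arrays of *degenerate* wells whose
modes hybridize and extend across the whole tract. Delocalization is
measured by the participation number `P = 1/Σ_n v_n⁴`.

### Parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `D_W`, `a_W` | 0.05 eV, 4.2 Å⁻¹ | Morse depth/width of weak (A:T) pairs, the Campa–Giansanti phenomenological set |
| `D_S`, `a_S` | 0.075 eV, 6.9 Å⁻¹ | strong (C:G) pairs; `D_S = 1.5 D_W` encodes three vs two hydrogen bonds (warned about, not enforced) |
| `k`, `ρ`, `α` | 0.025 eV/Å², 2, 0.35 Å⁻¹ | stacking interaction; only `k(1+ρ)` enters the Hessian |
| `eps` | 0.01 | tail mass defining a mode's boundary sites `[s, e]`: `s` is the largest site whose left cumulative mass is ≤ ε, `e` the smallest site whose right tail is ≤ ε. The interval therefore *includes* the crossing site on each side |
| `delta` | 1e-4 | component threshold for the extension indicator `ext` (first to last component above `delta`); `ext` and `P` are deliberately different: a mode with a few large distant components and tiny ones in between has small `P` and huge `ext` |
| `P_thr` | 3.7 | delocalization threshold. Modes confined to an embedded 5-site run have `P ≈ 4.0`, to a 4-site run `P ≈ 3.3`; 3.7 separates them, which makes the shortest detectable regular sequence the 7-mer X·N₅·X (a 5-homopolymer with its opposite-class flanks). A threshold of exactly 4.0 sits on the knife edge of the 5-site case and was rejected for that reason |
| `tol` | 0.3 | mode-count tolerance: a candidate `[s, e]` is accepted when the number of delocalized modes contained in it matches the interior length `e − s − 1` within 30% |
| `min_len` | 7 | minimum reported region length |

### The two conventions that required a decision

**Boundary sites.** The tail criterion admits two readings that differ by
one site per side: take the first site *after* the ε-crossing, or include
the crossing site. We include it. The decisive observation is the
structure of the shortest regular sequences the method is meant to
report: strings like TCCCCCT — a 5-run plus one flanking base of the
opposite class on each side — and the 19-mer
CTAATTTTTGTATTTTTAG = S·W₈·S·W₈·S, whose eigenvector support lives on
the two W runs yet whose reported length is 19. Both come out exactly
under the inclusive convention and are clipped to 17/5-core under the
exclusive one.

**Counting criterion.** An isolated regular region of `m` sites owns
exactly `m` modes, so the number of whole-chain modes extending over the
region should be ≈ `m`. We apply this per delocalized eigenvector —
`n` = number of delocalized modes whose interval is contained in the
candidate interval, compared against the *interior* length — and merge
accepted intervals afterwards. The alternative (merge all overlapping
delocalized intervals first, then test the merged candidate) was
implemented and discarded: rare long-range resonances between distant
same-class sites produce occasional spurious wide modes which, merged
first, swallow genuine regions into candidates that then fail the test.
Per-mode testing rejects exactly the spurious modes and keeps the rest.

With these conventions, on planted data the detector reports: nothing
over 4-runs; `q + 2` over a planted `q`-homopolymer (`q ≥ 5`); exactly
the 19-mer over its planted copy; exactly AGGAGGA over its planted copy;
and zero false positives over regularity-free backgrounds (20 × 300 nt
and 5 × 1000 nt null seeds in the test suite).

## 3. What the synthetic generator emulates — and what it does not

`synth_promoters()` (preset `human4`) emulates the coarse structure the
clustering method assumes: a CG-rich class (p_C = p_G = 0.35), an AT-rich
class (p_A = p_T = 0.35), and two classes of uniform composition sharing
one fixed pseudo-random element of length 0.6·L inserted at a random
position, forward-strand in one class and reverse-complemented in the
other (the strand-symmetric insertion signature of transposons). It does
*not* emulate: real Alu sequence (a hook accepts a user element),
insertion-age divergence (no substitutions/indels on the element), CpG
islands, TSS-proximal positional gradients, or length variation. A green
clustering test therefore establishes that the pipeline separates
composition classes and shared-element classes at realistic score
contrast — not that real promoter families will be equally separable.

`plant_regular()` builds *regularity-free* backgrounds by a backtracking
sampler over the W/S alphabet and inserts given tracts verbatim. Because
the detector genuinely responds to any ordered structure, "regularity
free" must be stronger than "no short-period repeats": the sampler bans
homopolymer runs ≥ 5, p-periodic tracts ≥ 6 (p = 2, 3) and ≥ 2p
(4 ≤ p ≤ 16), and W/S palindromes ≥ 9 (palindromes act as degenerate
double wells). Random sequences violate these rules every ~15 positions,
so rejection sampling of whole sequences is infeasible and the
constructive sampler is the design. Two junction subtleties, both found
empirically and both documented here because they are easy to
rediscover the hard way:

* a background site of the tract's class at distance two (with an
  opposite-class site between) is exactly resonant with an embedded
  run's band-centre mode and smears the detected boundary; homopolymer
  tracts therefore carry a two-site opposite-class *guard zone*;
* mirror-symmetric background around a planted tract makes the two
  flanking wells degenerate, with the same effect; palindromic patterns
  may therefore involve at most two background sites per side of a
  tract (the minimal mirrors forced by the tract itself), enforced up to
  palindrome length 41 — mirrors wider than that pair wells separated by
  the whole tract, whose hybridization is negligible.

A planted `q`-run is thus reported as `q + 2` *by construction of the
method*, not of the generator: the flanks are the ε-crossing sites.

## 4. Numerical choices

* Eigendecompositions use LAPACK via `eigen(symmetric = TRUE)`; a
  1000-site chain takes ~2 s. Eigenvector signs are fixed by making the
  largest-magnitude component positive.
* The uniform free chain has the closed-form spectrum
  `λ_m = 2Da² + 2k(1+ρ)(1 − cos(mπ/L))`, `m = 0..L−1`; the test suite
  holds the implementation to it at 1e-8, and to a finite-difference
  Hessian of the full potential (Richardson-extrapolated central
  differences) at 1e-6.
* Alignment scores come from Biostrings' C implementation; the EMBOSS
  gap dialect and the semiglobal end-gap rule are pinned by an
  exhaustive alignment-path enumeration oracle for short pairs.
* k-means: own Lloyd implementation (centroid-movement tolerance, empty
  clusters re-seeded), deterministic under seed; ties in the eigengap
  and in `which`-style selections break toward the smaller index within
  1e-12.
* The eigengap tie rule matters for exactly-equal gaps, which occur for
  arithmetic spectra; floating-point noise is absorbed by the 1e-12
  margin.

## 5. Known limitations

* The harmonic treatment cannot see regularity that exists only in the
  quaternary alphabet (e.g. ACACAC... is homogeneous W in W/S); this is a
  property of the model, inherited deliberately.
* The detector's minimum length (7) and boundary conventions are
  calibrated to the default Morse/stacking parameters; changing `k` by an
  order of magnitude changes the localization length and invalidates
  `P_thr` (the band-overlap condition `4k(1+ρ) ≳ 2D_Sa_S² − 2D_Wa_W²`
  marks where the dichotomic picture breaks down entirely).
* `null_threshold()` uses one reshuffle replicate per promoter by
  default; for very small sets (< ~20) increase `null_replicates`.
* Repeat-overlap statistics use strict containment by default; an
  occurrence straddling a repeat boundary counts as outside
  (`overlap_rule = "any_overlap"` relaxes this).
* The packaged 44-member TATA exclusion list is a synthetic placeholder
  with the correct cardinality only (the file name says so); supply a
  curated list for biological use.
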