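---
title: "Reconstructing 3D chromatin structures from Hi-C contact maps with chromrec"
author: "chromrec authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing 3D chromatin structures from Hi-C contact maps with chromrec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromrec)
```

## The problem

Hi-C measures, genome-wide and averaged over a cell population, how often
pairs of genomic loci are cross-linked — a symmetric matrix of contact
frequencies $f_{ij}$ between $n$ fixed-size bins. Because spatially close
loci touch more often, the map carries information about the 3D folding of
chromatin, and a long line of methods turns it into a consensus 3D
structure: one point per bin, placed so that pairwise distances agree with
distances inferred from the contacts.

Two obstacles make this hard at scale. First, contact frequency is an
indirect, noisy, and heavily censored proxy for distance: only a small
fraction of pairs is observed, observed counts are reliable mostly for
close pairs, and the frequency-to-distance conversion leaves unobserved
pairs at infinite distance. Second, classical distance-geometry tools
(multidimensional scaling, all-pairs shortest paths) need $O(n^2)$ space
and worse time, which stops working around tens of thousands of bins — the
regime of kilobase-resolution maps.

`chromrec` implements a pipeline designed around those two obstacles:

1. **Power-law conversion.** Observed contacts become distances through
   $d_{ij} = 1/f_{ij}^{\alpha}$, with $\alpha \in [0.1, 3]$ estimated from
   the data ($\alpha = 1$ is the classical "inverse frequency" choice).
2. **Shortest-path completion with a pivot oracle.** Converted distances
   define a weighted graph; distances for unobserved pairs are
   shortest-path distances in that graph. Rather than all-pairs shortest
   paths, Dijkstra runs only from $\ell \ll n$ random *pivots*, and any
   distance is served on demand as
   $\min_{p} d_p(i) + d_p(j)$ — an upper bound that tightens as pivots are
   added. Storage is $O(\ell n + e)$.
3. **Progressive assembly (iMDS).** A random permutation of the loci is cut
   into overlapping subsets; each subset's oracle distance matrix is
   embedded by classical (Torgerson) MDS, and subsets are folded
   left-to-right by rigidly superposing the shared anchor loci (allowing
   reflection, since each local embedding has an arbitrary chirality) and
   averaging the anchors' two images.
4. **Scalable weighted polish (sMDS).** Rounds of block-wise weighted MDS:
   loci are randomly re-partitioned into disjoint blocks each round; each
   block is refined by SMACOF stress majorization with weights
   $w_{ij} = \hat d_{ij}^{-2}$, superposed back onto its previous placement,
   and every locus moves to the average of its old and new positions.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `pivotFrac` | 0.1 | fraction of loci used as pivots; at least 10% is recommended — below that, approximation error becomes visible in the reconstruction |
| `pivotMin` | 50 | pivot-count floor (capped at $n$): at $n = 100$ a bare 10% leaves 10 pivots and the oracle's systematic distance inflation dominates small-map reconstructions; the floor makes small-map oracles near-exact at negligible cost and is inactive for $n \ge 500$ |
| `subsetSize` | 500 | loci per iMDS subset; controls the $O(\mathrm{subsetSize}^3)$ eigendecompositions |
| `overlap` | 50 | anchor loci shared by consecutive subsets; at least 4 non-coplanar points are needed to pin down a rigid motion, and ~50 makes the estimated motion stable against local embedding noise |
| `weightScheme` | `inv_sq` | $w = \hat d^{-2}$; short distances are the reliable ones in contact data, and this scheme outperformed $w = 1$ and $w = 1/\hat d$ in our comparisons |
| `smdsBlockSize` | 500 | loci per polish block; each round costs $O(n \cdot \mathrm{blockSize}^2)$ versus $O(n^3)$ for one full weighted-MDS iteration |
| `smdsMaxRounds`, `smdsTol` | 200, 1e-4 | rounds stop when mean per-locus displacement per round falls below `smdsTol` times the radius of gyration; the block/average scheme needs roughly an order of magnitude more (cheap) rounds than full WMDS would need iterations |
| `alpha` | `NA` (estimate) | fixed exponent, or golden-section estimation (below) |
| `balance` | `FALSE` | Sinkhorn-style matrix balancing before conversion; see below |
| `seed` | 1 | controls pivot draw, subset permutation, block permutations |

All distances are in the arbitrary units induced by the conversion; the
reconstruction is defined up to a similarity transform (rotation,
translation, reflection, global scale), which is why accuracy is measured
by similarity-invariant quantities (distance correlations, unit-scale
superposition RMSD).

## Estimating the exponent

For a candidate $\alpha$, a cheap reconstruction is scored by the goodness
of fit $\sum_{f_{ij}>0} (f'_{ij} - f_{ij})^2$ with
$f'_{ij} = 1/d(X)_{ij}^{1/\alpha}$, and the score is minimized over
$\alpha \in [0.1, 3]$. Design choices here:

* **Probe reconstruction.** Each probe embeds a fixed uniform subsample of
  at most 500 loci: the induced sub-map is converted, exact shortest paths
  are computed on the induced subgraph (every subsample locus acts as a
  pivot — affordable at this size), and classical MDS embeds the result.
  Using exact rather than pivot-approximated distances in probes matters:
  the approximation inflates generic distances and that inflation biases
  the selected exponent upward. On noise-free power-law maps this
  estimator recovers the generating exponent essentially exactly
  (0.7, 1.0, 1.5 recovered within the search tolerance in our tests).
* **Search.** The goodness landscape is not globally smooth: near the
  $\alpha = 0.1$ edge all converted distances approach 1 and embeddings can
  collapse pairs, producing enormous spikes (a collapsed observed pair is
  scored as an arbitrarily bad fit rather than an error). A 15-point grid
  scan followed by golden-section refinement inside the best grid bracket
  keeps the evaluation count at a constant plus $O(\log(\mathrm{range}/tol))$
  while being robust to those spikes. The bracket tolerance is 0.01 in
  $\alpha$: results are insensitive below that scale.
* **Known bias under count noise.** With Poisson-sampled counts the
  goodness-optimal exponent sits systematically above the generating one
  (about 1.3–2.0 when the generating exponent is 1, depending on count
  depth): compressing the metric smooths count noise, and the criterion
  rewards it. The basin is flat — goodness varies by under 10% across
  $\alpha \in [1.4, 2.6]$ in our measurements — and reconstruction accuracy
  is correspondingly insensitive across that band, so the bias is
  inconsequential for structure quality; but the estimate should not be
  read as a physical scaling exponent.

## Balancing

`balanceContacts()` removes per-locus coverage bias by symmetric iterative
proportional scaling (alternately dividing by the square roots of row sums
until the coefficient of variation of row sums drops below `tol`). This is
a deliberately simple stand-in for Knight–Ruiz-type balancing with the same
fixed point: equal row sums. It is the right preprocessing for *measured*
Hi-C maps, whose row sums mix geometry with mappability, fragment and GC
biases.

It is deliberately **off by default** in `reconstructStructure()`. In a
bias-free map — any map our simulator produces — row-sum variation *is*
geometric signal (interior loci touch more partners than peripheral ones),
and forcing row sums equal measurably destroys reconstruction accuracy: in
our n = 2000 benchmark, balancing the binary map dropped the
distance-Pearson correlation of the final structure from 0.98 to 0.68.
Enable it for real data with `reconstructionConfig(balance = TRUE)`.

## What the simulator emulates, and what it does not

`simulatePolymer()` grows fixed-bond-length random-walk chains confined to
a sphere with an excluded-volume rejection rule (no two loci closer than
0.7 bond lengths; after a capped number of rejected proposals the
least-crowded in-sphere proposal is accepted so generation always
terminates). This reproduces the coarse features that matter for
contact-map reconstruction — local chain continuity, global compaction, a
neighbour-distance scale well separated from the all-pairs distance scale —
and is deterministic under a seed. It is *not* a physical polymer model: no
Langevin dynamics, no chain stiffness or topological constraints, no
thermal-equilibrium guarantee. Conclusions drawn from passing tests are
about the reconstruction machinery on polymer-like confined geometries,
not about chromatin biophysics.

The default confinement radius, $\max(3, 1.2\,n^{1/3})$ bond lengths, keeps
the packing fraction moderate (a few percent) so that excluded volume is
active but the walk is not jammed.

Two observation models generate maps from a structure:

* `binaryContactMap(s, k)`: the $k$ closest pairs get frequency 1
  (deterministic; ties broken lexicographically). Unit-weight graphs make
  shortest-path distances hop counts — a regime where the pivot
  approximation is at its best, because dense unit-weight graphs have many
  co-optimal shortest paths for a pivot to land on.
* `poissonContactMap(s, alpha, beta)`: independent counts with rate
  $\lambda_{ij} = \beta / d_{ij}^{\alpha}$; `coverageToBeta()` calibrates
  $\beta$ to a target fraction of observed pairs by bisection on the
  analytic expected coverage. Fractional converted weights give the
  contact graph a much richer shortest-path structure, and low-count
  entries ($n_{ij} = 1$ regardless of distance) act as noisy long-range
  shortcuts; approximation-quality and accuracy figures are accordingly
  lower than in the binary regime at equal $n$ (see the acceptance notes
  below).

## Numerical choices and degenerate inputs

* Classical MDS clamps negative eigenvalues at zero and zero-pads when
  fewer than three positive eigenvalues exist (with a warning).
* SMACOF uses the weighted Guttman transform; the pseudo-inverse of the
  (rank $m-1$) weight Laplacian is computed once per block via the rank-one
  completion $(V + \mathbf{1}\mathbf{1}^T)^{-1} - m^{-2}\mathbf{1}\mathbf{1}^T$.
  Stress is non-increasing by construction and iteration stops at relative
  stress decrease below 1e-6 or `smdsMaxIter`. Points whose weights are all
  zero keep their initial coordinates.
* Superposition solves orthogonal Procrustes by SVD; when reflection is
  allowed the unconstrained (possibly improper) optimum is compared with
  the determinant-constrained proper rotation and the better is kept —
  algebraically identical to superposing the mirror image separately.
  Near-coplanar point sets are flagged `degenerate` (the minimizer is still
  returned); degenerate anchor sets in the assembly trigger one permutation
  redraw.
* Tail iMDS windows that would contribute no new loci are skipped; tail
  polish blocks smaller than 4 merge into their predecessor.
* Zero-frequency pairs get no edge (never a capped large distance); if the
  contact graph is disconnected the largest component is reconstructed and
  the dropped loci reported, with an optional backbone-edge fallback
  (median edge weight between consecutive same-chain loci) for sparse maps.
* EMR uses a relative tolerance of 1e-9: exact float equality is ill-posed.
* Uniform-weight graphs (every binary map after conversion) take a BFS fast
  path for shortest paths — hop counts times the common weight — which is
  several-fold faster than the heap-based Dijkstra used for general
  weights and bit-for-bit identical on such graphs.

## Problem sizes used in the shipped tests and acceptance runs

Unit and property tests run at $n \le 500$ (with exhaustive all-pairs
oracles up to $n = 300$). The large-scale checks use a single 10,000-loci
16-chain confined polymer with a top-10% binary map, 100–1,000 pivots,
1e5 sampled pairs for shortest-path quality (exact side recomputed by
Dijkstra/BFS from the sampled sources) and 1e6 sampled pairs for distance
correlations — the binary regime is the one in which large-scale
oracle quality is meaningful, while the Poisson model's harder
fractional-weight graphs are exercised at benchmark scale.
Benchmark-scale runs cover $n \in \{100, \dots, 500\}$ with 10 seeds each
(Poisson maps at 90% coverage as the dense regime, binary top-10%).
Polish rounds are capped at 6 for the 10,000-loci runs and 12 at benchmark
scale (the displacement trace is essentially flat after that many rounds);
these sizes are the package's chosen desk-scale experiment and are stated
in the test code.

## Known limitations

* A single consensus structure is inferred; ensemble heterogeneity across
  the cell population is out of scope.
* The Poisson low-coverage regime fundamentally limits long-range accuracy
  (count-1 shortcuts); the pipeline's weighted polish mitigates but does
  not remove this.
* The estimated exponent is a self-consistency optimum, upward-biased
  under count noise (see above).
* Balancing is a simple Sinkhorn-type scaler, not the Knight–Ruiz
  algorithm, and should be applied only to measured maps.
* Inter-chromosomal maps are treated as one point cloud; no per-chromosome
  scaffolding logic is applied beyond chain labels on backbone edges.
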