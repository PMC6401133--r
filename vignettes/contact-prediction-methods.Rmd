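---
title: "Methods: contact prediction with a fully convolutional residual network"
author: "contactnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact prediction with a fully convolutional residual network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Two residues of a folded protein are *in contact* when the distance between
their C-beta atoms (C-alpha for glycine) is strictly below 8 Angstrom.
Contacts separated by at least six positions along the sequence are the
informative ones for structure prediction; we split them by sequence
separation $|i-j|$ into *short* [6, 11], *medium* [12, 23] and *long*
[24, $\infty$) regimes, with separations 1–5 called *local* and excluded
from evaluation. Predicting the contact map of a sequence is treated as
pixel-level classification of an $L \times L$ image whose 51 channels
carry, per residue pair $(i,j)$:

* channels 1–40: the 20-dimensional positional profiles of residues $i$
  and $j$ (MSA column frequencies with an additive pseudocount; gaps are
  excluded from the normalization),
* 41–46: 3-state secondary-structure probability vectors of both residues,
* 47–48: a relative solvent-accessibility scalar for both residues,
* 49: a coevolutionary coupling score (read from an external flat-matrix
  file, or fabricated by the synthetic generator),
* 50: mutual information between the two alignment columns (natural log,
  uniform pseudocount, no average-product correction),
* 51: a statistical contact pair potential
  $U(a,b) = -\log\left[P_{\mathrm{obs}}(a,b \mid \mathrm{contact}) /
  P_{\mathrm{exp}}(a,b)\right]$ estimated from a structure corpus by
  additive smoothing, with $P_{\mathrm{exp}}$ the product of corpus
  amino-acid compositions.

The classifier is a fully convolutional residual network: one entry
3×3 convolution (64 filters) with a ReLU, 19 identical residual blocks
(conv–ReLU–conv, add the skip, ReLU), a per-channel transpose average
$(O + O^\top)/2$, and a final 3×3 convolution to three output channels —
non-contact, contact and *ignored* (pairs involving residues missing from
the experimental structure) — followed by a per-pair softmax. That is 40
convolutional layers and 1,434,435 trainable parameters
(`n_parameters(contact_net_config())`), which rounds to 1.4 million.
There is no batch normalization (inputs have variable side length $L$)
and no dropout (the output needs pixel-level resolution).

### Exact output symmetry

A 3×3 convolution applied after the transpose average does not by itself
preserve matrix symmetry, so the transpose average is applied twice: once
on the 64-channel map before the final convolution (where it also damps
noise) and once on the 3-channel logits before the softmax. The second
average is algebraically equivalent to symmetrizing the final kernel and
makes $P_{ij}$ and $P_{ji}$ *bitwise* equal; it adds no parameters. The
reported probability $P$ is the contact-class softmax output, without
renormalization over the other two classes.

## Training

The loss is per-pair cross-entropy over the three classes, averaged over
pairs not labelled ignored; ignored pairs contribute zero loss and zero
gradient, so the third output class exists in the softmax but is never
reinforced. The contact class can be up-weighted (weights 1 and 4 are the
two protocol settings); a higher weight raises recall.

The optimizer is momentum SGD (learning rate 0.01, momentum 0.9, L2 weight
decay $10^{-4}$, optional per-epoch learning-rate decay, all configurable)
with batch size 1, since inputs differ in size. The reference literature
for this family of models does not pin an optimizer or schedule, so these
defaults were chosen once as ordinary values for residual convnets of this
depth and are deliberately not tuned per experiment. One caveat is
documented: with batch size 1 and a single training target, the gradient
is never averaged over targets and momentum SGD becomes step-size
sensitive — some initializations oscillate indefinitely at the default
rate. `train_control(optimizer = "adam")` provides an adaptive
alternative that is robust in that regime, and the package's single-target
overfit demonstration uses it (lr 0.003, 200 epochs); multi-target
training keeps the SGD default. All randomness — He weight
initialization, epoch shuffling, data splits — derives from one mandatory
integer seed, so a fit is reproducible bit for bit.

The ensemble protocol splits the training ids five times into a
validation subset (pairwise disjoint across splits) and a training
remainder, trains each split once per contact-class weight (5 × {1, 4} =
10 models), and reports the arithmetic mean of the member probability
maps.

## Evaluation

`top_k_precision()` ranks eligible pairs — upper triangle, requested
regimes, not ignored — by probability, ties broken by ascending $(i,j)$ so
the selection is a total order, takes the top $\lceil L/k \rceil$
($k \in \{1,2,5,10\}$), and reports the fraction of native contacts among
them. Ceiling was chosen for $L/k$ (the convention is not fixed by the
evaluation literature); when fewer eligible pairs exist than
$\lceil L/k \rceil$, all are taken and the denominator shrinks
accordingly. A target with no native contact in the requested regimes
scores 0, mirroring evaluations that select top predictions regardless of
score significance. `precision_by_probability_bin()` bins positive
predictions ($P > 0.5$) by probability, reporting empty bins as undefined
rather than 0, and `prediction_depth()` is the number of confident
($P > 0.8$) medium/long predictions divided by $L$.

## Contact-pattern analysis

Packed secondary-structure elements appear as dense clusters of points on
the contact map. `cluster_contacts()` groups the medium/long native
contacts with HDBSCAN (implemented in the package: core distances, mutual
reachability, minimum spanning tree, single-linkage hierarchy, condensed
tree at minimum cluster size 3, excess-of-mass selection). Only the
minimum cluster size is fixed by the analysis design; the remaining
choices — Euclidean metric on the $(i,j)$ indices and
`min_samples = min_cluster_size = 3` — are the common defaults of the
reference implementations. Two numerical caveats are documented rather
than hidden:

* Mutual-reachability distances tie exactly whenever one point's core
  distance dominates several pairs, and the dendrogram shape under ties is
  implementation-defined. This package sorts MST edges by weight with
  insertion order as tie-break, which reproduces a reference
  implementation on tie-free data (59/60 random fixtures in development
  checks; the one divergence was an exact tie).
* When the cluster hierarchy is a single root (e.g. three adjacent
  points and nothing else), strict excess-of-mass with a non-selectable
  root would label everything noise. The package then falls back to
  selecting the root as a single cluster, keeping the points that persist
  beyond the root's birth density — so one compact blob is one cluster,
  while far outliers remain noise.

A native cluster is *hit* when at least one correctly predicted contact
lies in it (the hit criterion is this package's definition; coverage
statistics are insensitive to reasonable alternatives on clustered maps).
Cluster coverage is hits over clusters; contact coverage is correctly
predicted in-cluster contacts over all in-cluster native contacts;
`delta_coverage()` is the signed difference between two predictors on the
same native cluster set, and `compare_predictors()` truncates the rival
predictor to the reference's positive count so both are judged on equally
long lists. False-positive proximity uses Chebyshev distance, so a
"two-residue shift" means both indices within ±2 of a cluster member.

## Restraints

Each positive prediction becomes one restraint: an 8.0 Angstrom upper
bound between the side-chain centers of mass, carrying $P$ as confidence.
`combine_contact_sources()` merges template-derived pairs as a tagged
union — template pairs enter at a configurable floor probability
(default 0.5) and keep their tag so template-derived restraints pass
through unchanged; overlapping pairs are counted once. Only the
side-chain center-of-mass bound is emitted (no additional C-beta bound);
the union-with-tags arithmetic is this package's design choice, as the
combination rule is otherwise underdetermined.

## The synthetic generator, and what it does not show

`generate_toy_fold()` builds chains of ideal helices (rise 1.5 A/residue,
100°/residue, radius 2.3 A) and strands (rise 3.3 A/residue) packed as
antiparallel rods 9 A apart with short connecting loops, pseudo C-beta
atoms at a 1.6 A radial offset, and randomly planted glycines to exercise
the C-alpha fallback. Packed neighbors produce clustered medium/long
contacts; a single helix produces none. Typical toy targets have non-local
contact densities of a few percent of non-local pairs, the sparse regime
real single-domain proteins show.

`generate_covarying_msa()` makes the coevolution signal learnable by
construction: each contact pair (restricted to a one-to-one column
matching) mutates *jointly* with probability equal to the covariation
strength (default 0.9, the "strong covariation" condition; the second
column is a fixed random permutation image of the first), while background
columns mutate independently at rate 0.35. The fabricated coevolution
matrix is the alignment's normalized mutual information plus Gaussian
noise (sd 0.05) — a stand-in with the statistical shape, not the
inferential power, of a real coupling analysis. Alignment depth defaults
to 200 rows, deep enough for stable column statistics at these lengths.

Desk-scale experiments train a scaled-down configuration of the same
architecture (16 filters, 4 residual blocks; ~29k parameters) for 30
epochs on 30 targets of length ≈ 50, with held-out evaluation on 8 more;
the single-target overfit check runs 300 epochs. These sizes are the
package's demonstration conditions: large enough that held-out top-L/5
medium/long precision is far above chance, small enough to run on one
CPU core in minutes.

What passing these tests shows is that the implementation — features,
network, loss masking, ensembling, evaluation, clustering — is internally
correct and can extract a planted covariation signal. It does **not**
show real-protein performance: synthetic folds have idealized geometry,
no real evolutionary structure, no alignment depth variation, and a
coevolution channel that is by construction informative. Numbers obtained
on synthetic data must never be quoted as expected accuracy on real
targets.

## Degenerate inputs and numerical conventions

* Residue indexing is 0-free: everything user-facing is 1-based; PDB
  chains are renumbered sequentially on read (insertion codes dropped),
  the first polymer chain, first model and highest-occupancy altloc are
  selected by default.
* The 8 A comparison is strict `<`; probability cutoffs are strict `>`.
* Residues lacking both C-beta and C-alpha are *missing*: their pairs are
  ignored, never zero-filled.
* Sequence letters outside the 20-letter alphabet map to the uniform
  profile row and the mean pair potential.
* An alignment column with no countable letters and zero pseudocount
  falls back to the uniform profile row.
* Amino acids absent from a pair-potential corpus get $U = 0$ (no
  information) rather than a divergent log-odds.
* Probability maps must be symmetric on input; asymmetric input is an
  error, not silently symmetrized (except explicit readers, which
  average).

## Known limitations

* No GPU and no batching: training beyond toy scale is impractical in
  this implementation.
* The pair potential is a generic log-odds table, not a published
  knowledge-based potential; it is swappable wherever a table is
  accepted.
* HDBSCAN tie-breaking can differ from other implementations on integer
  contact coordinates (see above); cluster counts on real maps may move
  by ±1 at exact ties.
* mmCIF input, C-alpha-only contact definitions and distance-map
  regression are out of scope.
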