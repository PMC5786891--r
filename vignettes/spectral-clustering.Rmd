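---
title: "Clustering DNA sequences by their power spectra: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering DNA sequences by their power spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectraclust)
```

## The model

`spectraclust` compares nucleotide sequences without aligning them. A
sequence of length $L$ is mapped to four binary indicator channels
$\hat{X}_1 \dots \hat{X}_4$ (order A, G, C, T), each with a 1 where that
base occurs — the Voss representation. Each channel is zero-padded to a
common length $n$ and transformed with the unnormalized DFT
$U_c[q] = \sum_{t=0}^{n-1} \hat{X}_c[t]\, e^{-2\pi i qt/n}$; the sequence's
descriptor is the summed power spectral density

$$S[q] \;=\; \sum_{c=1}^{4} \lvert U_c[q] \rvert^2, \qquad q = 0,\dots,n-1 .$$

$S$ captures the periodic patterning of the bases (codon-frame structure,
repeats, composition) and is invariant to cyclic shifts of the sequence,
which is what makes the comparison alignment-free. Two sequences are
compared by the Euclidean distance between their spectra, and a set of
$m$ spectra $\Omega = [\omega_1,\dots,\omega_m]$ is partitioned by
K-means:

* initialization assigns each observation a uniformly random label in
  $1..k$ (all $k$ labels guaranteed present);
* centroids are element-wise means of their members; assignment is by
  nearest centroid under Euclidean distance;
* the whole run is repeated for 50 independent restarts and the restart
  with the smallest total within-cluster sum of *squared* distances is
  kept.

The result is visualized radially. With $M$ the unweighted mean of the
$k$ centroids, each centroid's distance $d_j = \lVert C_j - M\rVert$ is
computed, clusters are sorted by $d$ ascending, and sorted index
$\iota \in \{0,\dots,k-1\}$ receives angle $\theta_\iota = \iota\,2\pi/k$,
position $(d_\iota\cos\theta_\iota,\; d_\iota\sin\theta_\iota)$. Each
sequence is then placed around its own centroid at radius
$\delta_z = \lVert \omega_z - C_\iota \rVert$ and angle
$\theta_z = \mathrm{rank}(z)\,2\pi/m_\iota$ (rank by $\delta_z$ ascending
within the cluster, $m_\iota$ members). All radii are true distances in
spectrum space; the angular coordinate is purely ordinal.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `psd_length` / `n` | `"auto"` (max sequence length) | common spectrum length; bins are unitless frequency indices $q/n$ cycles/base. A fixed value (e.g. 4100) makes runs on different subsets comparable. Sequences longer than an explicit `n` are an error — never truncated. |
| `drop_dc` | `FALSE` | the DC bin $S[0] = \sum_c (\text{count of base } c)^2$ carries only base composition and dominates magnitudes; the flag zeroes it when composition should not drive the clustering. |
| `k` | — | number of clusters; the method is intended to be run at several values (e.g. number of kingdoms/phyla/classes) and compared. |
| `restarts` | 50 | independent random-label restarts; best objective kept. |
| `max_iter` | 300 | per-restart cap; convergence is *unchanged labels*, typically reached in well under 30 iterations. |
| `seed` | — | one master seed; restart seeds are derived from it, so results are bit-reproducible. |

## Numerical and design choices

* **PSD convention.** The spectrum is the *full two-sided* length-$n$
  vector of unnormalized squared DFT magnitudes, summed over channels.
  No normalization by sequence length is applied; total power obeys
  Parseval's identity $\sum_q S[q] = n \cdot (\text{unambiguous length})$,
  which the tests assert to 1e-9 relative tolerance. Consequently longer
  sequences carry more spectral mass — a deliberate property shared with
  the padding convention (padding preserves all information; a common $n$
  is required for Euclidean comparison).
* **Ambiguity codes.** IUPAC ambiguity characters (and N) are accepted at
  parse time, mapped to zero in all four channels, and counted; `U` is
  read as `T`. No fractional encoding is attempted.
* **Objective.** The clustering minimizes the sum of *squared* Euclidean
  distances. Centroid-as-mean is only optimal for the squared objective,
  so the squared form is the internally consistent reading of
  "minimize the total distance to centroids"; "best convergence score"
  across restarts is taken to mean minimal final objective.
* **Empty clusters.** If an assignment step empties a cluster, its
  centroid is reseeded to the point farthest from the cluster's previous
  centroid and that point joins the cluster. This keeps $k$ clusters and
  preserves the monotone decrease of the objective, which every logged
  restart trace is tested for.
* **Ties.** Assignment ties go to the lowest cluster index; distance ties
  in the layout sort go to the lower original index (clusters) or input
  order (sequences). Both rules exist purely for determinism.
* **Angle index range.** The layout assigns $k$ distinct angles
  $\iota = 0,\dots,k-1$; an index of $k$ would duplicate the angle 0.
* **Within-cluster angles.** The per-sequence angle formula mirrors the
  per-cluster one with $k$ replaced by the cluster size — the only
  reading that keeps member angles distinct. Sequences may legitimately
  overlap cluster rays; no jitter is applied, because radius readability
  (compactness = relatedness) is the point of the plot.
* **Labels.** Internally clusters are 1-based (the R convention); all
  outputs use `C-1 … C-k`. `cmd_cluster` renumbers clusters by distance
  to the main centroid before writing, so `C-1` in the assignments table
  is the innermost cluster of the plot.
* **Reference comparison.** "Mean squared distance between a cluster
  centroid and the sequences assigned to it" is read as the member-mean:
  entry $(j, c) = \frac{1}{m_j}\sum_{z \in j}\lVert\omega_z - c\rVert^2$,
  with the cluster's own centroid as the first column. Because the
  construction could also be read centroid-to-centroid, that cheaper
  matrix is exported alongside (`centroid_distances`), clearly labeled.

## What the synthetic generator emulates — and what it does not

`generate_family()` draws one ancestor per family (a tiled motif such as
`AT` or `ACA`, or a composition-weighted random sequence) and then $n$
descendants by independent per-site substitution with probability $\mu$,
uniform over the three alternative bases. This produces families with
controlled within-family spectral spread and strong between-family
separation: a period-2 ancestor concentrates power at $q = n/2$, a
period-3 ancestor at $q \approx n/3$, and a random ancestor spreads power
broadly, so the three standard test families are separable by
construction. Defaults for the end-to-end tests are 15 sequences × 300 bp
per family at $\mu = 0.02$ — the scale of a conserved barcode-marker
family with a few percent divergence.

What it does **not** emulate: indels (members of a family share length —
length variation in real markers, and the spurious length-driven clusters
it can create, are exercised only through cross-family length
differences), phylogenetic correlation structure (all descendants are
independent draws from the ancestor), transition/transversion bias, and
composition heterogeneity along the sequence. A green planted-recovery
test therefore establishes that the pipeline separates families whose
spectra differ strongly; it does not establish taxonomic accuracy on real
markers, where between-group spectral distances can be comparable to
within-group spread.

## Known limitations

* K-means with random restarts is a heuristic; on small instances the
  tests verify it attains the exhaustively enumerated optimum, but there
  is no such guarantee at realistic sizes — only the best of 50 restarts.
* The unnormalized, DC-inclusive spectrum makes sequence length and base
  composition strong clustering signals. That is faithful to the method
  (it is exactly why unusually short gene copies form their own cluster),
  but `drop_dc = TRUE` and a fixed `psd_length` are the right settings
  when that behavior is unwanted.
* Whether the spectrum should be one-sided and/or length-normalized is
  genuinely open; the two-sided unnormalized convention is fixed here and
  documented, and distances are comparable only between runs using the
  same convention and the same $n$.
* The radial plot encodes distance, not topology: two clusters at similar
  radii are not necessarily similar to each other, only similarly far
  from the main centroid.
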