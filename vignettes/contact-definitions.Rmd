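---
title: "Contact definitions and the evaluation of evolutionary couplings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact definitions and the evaluation of evolutionary couplings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eccontacts)
```

## The problem

Evolutionary coupling (EC) analysis scores pairs of columns in a protein
multiple-sequence alignment by their direct covariation and predicts that
high-scoring pairs are spatially close in the folded structure. Benchmarks of
EC methods therefore need a set of "true" residue–residue contacts derived
from a reference structure — and there is no single agreed way to derive one.
A residue pair can be called a contact based on the distance between their
Cα atoms, their Cβ atoms, the geometric centers of their side chains, or the
minimum distance over heavy-atom pairs (all atoms, or side-chain atoms only).
These definitions agree on the broad shape of the distance matrix but
disagree substantially exactly in the short-distance regime where contacts
are defined, so the choice changes both the benchmark outcome and its
biological reading: if couplings preferentially recover side-chain-defined
contacts, the underlying epistasis acts through side-chain interactions.

This package implements the full comparison pipeline: structure cleaning,
the five distance definitions, fixed and count-matched contact maps,
side-chain orientation classification, a transparent coupling scorer plus
readers for externally computed coupling matrices, ranking evaluation (PPV
and average precision), paired method comparison, and a synthetic-data
generator with planted covariation that makes every stage testable without
external datasets.

## Contact definitions

For a cleaned single chain with residues numbered $1..L$, the package
computes a symmetric $L \times L$ distance matrix under one of five
reference methods:

* **CA** — distance between Cα atoms.
* **CB** — distance between Cβ atoms; glycine, which has no Cβ, falls back
  to Cα.
* **SC_CENTER** — distance between side-chain geometric centers: the
  unweighted mean of all non-backbone heavy atoms (Cβ included, Cα
  excluded); glycine again falls back to Cα. The unweighted mean depends
  only on atom positions, not on atomic masses.
* **MIN_ALL** — minimum distance over all heavy-atom pairs of the two
  residues.
* **MIN_SC** — minimum distance over side-chain heavy atoms only (glycine
  contributes its Cα).

Backbone means N, CA, C, O and the terminal OXT; everything else, including
Cβ, is side chain. A contact map keeps the pairs with chain separation
$j - i \ge$ `min_sep` (default 12, so pair (1, 13) is the closest eligible
pair) whose distance is at most a cutoff. Two cutoff regimes are supported:

* **fixed** — one cutoff per method (defaults 8 Å for CA, 7.6 Å for CB,
  7.5 Å for SC_CENTER, 4.5 Å for the minimum-distance methods);
* **matched** — the CA 8 Å map defines a count $n$, and every other method
  selects its $n$ shortest eligible pairs, so that positive predictive
  values are comparable across definitions without normalising for contact
  density. The $n$-th smallest distance is reported as the effective
  cutoff.

Distances are compared inclusively (`<=`), and matched selection breaks ties
deterministically by (distance, $i$, $j$), so a map is reproducible across
platforms. Agreement between two definitions is summarised by the fraction
of shared pairs in count-matched maps and by the Spearman correlation of the
eligible-pair distance vectors.

## Side-chain orientations

For a residue pair $(a, b)$, draw the vector from Cα$_a$ to the side-chain
center of $a$ and the vector from Cα$_a$ to Cα$_b$. If the angle between
them is strictly less than $\pi/2$ (positive dot product), the side chain of
$a$ points toward $b$. Repeating from $b$ classifies the pair as
*both_toward* (type i), *mixed* (type ii), or *both_away* (type iii). For
side-chain directions distributed isotropically and independently of the
inter-residue geometry, the expected composition is $\{1/4, 1/2, 1/4\}$.

Glycine needs a convention: its side-chain center coincides with Cα, the
orientation vector has length zero and the angle is undefined. The zero dot
product fails the strict test, so a glycine side is classified as *not*
pointing toward its partner; summaries accept `exclude_glycine = TRUE` to
drop glycine-containing pairs instead. The default keeps every pair
classifiable, at the cost of biasing the all-pairs composition away from
$\{1/4, 1/2, 1/4\}$ in proportion to glycine content; tests of the isotropic
expectation therefore exclude glycine.

## Coupling scores

The package does not reimplement global inverse-model methods
(pseudolikelihood Potts models, sparse inverse covariance). It provides:

* readers for externally computed scores — plain whitespace-separated
  $L \times L$ matrices (asymmetric input is symmetrised by the elementwise
  maximum) and 1-based `i j score` edge lists;
* a transparent local scorer: mutual information with average product
  correction (MI+APC) and identity-based sequence reweighting.

For columns $i, j$ with weighted frequencies $f$ over a 21-state alphabet
(20 amino acids + gap, the gap kept as a state so the per-column observation
count stays constant; `treat_gaps = "exclude"` renormalises per pair
instead),

$$\mathrm{MI}_{ij} = \sum_{a,b} f_{ij}(a,b)\,
  \ln\frac{f_{ij}(a,b)}{f_i(a) f_j(b)}, \qquad
  S_{ij} = \mathrm{MI}_{ij} - \frac{\bar M_i \bar M_j}{\bar M},$$

where $\bar M_i$ is the mean MI of column $i$ against all others and
$\bar M$ the grand mean over off-diagonal entries (the average product
correction). Sequence weights follow the standard identity clustering: the
weight of a sequence is the reciprocal of the number of sequences (itself
included) with fractional identity at least 0.8.

Numerical choices:

* pseudocount 0.5 per state per column, with the pair pseudocount set to
  $\lambda/21$ per cell so pair and single frequencies share a normaliser;
  `pseudocount = 0` gives the plug-in estimator with $0 \ln 0 = 0$;
* `bias_correction = TRUE` applies the Miller–Madow correction
  $(m_{ij} - m_i - m_j + 1)/(2 N_\mathrm{eff})$, where $m$ counts occupied
  cells. The plug-in estimator's upward bias, about $q^2/2N \approx 0.036$
  nats at $N = 5000$, is material when estimates are compared against
  analytic MI values; with the correction the comparison is tight to well
  under 0.01 nats. The correction is intended for such oracle comparisons
  with `pseudocount = 0`, not for ranking (APC removes shared background,
  and ranking is invariant to it);
* rankings are restricted to pairs with separation $\ge$ `min_sep` *before*
  taking the top $k$ — the same restriction applied to contacts — so that
  the PPV numerator and denominator count the same pair universe. $k$
  defaults to $\lfloor L/2 \rfloor$;
* ranking ties break by $(i, j)$, deterministically.

## Evaluation

PPV at depth $k$ is the fraction of the $k$ highest-scoring eligible pairs
that are contacts. Average precision,
$\mathrm{AP} = \sum_k (R_k - R_{k-1}) P_k$, summarises the full ranking and
is less sensitive to the contact count, which matters in the fixed-cutoff
regime where methods yield different numbers of contacts. Two contact
definitions are compared across replicate proteins with a two-sided Wilcoxon
signed-rank test on paired accuracies (exact null below 25 pairs, normal
approximation with continuity correction above) together with the median of
per-protein accuracy ratios, reported as a percent increase. All-zero
difference vectors are rejected as degenerate rather than assigned a
p-value.

## The synthetic-data generator

`synth_structure()` grows a self-avoiding Cα trace with 3.8 Å consecutive
spacing inside a confinement sphere of radius `compactness` $\cdot L^{1/3}$,
then attaches to every non-glycine residue a Cβ at 1.5 Å plus 1–3 further
pseudo side-chain atoms at up to 4 Å along an isotropically drawn
per-residue direction. Amino acids are uniform over the 20 types. If the
walk jams repeatedly at the target density, the radius inflates by 5% per
block of failed restarts before a hard error; all draws derive from the
seed, so structures are reproducible.

`synth_alignment()` plants pairwise covariation at structural contacts:
starting from the contacts of the chosen definition (count-matched to the
CA 8 Å map), pairs are thinned to a pairing in which each site belongs to at
most one pair, and for each planted pair $(i, j)$ each sequence
independently links $s_j = \pi_{ij}(s_i)$ through a fixed random bijection
with probability $c$, drawing both sites uniformly and independently
otherwise. Sequences are i.i.d. — no phylogeny — and gap-free. Because each
site sits in at most one planted pair, the joint distribution of a planted
pair is known exactly and its mutual information has the closed form

$$\mathrm{MI}(c) = \left(c + \frac{1-c}{q}\right) \ln(cq + 1 - c)
  + (1-c)\left(1 - \frac{1}{q}\right) \ln(1-c), \quad q = 20,$$

implemented as `planted_mi()`; $\mathrm{MI}(0) = 0$ and
$\mathrm{MI}(1) = \ln 20 \approx 3.0$ nats. This gives the package an
analytic oracle: empirical planted-pair MI must converge to
$\mathrm{MI}(c)$, and the test suite checks it at $c \in \{0, 0.5, 1\}$,
$N = 5000$ within 0.05 nats.

Two generator design points deserve emphasis:

* **One pair per site.** Allowing a site to join several planted pairs
  would create higher-order dependencies requiring a Potts Gibbs sampler,
  and the planted MI would no longer be available in closed form. The cost
  is a cap: at most $\lfloor L/2 \rfloor$ pairs can be planted, exactly the
  conventional evaluation depth. The planted set is therefore chosen as a
  large matching of the contact graph — greedily matching the free site
  with the fewest free partners, then improving with length-3 augmenting
  paths — rather than greedily by distance, which leaves a third of the
  possible pairs unplanted and caps top-$L/2$ recovery around 0.75 even
  for a perfect method. On the generated contact graphs the heuristic
  matched the exact maximum matching in every case we checked.
* **Compactness.** The default confinement scale 2.8 packs the toy chains
  densely enough that essentially every site carries eligible long-range
  side-chain contacts, so a near-complete pairing exists. The resulting
  long-range contact density (3–4 contacts per residue at separation
  $\ge 12$) is higher than in natural globular proteins (roughly 1.5); the
  generator trades that realism for a testbed in which near-perfect
  recovery of the planted definition is attainable and failures are
  attributable to the method, not to the planting.

What the generator emulates: structures in which different contact
definitions overlap only partially (as real structures do), and alignments
whose covariation sits exactly at the contacts of one chosen definition with
known strength. What it does not emulate: phylogenetic correlation between
sequences, gaps and alignment errors, thermodynamic or packing realism in
side-chain geometry, multi-body epistasis, and the indirect-correlation
structure that motivates global inverse methods (planted pairs are
site-disjoint, so MI sees no transitive chains). Passing tests on this
generator validates the pipeline's bookkeeping and statistics; it does not
certify performance of MI+APC on natural alignments, where global methods
are known to be stronger.

## Study conditions used by the tests and the acceptance script

The planted-recovery checks run at $L = 100$, $N = 3000$, $c = 0.7$,
planting on side-chain-center contacts: with
$\mathrm{MI}(0.7) \approx 1.56$ nats against a noise floor around
$10^{-2}$, recovery of the planted definition saturates, and the contrast
with the CA definition isolates the definition effect. The
recovery-versus-depth trend is instead checked at $c = 0.15$
($\mathrm{MI} \approx 0.13$ nats), chosen from the closed form so that
detection crosses its threshold inside the tested range
$N \in \{100, 500, 1000, 3000\}$ — at $c = 0.7$ the curve is already flat
near its ceiling at $N = 100$. The MI oracle uses $N = 5000$ and $L = 60$.
These sizes keep the default test suite and the acceptance script at a few
tens of seconds on one CPU.

The worked example on PDB entry 1AOE (chain A, $L = 192$: 295 CA contacts
at 8 Å, a matched side-chain-center cutoff of 7.33 Å, 56% overlap) and the
150-protein benchmark medians are asserted in the acceptance tests but
require the corresponding PDB files on disk under `tests/testthat/data/`;
they are not redistributed with the package.

## Degenerate inputs and edge cases

* Residues missing their entire side chain (or Cβ under the CB method) are
  a hard error by default; `missing_sidechain = "ca"` substitutes Cα with a
  warning. Silent substitution is avoided because it changes contact maps.
  The package never rebuilds missing atoms.
* Alternate locations keep the highest occupancy, ties broken by altloc
  identifier; MSE/SEC map to MET/CYS only when `map_nonstandard = TRUE`;
  any other non-standard residue is an error naming the residue.
* Ambiguity codes (B, Z, X) in alignments count as gaps by default.
* `contacts_matched` refuses $n$ larger than the eligible-pair count;
  `overlap_fraction` refuses maps with unequal counts; Spearman correlation
  refuses fewer than 3 eligible pairs; `paired_comparison` refuses fewer
  than 5 pairs and all-zero differences.

## Limitations

The MI+APC scorer is a local statistic and underperforms pseudolikelihood
and inverse-covariance methods on natural alignments; it is the package's
transparent stand-in and the interface through which external score
matrices are evaluated, not a contribution to coupling inference. Empirical
accuracy distributions over protein families depend on homolog retrieval
and alignment pipelines that are out of scope here. The toy structures have
no real backbone beyond Cα, so MIN_ALL on synthetic data reduces to a
minimum over Cα plus pseudo side-chain atoms.
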