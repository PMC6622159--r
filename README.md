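# eccontacts

Evaluating evolutionary couplings against alternative residue–residue
contact definitions.

## What this is for

Evolutionary coupling (EC) analysis scores pairs of columns in a protein
multiple-sequence alignment by their direct covariation; high-scoring pairs
tend to be spatially close in the folded structure, and EC methods are
routinely benchmarked by how many of their top-ranked pairs are "true"
contacts in a reference structure. But *true contact* is not a standardized
notion: a pair can be called a contact from the distance between Cα atoms,
Cβ atoms, side-chain geometric centers, or the minimum heavy-atom distance
(over all atoms, or side-chain atoms only). These definitions overlap only
partially exactly in the short-distance regime where contacts live, so the
choice changes benchmark outcomes — and carries biological meaning: if
couplings preferentially recover side-chain-defined contacts, the epistasis
they detect acts through side-chain interactions.

`eccontacts` is an R package for structural bioinformaticians who want to
run this comparison on their own structures and couplings, or to study it in
a controlled setting. It provides:

- **Structure handling** — PDB cleaning (single chain, heavy atoms, one
  altloc, standard residues, 1..L renumbering) via `load_structure()`.
- **Contact geometry** — distance matrices under five reference methods
  (`CA`, `CB`, `SC_CENTER`, `MIN_ALL`, `MIN_SC`), contact maps at fixed
  cutoffs (`contacts_fixed()`, e.g. the conventional CA 8 Å rule, chain
  separation ≥ 12) or count-matched across methods (`contacts_matched()`),
  plus overlap fractions and Spearman distance correlations.
- **Side-chain orientations** — the strict-π/2 vector test classifying each
  pair as both side chains pointing toward each other / mixed / both away
  (`classify_pairs()`, `orientation_summary()`).
- **Coupling scores** — readers for externally computed L×L score matrices
  and edge lists, and a transparent mutual-information scorer with average
  product correction and 0.8-identity sequence reweighting (`mi_apc()`,
  `sequence_weights()`).
- **Evaluation** — PPV of the top L/2 couplings (`ppv_top_k()`), average
  precision (`average_precision()`), and paired Wilcoxon comparison of
  contact definitions across proteins (`paired_comparison()`).
- **Synthetic data** — toy structures and alignments with covariation of
  known strength `c` planted at the contacts of a chosen definition
  (`synth_structure()`, `synth_alignment()`), with the analytic
  mutual-information oracle `planted_mi(c)`.
- **Pipeline** — `run_config()`, `run_contacts()`, `run_eval()` orchestrate
  the stages and write deterministic text reports; a thin command-line
  front end ships in `inst/scripts/eccontacts`.

The central quantity is the positive predictive value at depth L/2: with
eligible pairs restricted to chain separation ≥ 12 and ranked by coupling
score,

PPV@L/2 = |top-⌊L/2⌋ pairs ∩ contacts| / ⌊L/2⌋,

compared across contact definitions whose maps are count-matched so the
PPVs are directly comparable.

## Worked example

Generate a toy protein with covariation planted at its side-chain-center
contacts, score the alignment with MI+APC, and evaluate the ranking against
three contact definitions:

```r
library(eccontacts)

p   <- synth_params(L = 60, N = 1500, c = 0.7, planted_on = "SC_CENTER", seed = 42)
s   <- synth_structure(p)
aln <- synth_alignment(s, p)

cfg <- run_config(s, alignment = aln, reweight = FALSE,
                  methods = c("CA", "CB", "SC_CENTER"),
                  output_dir = file.path(tempdir(), "demo"))
run_contacts(cfg)
#> contact_report: L = 60
#> contacts: CA=197 CB=197 SC_CENTER=197
#> effective cutoffs (A): CA=8 CB=8.2 SC_CENTER=8.41
#> pairwise contact overlap:
#>              CA    CB SC_CENTER
#> CA        1.000 0.787     0.690
#> CB        0.787 1.000     0.888
#> SC_CENTER 0.690 0.888     1.000
run_eval(cfg)
#> eval_report: L = 60 | k = 30
#>     method  k   ppv average_precision n_true
#>         CA 30 0.467             0.201    197
#>         CB 30 0.700             0.258    197
#>  SC_CENTER 30 0.900             0.316    197
#>
#> orientation (both_toward fraction):
#>                 set n_pairs both_toward
#>           all_pairs    1176       0.165
#>         contacts_CA     197       0.208
#>         contacts_CB     197       0.350
#>  contacts_SC_CENTER     197       0.391
#>           top_0.25L      15       0.133
#>            top_0.5L      30       0.233
#>              top_1L      60       0.200
```

Reading the output: the three definitions were count-matched to the 197
contacts of the CA 8 Å rule (the matched cutoffs for CB and side-chain
centers come out at 8.2 and 8.41 Å for this toy protein), yet only 69% of
CA contacts coincide with side-chain-center contacts. The same ranked
couplings recover side-chain-center contacts far better (PPV 0.90 at top
L/2 = 30) than CA contacts (0.47) — the couplings were planted on
side-chain-center contacts, and the CA definition misses the part of that
signal outside its own map. Contacts defined via side-chain centers are also
progressively enriched in pairs whose side chains point toward one another
(0.391 vs 0.208 for CA and 0.165 among all eligible pairs).

The same pipeline runs on real data: point `run_config()` at a PDB file
plus either a FASTA/A2M alignment (scored with MI+APC) or a precomputed
coupling matrix in plain L×L text.

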