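---
title: "Methods: physicochemical profiling and abundance-weighted correlation screening of urinary protein fractions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physicochemical profiling and abundance-weighted correlation screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stonescreen)
```

## The scientific setting

Calcium oxalate (CaOx) is the dominant crystalline phase of kidney stones.
Urinary proteins interact with CaOx crystals at every stage of stone
formation — nucleation (crystallization), growth, crystal–crystal
aggregation, and adhesion of crystals to renal epithelium — and may promote
or inhibit each stage. A common experimental design fractionates the pooled
urinary proteome by anion-exchange chromatography (fractions of decreasing
isoelectric point), measures each fraction's effect in four in-vitro crystal
assays, identifies the proteins of each fraction by MS/MS with relative
abundances, and asks which sequence-derived properties of the proteins track
the fractions' activities.

`stonescreen` implements the computational half of that design as a tested,
reusable pipeline: descriptor profiling, activity quantification, abundance
weighting, and a Spearman/Benjamini–Hochberg correlation screen, plus a
synthetic-data generator so that every stage is verifiable without any
external data.

## Descriptors and their parameters

All descriptors are computed from the 20 standard residues only; sequences
containing other letters are rejected by default, or stripped under the
explicit `skip_residue` policy (silent substitution would bias every
table-based descriptor).

* **Molecular weight** — sum of average (isotope-abundance-weighted) residue
  masses plus one water (18.01524 Da). Average rather than monoisotopic
  masses match the convention of sequence-property servers. Posttranslational
  modifications are out of scope.
* **Theoretical pI** — root of the Henderson–Hasselbalch net charge over the
  termini and the D, E, C, Y, H, K, R side chains, found by bisection on
  [0, 14] to 10^-3 pH. The default pKa set is the Bjellqvist set including
  residue-specific terminal overrides (e.g. an alanine N-terminus at 7.59).
  With both termini always ionizable, the charge is strictly decreasing from
  positive to negative across the interval, so bisection cannot fail.
* **GRAVY** — mean Kyte–Doolittle hydropathy; < 0 is hydrophilic.
* **Instability index** — (10/L)·Σ over the L−1 dipeptides of the Guruprasad
  DIWV weight, unlisted dipeptides weighing 1.0. Note the published DIWV
  table has negative entries, so short acid-rich sequences score below zero;
  all values below 40 are classed stable.
* **Composition** — fractions of residues in five classes. The four
  charge/polarity classes must partition the 20 residues (validated at
  scheme construction); aromatic overlaps them and is reported separately.
  The default partition (positive {K,R,H}, negative {D,E}, polar
  {S,T,N,Q,C,Y,G}, nonpolar {A,V,L,I,P,M,F,W}, aromatic {F,W,Y}) is one
  defensible choice among several — whether histidine is "positive", or
  glycine "polar", varies between textbooks — so the scheme is fully
  configurable and recorded in outputs.
* **Threshold classes** — low/high MW at 50 kDa, stable/unstable at
  instability 40, hydrophilic/hydrophobic at GRAVY 0. The conventional
  definitions use strict inequalities on both sides and leave the boundary
  undefined; this package resolves all three boundaries upward
  (≥ threshold → high/unstable/hydrophobic), a single consistent rule on a
  measure-zero set.
* **Oxalate-binding motifs** — PROSITE-syntax patterns scanned over the
  sequence. Under the default `all_starts` mode every start position whose
  window can satisfy the pattern yields one hit, with variable-range
  elements matched shortest-first (deterministic and directly checkable
  against a brute-force matcher); `non_overlapping` gives greedy disjoint
  hits for sensitivity analysis. The shipped motif file is a synthetic
  placeholder so the pipeline runs self-contained; every manifest records
  the motif-file checksum, and real analyses must substitute the published
  oxalate-binding motif definitions.
* **Calcium-binding sites** — counted from UniProt flat-text features:
  BINDING features with ligand Ca(2+) and legacy CA_BIND spans (overlaps
  merged and counted once), plus DOMAIN features whose description contains
  "calcium-binding". Each component of the rule can be switched off.
* **Secondary structure** — each residue takes the argmax over four states
  of window-averaged propensities (default window 17, truncated at the
  termini; ties resolved helix > strand > turn > coil). The helix and strand
  columns of the shipped table are Chou–Fasman conformational propensities;
  the coil column reuses the aperiodic propensity and the turn column is the
  normalized per-residue turn occurrence probability. This is deliberately a
  transparent single-sequence stand-in, **not** a reimplementation of
  database-trained predictors (SOPMA and kin): such tools depend on curated
  alignment databases and are not reproducible from a propensity table.
  Their output can be imported verbatim with `import_ss()` (fraction tables
  or per-residue H/E/T/C strings), and any comparison against numbers
  produced with such tools must use the imported path.

## Activity quantification

Each assay readout (crystal counts per field, crystal size, aggregate
counts, adherent crystals) is converted per replicate to
`100·(x_i − mean(ref))/mean(ref)`; the fraction's activity is the replicate
mean ± SEM. The reference defaults to the negative control (an inert protein
at matched concentration) rather than the blank, because fraction effects
are conventionally stated against a protein-matched control; the blank is
available by configuration. Replicates are independent experiments; no
pairing with specific reference replicates is assumed. The replicate-level
tidy table (`compare_to_reference()`) feeds any standard multiple-comparison
test; the package deliberately implements none (ANOVA, Tukey and
Kruskal–Wallis are available in base R).

## The correlation screen

Within each fraction, MS intensities are normalized to weights summing to 1.
The screen has 22 property rows × 4 activity columns in two natural units of
analysis:

* **Per-protein descriptors** (MW, pI-free descriptors, instability, GRAVY,
  composition, secondary structure, binding counts per protein) are pooled
  over protein-in-fraction entries: x_i = w_i·P_i against
  y_i = w_i·A_f(i), n = Σ fraction sizes (348 under the default design).
  Assigning the whole-fraction activity to each member protein scaled by its
  weight is the only construction by which per-protein abundance can enter
  an activity measured once per fraction; it is a reconstruction, and its
  statistical consequences are analyzed below.
* **Percentage-type rows** (share of calcium-binding, oxalate-binding,
  low/high-MW, stable/unstable, hydrophilic/hydrophobic proteins) exist only
  per fraction; the abundance-weighted share (summed weights of qualifying
  proteins) is correlated against the fraction activities, n = number of
  fractions.

rs is the Pearson correlation of mid-ranks (average ranks on ties); p values
use the t approximation with n−2 degrees of freedom, with an exact
permutation option for fraction-level cells (n ≤ 9). Constant inputs yield a
flagged NA cell excluded from adjustment. The BH family is all non-NA cells
of one screen (88 by default; per-activity families by configuration).
Significance requires both p_adj < 0.05 and |rs| > 0.8 — the rationale for
the |rs| gate is that at n ≈ 350 even tiny correlations are "significant" by
p value alone.

## The synthetic study and what it does (not) show

`simulation_config()` defaults define the emulated study: 9 fractions of
10, 12, 71, 71, 60, 55, 25, 38, 6 proteins; sequence lengths uniform on
80–7000 residues; residues drawn iid from Swiss-Prot background
frequencies; log-normal within-fraction intensities (sdlog 2, spanning
roughly 3–4 orders of magnitude, typical of MS relative-abundance tables);
3 replicates per assay condition with 3% CV replicate noise; per-assay true
activity ranges matching the observed spans (crystallization −18–23%, growth
−10–65%, aggregation 178–320%, adhesion 45–57%). A planted link makes a
fraction's true activity a strictly increasing (min-max-scaled) function of
its abundance-weighted descriptor mean, mixed with an independent uniform
component in proportion 1 − strength.

The generator reproduces the study's *dimensions and scales*, not its
biology: real urinary proteomes have right-skewed length distributions
(mean MW ~90 kDa rather than the ~400 kDa of uniform lengths), real
sequences are not iid (so the synthetic instability distribution sits lower
than in real urine), and proteins can recur across fractions whereas
synthetic proteins belong to exactly one. Passing tests therefore
demonstrate correctness of the computations and recoverability of planted
structure — not that real data will behave comparably.

## The shared-weight confound

The pooled unit multiplies both screen variables by the same weight w_i.
Because log-normal weights vary over orders of magnitude while bounded
descriptors (composition and secondary-structure fractions, instability)
and positive-baseline activities (aggregation, adhesion) vary over narrow
ranges, the pooled ranks of both x = w·P and y = w·A are dominated by the
shared w, and rs approaches 1 *regardless of any real link*. Descriptors of
predominantly negative sign (GRAVY in a hydrophilic proteome) acquire the
mirrored negative correlation. Null simulations with this package
(`simulate_recovery()`, which screens planted and link-free datasets from
the same proteomes) show unplanted bounded-descriptor × positive-assay
cells flagged in essentially all null replicates, while wide-ranged or
sign-varying pairs stay quiet. Planted links at the fraction level are
recovered reliably (a strength-0.9 MW → aggregation link is flagged in 100%
of replicates), but recovery cannot be distinguished from the confound for
bounded descriptors.

Practical consequences: treat pooled abundance-weighted correlations as a
descriptive ranking, compare them against the package's own null
calibration at matched weight dispersion before interpreting any cell, and
use `unit = "fraction"` (weighted fraction means, n = number of fractions)
as the inferentially safer sensitivity analysis — it has far less power but
no shared-weight term.

## Numerical and engineering choices

* Bisection tolerance 10^-3 pH for pI (checked against a 10^-3-step grid
  scan to 0.01 pH); double-precision rank statistics; perfect monotone
  inputs report the smallest representable positive p rather than 0 so that
  downstream adjustment stays in (0, 1].
* Motif scanning compiles PROSITE patterns to lazy lookahead regular
  expressions (all start positions, shortest satisfying span per start); the
  test suite checks equality with a recursive brute-force matcher.
* All generators are seeded; identical configuration + seed reproduces every
  file byte-identically. The run manifest records tool version, the full
  configuration snapshot, and input checksums (its timestamp line is the one
  permitted difference between reruns).
* Validation problem sizes: the Monte-Carlo recovery study uses 200
  replicates of the full 348-entry design (each replicate re-generates and
  re-profiles its proteome and screens one planted and one null dataset);
  oracle comparisons use exhaustive enumeration at small n (all sequences of
  length ≤ 4 over a 3-letter alphabet for the instability oracle, 200
  random 50-mers for the motif oracle, 1000 random tied vectors for the
  rank-correlation oracle).

## Known limitations

* The built-in secondary-structure predictor is a propensity heuristic; its
  absolute state fractions are not comparable to database-trained tools.
* The shipped oxalate-motif set is a placeholder; motif counts are only
  meaningful once the published definitions are supplied.
* The exact composition classes behind published composition percentages
  vary between tools; the default scheme is configurable precisely because
  no single partition is canonical.
* The abundance-weighted pooled screen carries the shared-weight confound
  analyzed above; this package quantifies it but cannot remove it without
  changing the method it implements.
* UniProt parsing targets the flat-text dialect only (stable, line-oriented,
  easy to fix); XML is out of scope.
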