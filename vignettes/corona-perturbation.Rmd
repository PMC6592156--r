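---
title: "Methods: perturbation profiling of the nanoparticle protein corona"
author: "coronashift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perturbation profiling of the nanoparticle protein corona}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

When nanoparticles meet blood plasma, a protein corona forms on their
surface within minutes. Binding is strikingly selective — a few hundred of
the >9000 plasma proteins — and, experimentally, a large fraction of corona
proteins stays bound even when the plasma solution is driven across wide pH
(4.9–8.9) and temperature (4–47 °C) ranges before particle addition.
`coronashift` implements the quantitative analysis of such perturbation
experiments: which proteins persist, which exchange, at what condition a
protein's binding flips, and which sequence-derived physicochemical
properties distinguish the persistent fraction from the plasma background.

The canonical design the package assumes is five condition values per axis,
three replicates each, plus matched particle-free controls processed
identically without particles.

# Quantification: Top3 with control subtraction

Peptide tables are long tables of
`(peptide, protein, condition, replicate, abundance)` with linear, strictly
positive abundances; absence is a missing row, never a zero. `top3()`
collapses them per (protein, condition, replicate) cell to the median of
the three most abundant peptides, and excludes cells with fewer than
`min_peptides = 3` quantified peptides. When exactly three peptides exist
the median and the middle of the top three coincide; with ties any three
maximal values give the same median (asserted by test).

`subtract_control()` corrects each sample cell by the matched control cell
*on the linear scale*, clamped at zero. Subtraction on the log scale would
correspond to division; linear subtraction matches the physical picture of
the control measuring additive non-specific carry-over. Choices pinned
here:

* a control cell (or protein, or whole condition) absent from the control
  is treated as zero carry-over; a condition present *only* in the control
  indicates mismatched experiments and errors out;
* a corrected value of exactly 0 is kept in the matrix but counts as
  non-detection downstream (no log10 value, no presence);
* correction is per replicate by default (`per_replicate = FALSE` switches
  to subtracting control condition means) — the per-replicate form uses all
  the information in the triplicate design.

Presence at a condition requires detection (corrected abundance > 0) in at
least `min_replicates = 2` of 3 replicates: tolerant to one replicate
dropout, strict enough to exclude singletons. The persistent set is the
intersection of presence across all conditions.

# Critical-condition profiling

For each persistent protein, all replicate log10 abundances are fit against
the condition $x$ with the 4-parameter logistic

$$A(x) = b + \frac{t - b}{1 + e^{s (x - x_c)}},$$

with lower/upper plateaus $b \le t$ (the parameterisation is canonicalised
after fitting; $(b, t, s) \to (t, b, -s)$ leaves the curve unchanged), slope
$s$, and midpoint $x_c$ — the **critical temperature / critical pH**, the
condition midway between the attached and detached states.

Numerical choices:

* **Optimiser.** Levenberg–Marquardt (`minpack.lm::nlsLM`) multi-started
  over a 9-point grid of $x_c$ across the condition range × both slope
  signs × two slope magnitudes (36 starts), with a Nelder–Mead fallback if
  every start fails. With only five design points, multi-start is what
  protects against local minima.
* **Observable-window constraint.** $x_c$ is box-constrained to
  [min condition − one step, max condition + one step], where "one step" is
  the adjacent design-point spacing at that end. A transition midpoint
  further out than that is not observed, only extrapolated; allowing it
  makes near-edge responders drift to meaningless extrapolated fits. A fit
  that nevertheless lands outside the window (possible via the fallback
  path) is demoted to flat.
* **Model selection.** A sigmoid verdict requires (i) fitted end-to-end
  change $|A(x_{max}) - A(x_{min})| \ge$ `amplitude_threshold` (default
  0.5 log10 units) and (ii) an F-test of the 4-parameter sigmoid against
  the 1-parameter flat model rejecting at `alpha = 0.05` (df 3 and
  $n - 4$). The end-to-end change, not the plateau separation $t - b$, is
  gated: the plateau separation can be large for a curve whose transition
  barely enters the observed range, which is an extrapolation artifact,
  not an observed abundance change. A constant profile short-circuits to
  flat.
* **Classes.** Flat verdict → Class I. Otherwise Class II if
  $x_c <$ boundary, Class III if $x_c \ge$ boundary, suffixed `-up`/`-down`
  by the direction of abundance change with increasing condition
  ($-\operatorname{sign}(s)$ under $t \ge b$). The boundary is the centre
  design point (30 °C, pH 6.8). A midpoint exactly on the boundary is
  Class III: Class II is defined as the strictly-below side, and since the
  boundary is itself a design point such ties are real and need a pinned
  rule.

`critical_correlation()` correlates fitted critical values with external
per-protein annotations (melting temperatures, isoelectric points) via
`cor.test`; in the synthetic study this serves as a negative control (a
random annotation must not correlate).

# Dispersion-lessening enrichment

Per-protein property values are the arithmetic mean of per-residue AAindex
values over residues the index scores (an index must score ≥15 of the 20
residues to be accepted; a protein value is missing if under half of its
residues are scored). The mean, not the sum, is used so protein length
does not confound the property (a sum-mode would rank long proteins high on
every extensive scale).

Dispersion is $D = P_{90} - P_{10}$ with linear interpolation between order
statistics (the common "linear"/type-7 convention — pinned because
percentile conventions genuinely differ on small $n$). The lessening ratio
is

$$L = D_{corona} / D_{plasma},$$

with $L < 1$ (*lessened*) meaning the persistent corona concentrates
proteins of similar property value, $L > 1$ (*widened*) meaning avoidance
of a property band. The background is the full supplied plasma proteome,
not only detected proteins.

**The permutation null** draws `n_perm` uniform random subsets of the
background of the persistent set's size and recomputes $L$ for each
(`method = "bootstrap"` resamples with replacement instead; subset
permutation is the default because the null hypothesis is exactly "the
persistent set is a random draw of plasma proteins"). Lessening and
widening are two one-sided alternatives and the direction is chosen by the
observed $L$; the reported p-value is therefore the observed-direction tail
**doubled** and capped at 1, with the $+1$ correction so sampled p-values
are never zero. An undoubled data-selected tail would satisfy
$P(p \le t) \approx 2t$ under the null and inflate the FDR; with doubling
the null p-values are stochastically ≥ uniform (verified by a
Kolmogorov–Smirnov check in the test suite) and Benjamini–Hochberg control
holds. For small backgrounds `exact = TRUE` enumerates all
$\binom{n}{m}$ subsets and reports the doubled exact tail.

`lessening_scan()` runs all properties against one shared stream of
resampled subsets — the null resamples *proteins*, so the same subsets
apply to every property — and applies BH once across all tested properties,
filtering at `q < 0.005`. Choose `n_perm` with the threshold in mind: the
smallest attainable doubled p is $2/(n_{perm}+1)$, so with $P$ properties
BH can only reach $q < 0.005$ when $n_{perm} \gtrsim 400 P$ divided by the
expected number of co-significant properties; the analysis scripts use
`n_perm = 2999` for 544 properties (many properties co-respond, so ranks
are large), while the FDR-calibration test uses 4999 for 20 properties so
that discoveries are attainable and control is genuinely exercised.

The direction of shift (is the corona fraction higher or lower in the
property?) is reported as the persistent-minus-background difference of
medians, with the mean difference alongside.

# The property tree

The 544 indices are organised in six categories — composition,
physicochemical properties, beta propensity, alpha and turn propensities,
hydrophobicity, other. When no curated accession → category table is
supplied, `categorize_indices()` assigns categories by keyword matching on
the index descriptions; this is a heuristic stand-in, and a two-column TSV
overrides it.

`build_mst()` computes Pearson correlations between index value vectors
over their shared scored residues (< 3 shared residues → missing edge, not
an error), weights edges $w = 1 - |r|$, and extracts the minimum spanning
tree with Kruskal's algorithm. Equal-weight edges are taken in
lexicographic accession-pair order, so the tree is identical across runs
and platforms; any strictly decreasing transform of $|r|$ yields the same
tree (asserted against `igraph::mst` under $1/|r|$). Missing edges can
disconnect the graph, in which case a spanning forest is returned with a
warning. Export is GraphML/DOT (via igraph, with category, $q$, $L$ and
direction as node attributes; `q = -1` encodes "not tested" since GraphML
has no NA) or a TSV edge list.

# The synthetic-data generator

`synthetic_design()` + `generate_proteome()` + `generate_experiment()`
emulate the study design so every downstream stage can be tested against
known truth. What is emulated, and the defaults:

* five conditions ({4, 17, 30, 41, 47} °C or {4.9, 6.1, 6.8, 7.7, 8.9} pH)
  × 3 replicates plus particle-free controls;
* 300 proteins, sequence lengths uniform on 100–600 residues, background
  residue frequencies from the average composition of reviewed UniProt
  proteins;
* 40% persistent; 40% of the persistent set are sigmoid responders with
  critical values uniform inside the condition range (5% margin),
  amplitudes uniform on 1–2.5 log10 units, slope magnitudes uniform on
  0.25–0.6 per °C (1.5–3 per pH unit — transition widths of a few degrees
  or a fraction of a pH unit), directions 50/50;
* non-persistent ("exchanged") proteins are absent — missing rows, never
  zeros — in 1–2 random conditions;
* peptide counts per protein follow a discrete triangular distribution
  (min 1, mode 5, max 12; median ≈ 5); each peptide carries a fixed
  Normal(0, 0.5) ionisation offset; replicate noise is i.i.d.
  Normal(0, 0.2) on log10 abundance; baselines are Normal(6, 1) log10;
* controls contain 5% of the realised sample abundance times independent
  multiplicative noise;
* optionally, the persistent set is *enriched* in a named amino-acid index:
  residue sampling weights are exponentially tilted,
  $w_a \propto f_a e^{\lambda v_a}$, with $\lambda$ solved (uniroot) so the
  expected per-residue index value shifts by the requested amount. The
  analysis scripts plant a +0.5 Kyte–Doolittle hydropathy shift, which both
  shifts and narrows the persistent set's per-protein hydropathy
  distribution — the signature the lessening scan must detect.

Everything is driven by one integer seed through ordered draws, so
identical designs give byte-identical outputs (tested).

What the generator does **not** emulate: peptide-level missingness and
identification error (every planted peptide is quantified, so synthetic
peptide quantification rates are near 100%, unlike real DDA data),
between-run intensity drift and alignment error, shared/razor peptides,
correlated replicate noise, and real plasma abundance structure (the
9–10 order-of-magnitude dynamic range is compressed to a Normal(6, 1)
baseline). Passing tests therefore demonstrate correctness of the
computations and recoverability under the stated noise model, not
performance on real LC-MS data.

# Problem sizes and runtime

The test suite and analysis scripts are sized for a single CPU: 300-protein
proteomes, 200-responder recovery runs, 2999–4999 permutations for
544- and 20-property scans respectively (19999 where a single property must
clear the 0.005 FDR on its own), 200-dataset FDR calibration, and
brute-force oracle enumerations up to 7-node graphs and 56-subset exact
permutation tails. The full suite runs in ~3 minutes, the acceptance
script in ~2.

# Known limitations

* The sigmoid model assumes a single transition; multiphasic behaviour is
  fit by its dominant transition.
* With five design points the F-test's null distribution is approximate at
  best for heteroscedastic replicate noise; the amplitude gate carries most
  of the selectivity.
* Category assignment by description keywords misclassifies indices whose
  descriptions are terse; supply a curated table for publication-grade
  trees.
* The enrichment background should be the full plasma database; using only
  detected proteins (supported via the `background` choice made by the
  caller) changes the meaning of $D_{plasma}$.
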