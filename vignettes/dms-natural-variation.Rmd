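---
title: "Methods: combining deep mutational scanning with natural variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combining deep mutational scanning with natural variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pabscan)
```

## The measurement model

A deep mutational scanning selection starts from a variant library,
grows it under conditions where the protein's function limits growth,
and sequences the library before (input) and after (selected). The
estimand for variant $v$ is its relative growth advantage, observed
through the enrichment ratio

$$r_v = \frac{(s_v/\Sigma s)/(i_v/\Sigma i)}{(s_{wt}/\Sigma s)/(i_{wt}/\Sigma i)},$$

the post/pre frequency ratio normalized to the wild type's. Because the
totals cancel against the wild-type term, $r_v$ reduces to
$(s_v/i_v)/(s_{wt}/i_{wt})$; we nevertheless compute it through the four
frequencies so that alternative normalizations (e.g. frequencies over
only filter-passing variants, exposed via the `totals` argument of
`compute_scores()`) remain expressible. Scores are stored on the linear
scale and log2 is derived, because epistasis multiplies linear scores
while every classification threshold is quoted in log2 — storing linear
avoids a double conversion.

Assumptions worth keeping in mind: selection acts multiplicatively on
frequencies over the growth period; sequencing draws are independent
multinomials at each time point; and the wild-type variant is deeply
enough sampled that its ratio contributes negligible noise. Variants
whose input coverage is too thin for a stable ratio are *flagged*, never
dropped, so denominators of downstream statements ("$k$ of $n$
catalogued substitutions scored") stay auditable.

## Tunable parameters

| parameter | default | scale | rationale |
|---|---|---|---|
| `min_input_reads` | 40 | reads | strict `>`; reliability cutoff for the in vivo scan. The stringent contamination analysis uses 500; the two-hybrid assay passes variants with at least 20 reads (`min_input_reads = 19`). |
| `synonymous_variance_max` | 0.4 | log2² | library QC bound on the synonymous score variance (unbiased sample variance; the choice of estimator is ours, as only the bound is standard). |
| `pseudocount` | 0.5 | reads | added to both counts of zero-selected variants only, keeping their scores finite without perturbing well-covered variants; 0 floors them at a sentinel instead. |
| `mild_threshold`, `strong_threshold` | −0.15, −0.5 | log2 | category bounds. Strongly deleterious is strict `< −0.5`; mildly is `[−0.5, −0.15)`. The half-open intervals make categories exhaustive and mutually exclusive where a verbal "between" is ambiguous at its endpoints. |
| `hit_threshold_log2` | −1 | log2 | two-hybrid hits are strict `< −1`, i.e. more than 50% loss. |
| `burial_cutoff` | 0.1 | fractional ASA | buried iff ASA ≤ 0.1, boundary inclusive. |
| `neighbor_radius` | 1 | residues | immediate sequence neighbourhood for hit categorization. |
| `epistasis_min` | 0.2 | linear score | compensatory-candidate floor; no standard numeric value exists for a "high" epistasis score, so this is configurable and deliberately permissive. |
| `bin_width` | 0.25 | log2 | reporting histograms of the contamination estimate. The estimate itself uses category masses, not bins, so it is bin-width-robust by construction. |

The scanned window is a **required** argument everywhere a window is
consumed: published descriptions of a scan often give its length but not
its exact first residue, so hard-coding a default would silently
misalign catalogues.

## Natural-substitution cataloguing

The alignment reader walks the reference row to map alignment columns to
1-based reference residue numbering; reference-gap columns map to
nothing. Within the window, every homologue residue differing from the
reference yields a catalogue entry keyed `(position, ref, alt)` with the
set of carrying homologues. Three rules keep the catalogue conservative:
a homologue **gap** facing a reference residue is not a substitution
(a residue that is simply absent from a homologue tells us nothing about
tolerating a replacement); **insertions** relative to the reference
contribute nothing; and **ambiguity codes** (X, B, Z, J, U, O) are
skipped. Percent identity counts matches over reference window columns,
with gap-vs-residue as mismatch.

## Contamination from the synonymous null

Synonymous variants encode the wild-type protein, so their score spread
is pure measurement noise. For each deleteriousness category,

$$\widehat{\text{contamination}} =
  \min\!\left(1, \frac{N_{nat}\cdot \Pr_{syn}(\text{category})}
  {\#\{\text{natural in category}\}}\right),$$

the expected number of truly non-deleterious natural variants falling in
the category by chance over the number observed there. Empty categories
are flagged undefined rather than reported as zero. The estimator is
scale-free in both histogram sizes.

## Epistasis and co-occurrence

Epistasis is computed on the linear scale,
$\varepsilon = r_{ab} - r_a r_b$, because the multiplicative null is the
natural no-interaction model for growth rates (the product of log scores
would be dimensionally wrong). Doubles whose constituent singles lack a
passing score are excluded and *counted* (`n_excluded`), not silently
dropped. A pair co-occurs only if some *single* homologue carries both
members — two substitutions seen only in different lineages have never
been tested together by evolution. Group comparisons use the Wilcoxon
rank-sum test: exact enumeration when the smaller group has ≤ 10
observations and no ties, otherwise the normal approximation with tie
correction (delegated to `stats::wilcox.test`).

## Ancestral-state calls

A reconstructed residue is accepted singly when its posterior strictly
exceeds 0.7; otherwise a pair is reported when the top two are each at
least 0.3 and jointly exceed 0.75; otherwise the position is ambiguous.
The boundary semantics follow the quoted rule exactly (strict for 0.7
and 0.75, inclusive for the per-member 0.3). A tie between the second
and third residues is reported ambiguous; note that for a proper
probability vector such a tie can never satisfy the pair rule anyway
(the three probabilities would exceed 1), so the tie-break only matters
for defensive validation. Divergence in the burden analysis is proxied
by (100 − window percent identity) because branch lengths belong to the
upstream tree-building step this package deliberately does not redo;
newick trees are read only to order homologues in reports.

## What the simulator emulates — and what it does not

`simulation_config()` defaults encode the study conditions this analysis
was designed around: a 75-residue window, 52 homologues spanning roughly
55–88% identity, a 210-entry catalogue with 17 strongly and 45 mildly
deleterious substitutions, one human-like homologue at exactly 25
differences, three planted compensatory pairs with +0.3 linear
epistasis, small positive epistasis (0.02–0.10) for other co-occurring
pairs, 200 synonymous variants, sequencing depth $10^6$ per time point,
and one selection generation — so a planted fitness equals its expected
linear score. Strongly deleterious substitutions are placed in
homologues with probability increasing in divergence, reproducing the
burden-versus-divergence trend. Library composition is Dirichlet
(gamma concentration 50) with a 50× wild-type boost, and both sequencing
reads are multinomial draws — the minimal model that reproduces the
score estimator's noise structure.

Deliberately **not** emulated: phylogenetic correlation among homologues
(each is drawn independently given its divergence level), codon-level
mutagenesis chemistry, gapped alignments at study scale (gap handling is
tested on small constructed alignments), selection-bottleneck drift, and
PCR jackpot effects. Passing the end-to-end tests therefore demonstrates
the pipeline's correctness and statistical behaviour under its own
measurement model, not robustness to every artefact of a real
experiment. Likewise, the two-hybrid generator
(`simulate_twohybrid_counts()`) plants a 44-hit geometry split 22/8/11/3
across core, neighbour, proximal and other positions — it validates hit
calling and categorization at realistic scale, while the counts
themselves are synthetic stand-ins, not the published assay data.

## Numerical and degenerate-input choices

* Zero selected reads: pseudocount 0.5 on both counts (flagged
  `pseudocounted`), or a hard floor at linear 0 / log2 −∞ (flagged
  `floored`) when the pseudocount is disabled.
* Zero input reads: score undefined (`NA`), the variant flagged.
* Wild-type score is set to exactly 1 (log2 0) after normalization, so
  the fixed point holds to machine identity.
* Duplicate single-mutant variants for the same substitution: the
  highest-input-count variant wins the join.
* Empty catalogues, empty epistasis groups and empty contamination
  categories flow through with explicit flags rather than errors;
  fewer than two passing synonymous variants makes the QC an error
  because the variance is then meaningless.

## Problem sizes

The test suite and the acceptance script run the generator at its
study-scale defaults (684 library variants, depth $10^6$, 52
homologues) — small enough to complete in seconds, deep enough that
sampling noise (log2 standard error ≈ 0.05 per variant) sits well inside
every classification margin the generator plants.

## Known limitations

* The contamination estimator assumes the synonymous null shares the
  non-deleterious variants' noise distribution; coverage differences
  between the two sets violate this (hence the stringent 500-read
  filter).
* Epistasis on the linear scale conflates magnitude with baseline: a
  +0.3 deviation means more for singles near 1.0 than near 0.3. Ranked
  candidate lists mitigate, but do not remove, this.
* The burden–divergence correlation treats homologues as independent
  points; shared phylogeny inflates its nominal significance on real
  data.
* Hit categorization depends entirely on the supplied adjacency table;
  no distance criterion is computed from structure here.
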