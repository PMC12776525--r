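---
title: "Physicochemical analysis of TCR CDR3 repertoires with cdr3phys"
author: "cdr3phys authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physicochemical analysis of TCR CDR3 repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdr3phys)
```

## The problem

Checkpoint-inhibitor immunotherapy occasionally triggers severe
immune-related adverse events, including myocarditis. One line of evidence
implicates the physical chemistry of the T cell receptor itself: T cells
expanded in affected patients tend to carry CDR3β loops that are shorter
and richer in hydrophobic residues, and their amino-acid clonotypes are
reached by multiple independent nucleotide rearrangements (convergent
recombination). `cdr3phys` packages that analysis chain — clone
definition, mid-region hydrophobicity scoring, expansion and dominance
statistics, codon-redundancy classification, subset sharing, α–β pairing,
and the accompanying non-parametric tests — together with a fully seeded
repertoire simulator so that every stage can be validated against a known
ground truth without access to patient data.

## Clone definition

A *clone* is the set of cells of one chain (TRA or TRB) sharing an
identical CDR3 amino-acid sequence. V and J gene calls and the observed
nucleotide variants are aggregated per clone but are deliberately not part
of the key: identity at the protein level is exactly what makes
codon-redundancy events observable (a clone whose amino-acid sequence is
encoded by two or more distinct nucleotide rearrangements is a converging
clone, class CrE-2 or CrE-3; CrE-3 is the open-ended "three or more
variants" bin so class percentages always total 100).

Reading follows single-cell convention: only productive TRA/TRB contigs
with a consistent nucleotide/amino-acid pair
(`nchar(nt) == 3*nchar(aa)` and `translate(nt) == aa`) are retained, and
each barcode contributes at most one contig per locus (highest UMI count,
ties broken by the lexicographically smallest nucleotide sequence so the
result is deterministic). Barcodes are not required to carry both chains;
pairing analyses simply skip, and count, half-paired cells.

## Hydrophobicity scoring

Two residue scales are embedded:

* **Kyte–Doolittle** hydropathy (I = 4.5 … R = −4.5), the default for
  headline statistics;
* **Wimley–White interface** transfer free energies (water → POPC
  interface; charged Asp/Glu/Lys/Arg, neutral His), *negated at load* so
  both scales read "higher = more hydrophobic". The published raw values
  stay accessible in the object's `raw` slot.

A sequence's score is the arithmetic mean of its residue values. The
*mid-hypervariable region* is the CDR3 with `trimN` residues removed from
the N terminus and `trimC` from the C terminus; the defaults
`trimN = trimC = 3` remove the conserved cysteine-anchored "CAS…" motif
and the residues proximal to the J-encoded F/W-G-x-G motif, isolating the
junction-encoded loop apex. The boundary has no universal definition, so
both trims are arguments everywhere and are echoed into report metadata;
any reproduction claim should state them. Sequences no longer than
`trimN + trimC` have an empty mid region, which is treated as *missing
data*, never as a zero — zero is a legitimate mean on both scales and
silently imputing it would drag group comparisons toward it.

```{r}
hydrophobicity("CASSLGQAYEQYF")            # full CDR3, Kyte-Doolittle
midRegion("CASSLGQAYEQYF")                 # "SLGQAYE"
hydrophobicity(midRegion("CASSLGQAYEQYF"))
```

## Expansion, dominance, sharing

The *clonal expansion index* of a clone is the ratio of its frequency
among case cells to its frequency among control cells, times 100. The raw
ratio is undefined for clones absent from the control, so an additive
pseudocount (default one cell per condition total) keeps it finite:
$100\,(f_{case}+p/N_{case})/(f_{ctrl}+p/N_{ctrl})$. Both the pseudocounted
and the raw index are reported; the raw index satisfies the exact
antisymmetry $I_{a\to b} \cdot I_{b\to a} = 10^4$ for clones seen in both
conditions, which the tests exploit.

Repertoire dominance uses the Berger–Parker index — the frequency of the
single most abundant clone — computed per sample so that conditions can
be compared across samples. Copy-number bins for expansion summaries
default to 1, 2, 3–5, 6–10, >10 cells and "expanded" defaults to ≥ 2
cells in a condition; neither has a canonical published value, so both
are arguments.

Group comparisons use the two-sample Kolmogorov–Smirnov test (the
package's default for condition contrasts) and the Mann–Whitney test,
with the U convention fixed as "number of between-group pairs in which
the first group's value is larger, ties half"; under that convention the
rank-statistic AUROC of `rocFromScores()` equals
$U/(n_{pos} n_{neg})$ to machine precision, an identity asserted at
`1e-12` in the test suite. For a single predictor, logistic regression is
a monotone transform of the score and leaves the ROC unchanged, so ROC
curves are computed directly on scores. Monotone associations use
Spearman's rho with a Fisher-z 95% interval. The report additionally
emits Benjamini–Hochberg q-values across its headline comparisons,
clearly labelled as an extension of the per-comparison p-values.

**Weighting matters.** Condition-level hydrophobicity comparisons are
clone-weighted by default: all cells of a clone share one CDR3 sequence,
so cell-weighted values are pseudo-replicates. In simulation, cell
weighting inflated the KS false-positive rate several-fold under the
null, while the clone-weighted test held its nominal level (measured
3% at α = 0.05 over 200 seeds). Cell weighting remains available where
the cell-level composition is itself the question, e.g. length
distributions, whose bimodality is an expansion-weighted phenomenon.

## The synthetic repertoire generator

`generateRepertoire(simConfig(...))` emulates exactly the statistical
structure the analyses measure, no more:

* **Junctions.** Clone skeletons are a germline V stub + junctional
  insertion + J stub. The stubs are short invented sequences beginning
  `TGTGC` (encoding C-A…) and ending in J motifs whose final codon is F,
  so generated CDR3s look canonical (start C, end F). All stubs are whole
  codons, making the insertion codon-aligned; insert codons are drawn
  uniformly from the 61 stop-free codons, so every junction is productive
  by construction and no rejection sampling is needed. The insert length
  is derived from the condition's target CDR3 length (the planted
  quantity), capped at 18 nt.
* **Lengths.** Per-condition CDR3 length mixtures; the defaults give the
  case condition a 50/50 mixture of 12- and 15-mers against a 14/15
  control — the short/long bimodality of an affected repertoire.
* **Expansion.** Base clone sizes follow a discrete power law (exponent
  2.5, truncated at 500); cells are then allocated multinomially. In the
  case condition both the clone pool (acceptance thinning) and the
  allocation weights are tilted by $e^{\beta h}$, where $h$ is the
  clone's mid-region Kyte–Doolittle score and $\beta$
  (`hydroCouplingBeta`, default 0.5) is the planted
  hydrophobicity–expansion coupling. $\beta = 0$ recovers the null
  exactly.
* **Convergence.** Each expanded clone receives, with probability
  `convergenceRate` (default 0.25), one or two synonymously recoded
  nucleotide variants — codons resampled uniformly among synonyms, so
  amino-acid identity holds by construction — and with probability
  `multiVProb` a variant is re-anchored on an alternative V stub that
  encodes the same amino acids, planting multi-V convergence.
* **Pairing and subsets.** Cells carry a TRA partner with probability
  0.9; α target lengths are coupled to β lengths with slope
  `pairingCoupling` (default 0.6). Each clone has a primary phenotypic
  subset; cells keep it with probability 0.8, creating realistic subset
  sharing including cross-lineage (CD4/CD8) overlap.

Every run returns a ground-truth ledger (per planted clone: condition,
size, nucleotide variants, V genes, multi-V flag, primary subset,
mid-region hydrophobicity), and the whole output is a deterministic
function of the config, seed included.

What the generator does *not* emulate: realistic V(D)J generation
probabilities (no IGoR/OLGA-style model), somatic UMI/error structure,
doublets, or transcriptional phenotype. Tests passing on this generator
therefore demonstrate that the *analysis* recovers planted statistical
structure — not that real repertoires possess that structure.

## Numerical and design choices

* Realized clone sizes are the power-law weights thinned by multinomial
  allocation, so the size marginal is tested by comparing two independent
  seeds of the same law (two-sample KS) rather than a closed-form CDF.
* Problem sizes in the validation suite: the coupling-recovery experiment
  uses 100 seeds at 2,000 cells per condition, the null calibration 200
  seeds at 500 cells per condition with identical length modes (the
  calibration condition: differing length modes are themselves a real
  distributional difference, and the KS test correctly rejects under
  them). Oracle-equivalence checks use 1,000 random peptides, 100 random
  repertoires, 1,000 random label/score sets and 10,000 random junctions.
* Ties in ROC/U statistics use midranks; the normal approximation to U
  carries the standard tie correction.
* Empty mid regions are excluded (with a logged count) from mid-region
  statistics; strata with fewer than two CrE classes are flagged, not
  tested; Spearman's rho is declared undefined below three clones.
* Determinism: identical inputs produce byte-identical clone tables,
  fixtures and report JSON; nothing writes timestamps.

## Worked example

```{r}
sim <- generateRepertoire(simConfig(seed = 7, nCells = 400))
rep <- sim$repertoire
rep

h <- hydroByCondition(rep, "cardiotox", "no_irae")
round(c(case = h$mean_case, control = h$mean_control,
        ks_D = unname(h$test$statistic), p = h$test$p), 4)

cv <- classifyConvergence(rep)
subset(cv$summary, cre_class != "CrE-1")
```

## Limitations

The mid-region boundary (symmetric trims of width 3) is a convention, not
a published definition; results should always be read conditional on the
trims used. The expansion index is a descriptive ratio, not a model-based
estimate, and depends on its pseudocount at the rare-clone margin. CrE
classification counts observed variants and therefore undercounts
convergence at low sequencing depth. The ROC analysis covers a single
predictor; multi-feature logistic ROC is out of scope.
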