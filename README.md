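# cdr3phys

Physicochemical analysis of single-cell T cell receptor (TCR) CDR3
repertoires.

Checkpoint-inhibitor cardiotoxicity and related immune adverse events have
been linked to the physical chemistry of the TCR itself: expanded T cell
clones in affected patients carry CDR3β loops that are **shorter and more
hydrophobic**, and their amino-acid clonotypes are reached by multiple
independent nucleotide rearrangements (**convergent recombination /
codon-redundancy events**). `cdr3phys` implements that analysis chain for
immunologists working with 10x Genomics V(D)J or AIRR Rearrangement data:

* **Ingest** — 10x per-contig CSV and AIRR TSV readers/writers; productive
  TRA/TRB filtering with per-reason drop logging; one contig per barcode
  and locus (top UMIs, deterministic tie-break); clones defined by
  identical CDR3 amino-acid sequence per chain (`TCRRepertoire` S4 class).
* **Hydrophobicity** — mean residue hydropathy of the full CDR3 and of its
  mid-hypervariable region (default: trim 3 residues each side), on the
  embedded Kyte–Doolittle scale and the Wimley–White interface scale
  (sign-flipped at load so higher = more hydrophobic on both).
* **Expansion** — clonal expansion index (case:control frequency ratio
  × 100, with pseudocount), Berger–Parker dominance per sample,
  hydrophobicity vs copy number (binned means + Spearman's rho).
* **Convergence** — CrE-1/2/3 classification by distinct nucleotide
  variants per amino-acid clone, clone- and cell-weighted class
  percentages, convergence vs hydrophobicity within mid-length strata,
  multi-V convergent clones, α–β chain pairing of expanded clones.
* **Statistics** — two-sample Kolmogorov–Smirnov and Mann–Whitney tests,
  rank-statistic ROC with the exact identity AUROC = U/(n₊ n₋),
  Kruskal–Wallis across CrE classes, BH q-values.
* **Simulation** — a fully seeded V(D)J repertoire generator with planted
  clonal expansion (discrete power law), hydrophobicity–expansion
  coupling exp(β·h), condition-specific CDR3 length bimodality,
  synonymous convergence and β–α pairing, returning a ground-truth ledger
  for every planted clone.

## Worked example

```r
library(cdr3phys)

sim <- generateRepertoire(simConfig(seed = 7, nCells = 400))
rep <- sim$repertoire
rep
#> TCRRepertoire
#>   TRA: 725 cells, 258 clones
#>   TRB: 800 cells, 231 clones
#>   6 samples (cardiotox: 3, no_irae: 3)

## mid-region hydrophobicity, case vs control (clone-weighted KS)
h <- hydroByCondition(rep, "cardiotox", "no_irae")
round(c(case = h$mean_case, control = h$mean_control,
        ks_D = unname(h$test$statistic), p = h$test$p), 4)
#>    case control    ks_D       p
#> -0.6719 -1.0233  0.2903  0.0001

## codon-redundancy (convergent recombination) classes
cv <- classifyConvergence(rep)
subset(cv$summary, cre_class != "CrE-1")
#>   condition cre_class n_clones pct_clones pct_cells
#> 2 cardiotox     CrE-2       20  17.543860     21.25
#> 3 cardiotox     CrE-3        6   5.263158      6.00
#> 5   no_irae     CrE-2       13  10.569106     11.00
#> 6   no_irae     CrE-3        3   2.439024      3.50

## hydrophobicity rises with clonal expansion
m <- scoreRepertoire(rep)
e <- expansionIndex(rep, "cardiotox", "no_irae")
hydroVsExpansion(m[m$chain == "TRB", ], e)$rho
#> [1] 0.383
```

The case repertoire's mid-region CDR3s score ~0.35 Kyte–Doolittle units
more hydrophobic than control (KS p = 1e-4), convergence is enriched in
the case condition, and mid-region hydrophobicity correlates positively
with clone copy number — the planted structure the generator encodes and
the analyses recover.

Real data enter through `readContigs()` (dialects `"tenx_csv"` and
`"airr_tsv"`), `dedupePerBarcode()` and `buildClones()` with per-barcode
and per-sample metadata tables; `hydroReport()` writes every table plus a
JSON summary with the full parameter log. A small on-disk example lives
in `inst/extdata/fixture_repertoire/` with its ground-truth ledger.

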