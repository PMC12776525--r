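# Shared helpers: deterministic codon encoding for hand-built fixtures and
# a toy-repertoire builder specified directly as clone rows.

# one fixed codon per residue, so aa -> nt is deterministic and stop-free
.AA2CODON <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAT", I = "ATT", K = "AAA", L = "CTT", M = "ATG", N = "AAT",
  P = "CCT", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAT"
)

aa2nt <- function(aa) {
  vapply(strsplit(aa, ""), function(x)
    paste(.AA2CODON[x], collapse = ""), character(1))
}

# build a TCRRepertoire from clone-level spec: one row per
# (chain, cdr3_aa, condition[, subset, nt, v_gene]) with a cell count n
makeToyRepertoire <- function(spec) {
  if (is.null(spec$subset)) spec$subset <- "CD8 GZMK+"
  if (is.null(spec$nt)) spec$nt <- aa2nt(spec$cdr3_aa)
  if (is.null(spec$v_gene)) spec$v_gene <- "TRBV19"
  idx <- rep(seq_len(nrow(spec)), spec$n)
  n_all <- length(idx)
  rec <- data.frame(
    barcode = sprintf("toy%05d", seq_len(n_all)),
    chain = spec$chain[idx], v_gene = spec$v_gene[idx], j_gene = "TRBJ2-7",
    cdr3_nt = spec$nt[idx], cdr3_aa = spec$cdr3_aa[idx],
    umis = 2L, stringsAsFactors = FALSE
  )
  cells <- data.frame(
    barcode = rec$barcode,
    sample_id = paste0("s_", spec$condition[idx]),
    subset = spec$subset[idx], stringsAsFactors = FALSE
  )
  conds <- unique(spec$condition)
  samples <- data.frame(sample_id = paste0("s_", conds), condition = conds,
                        stringsAsFactors = FALSE)
  buildClones(rec, cells, samples)
}
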