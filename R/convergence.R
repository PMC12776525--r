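# Codon-redundancy (convergent recombination) analysis: clones whose
# amino-acid CDR3 is reached by more than one nucleotide rearrangement.
# CrE-k = k distinct nucleotide variants; CrE-3 is the open-ended >= 3 bin
# so class percentages always sum to 100 over {CrE-1, CrE-2, CrE-3}.

.cre_class <- function(n_variants) {
  factor(ifelse(n_variants >= 3L, "CrE-3",
                ifelse(n_variants == 2L, "CrE-2", "CrE-1")),
         levels = c("CrE-1", "CrE-2", "CrE-3"))
}

#' Classify codon-redundancy events
#'
#' Groups each clone's observed CDR3 nucleotide sequences and classifies
#' the clone by the number of distinct variants: CrE-1 (one variant,
#' non-converging), CrE-2 (two) or CrE-3 (three or more; converging =
#' CrE-2 or CrE-3). By default convergence is assessed within chain and
#' within condition (a variant seen in different conditions counts in
#' each); \code{scope = "pooled"} pools all cells of a chain as one
#' repertoire. Both clone-weighted and cell-weighted class percentages are
#' reported, since either weighting is defensible.
#'
#' @param rep a \code{\linkS4class{TCRRepertoire}}
#' @param scope \code{"condition"} or \code{"pooled"}
#' @param chain chain to analyse (default \code{"TRB"})
#' @return list with \code{records} (per clone [x condition]:
#'   \code{cdr3_aa}, \code{condition}, \code{n_nt_variants},
#'   \code{cre_class}, \code{n_cells}, \code{v_genes}) and \code{summary}
#'   (per condition x class: \code{pct_clones}, \code{pct_cells})
#' @export
classifyConvergence <- function(rep, scope = c("condition", "pooled"),
                                chain = "TRB") {
  stopifnot(is(rep, "TCRRepertoire"))
  scope <- match.arg(scope)
  rec <- rep@contigs[rep@contigs$chain == chain, , drop = FALSE]
  if (!nrow(rec)) stop("no records on chain ", chain)
  cond <- if (scope == "pooled") rep("pooled", nrow(rec)) else rec$condition
  key <- paste(cond, rec$cdr3_aa, sep = "\r")
  grp <- split(seq_len(nrow(rec)), key)
  records <- data.frame(
    chain = chain,
    cdr3_aa = vapply(grp, function(i) rec$cdr3_aa[i[1L]], character(1)),
    condition = vapply(grp, function(i) cond[i[1L]], character(1)),
    n_nt_variants = vapply(grp, function(i)
      length(unique(rec$cdr3_nt[i])), integer(1)),
    n_cells = vapply(grp, length, integer(1)),
    v_genes = vapply(grp, function(i)
      paste(sort(unique(rec$v_gene[i])), collapse = ";"), character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  records$cre_class <- .cre_class(records$n_nt_variants)
  records <- records[order(records$condition, records$cdr3_aa), , drop = FALSE]
  rownames(records) <- NULL
  summ <- do.call(rbind, lapply(split(records, records$condition), function(d) {
    data.frame(
      condition = d$condition[1L],
      cre_class = levels(d$cre_class),
      n_clones = as.integer(table(d$cre_class)),
      pct_clones = 100 * as.vector(table(d$cre_class)) / nrow(d),
      pct_cells = 100 * as.vector(tapply(d$n_cells, d$cre_class, sum,
                                         default = 0L)) / sum(d$n_cells),
      stringsAsFactors = FALSE
    )
  }))
  rownames(summ) <- NULL
  list(records = records, summary = summ)
}

#' Hydrophobicity of converging versus non-converging clones
#'
#' Compares mean mid-region hydrophobicity between CrE classes within
#' strata of mid-region length, the length-matched comparison that
#' separates the convergence effect from the shorter-CDR3 effect. Strata
#' containing fewer than two classes are flagged, not tested; the rest get
#' a Kruskal-Wallis test across classes.
#'
#' @param convergence result of \code{\link{classifyConvergence}} (its
#'   \code{records}), computed with \code{scope = "pooled"} or joined per
#'   condition
#' @param metrics per-clone metrics from \code{\link{scoreRepertoire}}
#' @return list with \code{table} (class x mid-length mean hydro_mid and
#'   n) and \code{tests} (per mid-length Kruskal-Wallis H and p, or NA
#'   with a flag where untestable)
#' @export
convergenceVsPhyschem <- function(convergence, metrics) {
  j <- merge(convergence[, c("chain", "cdr3_aa", "cre_class")],
             metrics[, c("chain", "cdr3_aa", "mid_length", "hydro_mid")],
             by = c("chain", "cdr3_aa"))
  j <- j[!is.na(j$hydro_mid), , drop = FALSE]
  tab <- stats::aggregate(list(mean_hydro_mid = j$hydro_mid),
                          by = list(cre_class = j$cre_class,
                                    mid_length = j$mid_length), FUN = mean)
  tab$n_clones <- stats::aggregate(list(n = j$hydro_mid),
                                   by = list(cre_class = j$cre_class,
                                             mid_length = j$mid_length),
                                   FUN = length)$n
  tests <- do.call(rbind, lapply(split(j, j$mid_length), function(d) {
    cls <- droplevels(d$cre_class)
    if (nlevels(cls) < 2) {
      data.frame(mid_length = d$mid_length[1L], H = NA_real_, p = NA_real_,
                 n = nrow(d), flag = "fewer than 2 classes")
    } else {
      kt <- stats::kruskal.test(d$hydro_mid, cls)
      data.frame(mid_length = d$mid_length[1L], H = unname(kt$statistic),
                 p = kt$p.value, n = nrow(d), flag = "")
    }
  }))
  rownames(tests) <- NULL
  list(table = tab, tests = tests)
}

#' Converging clones that use multiple V gene segments
#'
#' Among converging clones (two or more nucleotide variants), lists those
#' whose variants arise from at least two distinct V genes — convergence
#' achieved through different recombination events, not just synonymous
#' junctional nucleotides. Per-V variant and cell counts are included.
#'
#' @param rep a \code{\linkS4class{TCRRepertoire}}
#' @param chain chain to analyse (default \code{"TRB"})
#' @return data.frame per qualifying clone: \code{cdr3_aa},
#'   \code{n_nt_variants}, \code{n_v_genes}, \code{v_genes} and
#'   \code{per_v_cells} (";"-joined \code{gene=count} pairs)
#' @export
vGeneConvergence <- function(rep, chain = "TRB") {
  stopifnot(is(rep, "TCRRepertoire"))
  rec <- rep@contigs[rep@contigs$chain == chain, , drop = FALSE]
  grp <- split(seq_len(nrow(rec)), rec$cdr3_aa)
  rows <- lapply(names(grp), function(aa) {
    i <- grp[[aa]]
    nv <- length(unique(rec$cdr3_nt[i]))
    vg <- sort(unique(rec$v_gene[i]))
    if (nv < 2L || length(vg) < 2L) return(NULL)
    tab <- table(rec$v_gene[i])
    data.frame(
      chain = chain, cdr3_aa = aa, n_nt_variants = nv,
      n_v_genes = length(vg), v_genes = paste(vg, collapse = ";"),
      per_v_cells = paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                          collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chain = character(), cdr3_aa = character(),
                      n_nt_variants = integer(), n_v_genes = integer(),
                      v_genes = character(), per_v_cells = character())
  rownames(out) <- NULL
  out
}

#' Alpha-chain partners of expanded beta clones
#'
#' Pairs each cell's TRB call with its TRA call (cells lacking one chain
#' are excluded and counted), then, for each expanded beta clone, lists
#' the multiset of alpha CDR3 partners. Pairing multiplicity counts cells.
#' The beta-alpha mid-length association is summarised with a Spearman
#' correlation over cell-level (beta mid-length, alpha mid-length) pairs,
#' and beta mid-hydrophobicity is summarised by pairing multiplicity
#' (number of distinct alpha partners).
#'
#' @param rep a \code{\linkS4class{TCRRepertoire}} (contigs must be
#'   deduplicated: at most one TRA and one TRB per barcode)
#' @param expandedMin minimum cells for a beta clone to count as expanded
#'   (default 2)
#' @param scale,trimN,trimC hydrophobicity scoring parameters
#' @return list with \code{pairs} (per expanded beta clone x alpha
#'   partner: cell counts), \code{length_assoc} (Spearman rho and p),
#'   \code{hydro_by_multiplicity}, \code{n_unpaired}
#' @export
alphaBetaPairing <- function(rep, expandedMin = 2L,
                             scale = hydropathyScale("kyte_doolittle"),
                             trimN = 3L, trimC = 3L) {
  stopifnot(is(rep, "TCRRepertoire"))
  rec <- rep@contigs
  trb <- rec[rec$chain == "TRB", c("barcode", "cdr3_aa")]
  tra <- rec[rec$chain == "TRA", c("barcode", "cdr3_aa")]
  names(trb)[2] <- "beta"; names(tra)[2] <- "alpha"
  paired <- merge(trb, tra, by = "barcode")
  n_unpaired <- nrow(trb) + nrow(tra) - 2L * nrow(paired)
  beta_sizes <- table(trb$beta)
  expanded <- names(beta_sizes)[beta_sizes >= expandedMin]
  pp <- paired[paired$beta %in% expanded, , drop = FALSE]
  if (nrow(pp)) {
    pairs <- stats::aggregate(list(n_cells = pp$barcode),
                              by = list(beta = pp$beta, alpha = pp$alpha),
                              FUN = length)
    pairs <- pairs[order(pairs$beta, -pairs$n_cells, pairs$alpha), ,
                   drop = FALSE]
    rownames(pairs) <- NULL
    bl <- nchar(midRegion(pp$beta, trimN, trimC))
    al <- nchar(midRegion(pp$alpha, trimN, trimC))
    la <- if (nrow(pp) >= 3)
      suppressWarnings(stats::cor.test(bl, al, method = "spearman",
                                       exact = FALSE))
    else NULL
    mult <- tapply(pairs$alpha, pairs$beta, length)
    hyd <- hydrophobicity(midRegion(names(mult), trimN, trimC), scale)
    hbm <- stats::aggregate(list(mean_hydro_mid = hyd),
                            by = list(multiplicity = as.integer(mult)),
                            FUN = mean, na.rm = TRUE)
    hbm$n_beta_clones <- as.integer(table(as.integer(mult)))
  } else {
    pairs <- data.frame(beta = character(), alpha = character(),
                        n_cells = integer())
    la <- NULL
    hbm <- data.frame(multiplicity = integer(), mean_hydro_mid = numeric(),
                      n_beta_clones = integer())
  }
  list(
    pairs = pairs,
    length_assoc = if (is.null(la)) list(rho = NA_real_, p = NA_real_)
                   else list(rho = unname(la$estimate), p = la$p.value),
    hydro_by_multiplicity = hbm,
    n_unpaired = n_unpaired
  )
}
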