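# Clonal expansion, dominance and sharing. The expansion index follows the
# case:control dominant-clone frequency ratio x 100; a per-condition
# additive pseudocount (default one cell) keeps it defined for clones seen
# in only one condition, and the raw pseudo-free ratio is reported
# alongside (NA when the control frequency is zero).

#' Clonal expansion index of each clone
#'
#' For each clone of a chain, the ratio of its frequency among case cells
#' to its frequency among control cells, multiplied by 100. With
#' \code{pseudo > 0} the index is
#' \deqn{100 (f_{case} + pseudo/N_{case}) / (f_{ctrl} + pseudo/N_{ctrl})}
#' where \eqn{N} are condition cell totals for the chain; the pseudo-free
#' ratio is reported alongside as \code{index_raw} (NA where the control
#' frequency is zero).
#'
#' @param rep a \code{\linkS4class{TCRRepertoire}}
#' @param caseLabel,controlLabel condition labels present in the repertoire
#' @param pseudo additive pseudocount in cells (default 1)
#' @param chain chain to analyse (default \code{"TRB"})
#' @return data.frame per clone: \code{cdr3_aa}, \code{n_case},
#'   \code{n_control}, \code{freq_case}, \code{freq_control},
#'   \code{index}, \code{index_raw}
#' @export
expansionIndex <- function(rep, caseLabel, controlLabel, pseudo = 1,
                           chain = "TRB") {
  stopifnot(is(rep, "TCRRepertoire"))
  conds <- unique(rep@samples$condition)
  unknown <- setdiff(c(caseLabel, controlLabel), conds)
  if (length(unknown))
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "))
  cc <- cloneCounts(rep, by = "condition", chain = chain)
  n_case_tot <- sum(cc$n_cells[cc$group == caseLabel])
  n_ctrl_tot <- sum(cc$n_cells[cc$group == controlLabel])
  if (n_case_tot == 0 || n_ctrl_tot == 0)
    stop("no cells for one of the conditions on chain ", chain)
  keys <- sort(unique(cc$cdr3_aa))
  n_case <- integer(length(keys)); n_ctrl <- integer(length(keys))
  i <- match(cc$cdr3_aa[cc$group == caseLabel], keys)
  n_case[i] <- cc$n_cells[cc$group == caseLabel]
  i <- match(cc$cdr3_aa[cc$group == controlLabel], keys)
  n_ctrl[i] <- cc$n_cells[cc$group == controlLabel]
  f_case <- n_case / n_case_tot
  f_ctrl <- n_ctrl / n_ctrl_tot
  idx <- 100 * (f_case + pseudo / n_case_tot) / (f_ctrl + pseudo / n_ctrl_tot)
  raw <- ifelse(f_ctrl > 0, 100 * f_case / f_ctrl, NA_real_)
  keep <- n_case + n_ctrl > 0
  out <- data.frame(
    chain = chain, cdr3_aa = keys, n_case = n_case, n_control = n_ctrl,
    freq_case = f_case, freq_control = f_ctrl,
    index = idx, index_raw = raw, stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Berger-Parker dominance index
#'
#' Frequency of the most abundant clone: \code{max(counts) / sum(counts)},
#' in (0, 1]. Higher values mean a more dominated (less even) repertoire;
#' 1 is monoclonal. Scale-invariant in the counts.
#'
#' @param counts vector of per-clone cell counts, at least one positive
#' @return the dominance index
#' @examples
#' bergerParker(c(5, 3, 2))   # 0.5
#' @export
bergerParker <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (!length(counts) || all(counts == 0))
    stop("bergerParker needs at least one positive count")
  if (any(counts < 0)) stop("negative counts")
  max(counts) / sum(counts)
}

#' Berger-Parker dominance per sample
#'
#' Convenience wrapper computing the dominance index of every sample's
#' clone-size distribution on one chain, with its condition label, ready
#' for a group comparison.
#'
#' @param rep a \code{\linkS4class{TCRRepertoire}}
#' @param chain chain to analyse (default \code{"TRB"})
#' @return data.frame with \code{sample_id}, \code{condition},
#'   \code{berger_parker}, \code{n_cells}
#' @export
dominancePerSample <- function(rep, chain = "TRB") {
  cc <- cloneCounts(rep, by = "sample", chain = chain)
  samp <- sort(unique(cc$group))
  out <- data.frame(
    sample_id = samp,
    condition = rep@samples$condition[match(samp, rep@samples$sample_id)],
    berger_parker = vapply(samp, function(s)
      bergerParker(cc$n_cells[cc$group == s]), numeric(1)),
    n_cells = vapply(samp, function(s)
      sum(cc$n_cells[cc$group == s]), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Hydrophobicity as a function of clonal expansion
#'
#' Joins per-clone hydrophobicity metrics to case cell counts, summarises
#' mean mid-region hydrophobicity within copy-number bins, and tests the
#' monotone association with a Spearman rank correlation over (copy
#' number, hydro_mid) pairs (two-tailed p; 95 percent CI via the Fisher
#' z approximation). With fewer than 3 usable clones the correlation is
#' undefined and flagged.
#'
#' @param metrics per-clone metrics from \code{\link{scoreRepertoire}}
#' @param expansion per-clone table from \code{\link{expansionIndex}} (its
#'   \code{n_case} column is the copy number)
#' @param bins upper edges of the copy-number bins; defaults to
#'   1, 2, 3-5, 6-10, >10 cells
#' @return list with \code{bins} (per-bin n and mean hydro_mid),
#'   \code{rho}, \code{p}, \code{ci} (length-2), \code{n}
#' @export
hydroVsExpansion <- function(metrics, expansion, bins = c(1, 2, 5, 10, Inf)) {
  j <- merge(metrics[, c("chain", "cdr3_aa", "hydro_mid")],
             expansion[, c("chain", "cdr3_aa", "n_case")],
             by = c("chain", "cdr3_aa"))
  j <- j[!is.na(j$hydro_mid) & j$n_case > 0, , drop = FALSE]
  labs <- paste0(c(0, utils::head(bins, -1)) + 1, "-", bins)
  labs[bins == c(0, utils::head(bins, -1)) + 1] <-
    bins[bins == c(0, utils::head(bins, -1)) + 1]
  labs[is.infinite(bins)] <- paste0(">", utils::tail(bins, 2)[1])
  j$bin <- cut(j$n_case, breaks = c(0, bins), labels = labs)
  bin_tab <- stats::aggregate(list(mean_hydro_mid = j$hydro_mid),
                              by = list(bin = j$bin), FUN = mean, drop = FALSE)
  bin_tab$n_clones <- as.integer(table(j$bin))
  if (nrow(j) < 3) {
    return(list(bins = bin_tab, rho = NA_real_, p = NA_real_,
                ci = c(NA_real_, NA_real_), n = nrow(j),
                note = "fewer than 3 clones: correlation undefined"))
  }
  ct <- suppressWarnings(
    stats::cor.test(j$n_case, j$hydro_mid, method = "spearman",
                    alternative = "two.sided", exact = FALSE))
  z <- atanh(ct$estimate)
  se <- 1 / sqrt(nrow(j) - 3)
  list(bins = bin_tab, rho = unname(ct$estimate), p = ct$p.value,
       ci = unname(tanh(c(z - 1.96 * se, z + 1.96 * se))), n = nrow(j))
}

#' Clone sharing across phenotypic subsets or samples
#'
#' Clone-by-group matrix of cell counts, with a per-clone shared flag
#' (present in two or more groups) and, when grouping by subset, a
#' cross-lineage flag for clones spanning CD4 and CD8 subsets (lineage is
#' taken from the leading "CD4"/"CD8" token of the subset label).
#'
#' @param rep a \code{\linkS4class{TCRRepertoire}}
#' @param groupBy \code{"subset"} or \code{"sample"}
#' @param chain chain to analyse (default \code{"TRB"})
#' @return list with \code{matrix} (clones x groups counts), \code{shared}
#'   (named logical), \code{cross_lineage} (named logical, subset grouping
#'   only), and summary counts \code{n_shared}, \code{n_cross_lineage}
#' @export
sharingMatrix <- function(rep, groupBy = c("subset", "sample"),
                          chain = "TRB") {
  groupBy <- match.arg(groupBy)
  cc <- cloneCounts(rep, by = if (groupBy == "sample") "sample" else "subset",
                    chain = chain)
  if (all(is.na(cc$group))) stop("no ", groupBy, " labels present")
  m <- stats::xtabs(n_cells ~ cdr3_aa + group, data = cc)
  m <- matrix(as.integer(m), nrow = nrow(m), dimnames = dimnames(m))
  shared <- rowSums(m > 0) >= 2
  out <- list(matrix = m, shared = shared, n_shared = sum(shared))
  if (groupBy == "subset") {
    lineage <- sub("^(CD[48]).*", "\\1", colnames(m))
    cross <- vapply(seq_len(nrow(m)), function(i)
      length(unique(lineage[m[i, ] > 0])) > 1, logical(1))
    names(cross) <- rownames(m)
    out$cross_lineage <- cross
    out$n_cross_lineage <- sum(cross)
  }
  out
}
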