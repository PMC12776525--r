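# Readers/writers for the two rearrangement dialects and clone-table
# construction. Only productive TRA/TRB records with a consistent nt/aa
# CDR3 pair survive reading; every drop reason is counted and messaged.

.TENX_COLS <- c("barcode", "chain", "v_gene", "j_gene", "cdr3", "cdr3_nt",
                "productive", "umis")
.AIRR_COLS <- c("cell_id", "locus", "v_call", "j_call", "junction",
                "junction_aa", "productive", "duplicate_count")

.parse_productive <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "yes", "1")] <- TRUE
  out[x %in% c("false", "f", "no", "0", "none", "")] <- FALSE
  out
}

#' Read per-contig V(D)J annotation tables
#'
#' Reads a 10x Genomics \code{filtered_contig_annotations}-style CSV or an
#' AIRR Rearrangement TSV and returns the retained contig records: rows
#' that are productive, on the TRA or TRB locus, with non-empty CDR3
#' nucleotide and amino-acid sequences over the expected alphabets and with
#' \code{nchar(cdr3_nt) == 3 * nchar(cdr3_aa)}. All other rows are dropped
#' and a per-reason count is messaged. Rows whose productivity flag cannot
#' be parsed are dropped with a warning.
#'
#' @param path path to the contig table
#' @param dialect \code{"tenx_csv"} or \code{"airr_tsv"}
#' @return data.frame with columns \code{barcode}, \code{chain},
#'   \code{v_gene}, \code{j_gene}, \code{cdr3_nt}, \code{cdr3_aa},
#'   \code{umis}
#' @examples
#' dir <- system.file("extdata", "fixture_repertoire", package = "cdr3phys")
#' rec <- readContigs(file.path(dir, "contigs_tenx.csv"), "tenx_csv")
#' @export
readContigs <- function(path, dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tenx_csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    miss <- setdiff(.TENX_COLS, names(tab))
    if (length(miss))
      stop("tenx_csv table lacks mandatory column(s): ",
           paste(miss, collapse = ", "))
    rec <- data.frame(
      barcode = tab$barcode, chain = tab$chain,
      v_gene = tab$v_gene, j_gene = tab$j_gene,
      cdr3_nt = toupper(tab$cdr3_nt), cdr3_aa = toupper(tab$cdr3),
      productive = .parse_productive(tab$productive),
      umis = suppressWarnings(as.integer(tab$umis)),
      stringsAsFactors = FALSE
    )
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    miss <- setdiff(.AIRR_COLS, names(tab))
    if (length(miss))
      stop("airr_tsv table lacks mandatory column(s): ",
           paste(miss, collapse = ", "))
    rec <- data.frame(
      barcode = tab$cell_id, chain = tab$locus,
      v_gene = tab$v_call, j_gene = tab$j_call,
      cdr3_nt = toupper(tab$junction), cdr3_aa = toupper(tab$junction_aa),
      productive = .parse_productive(tab$productive),
      umis = suppressWarnings(as.integer(tab$duplicate_count)),
      stringsAsFactors = FALSE
    )
  }
  n_unparse <- sum(is.na(rec$productive))
  if (n_unparse > 0)
    warning(sprintf("%d row(s) with unparseable productivity flag dropped",
                    n_unparse))
  drops <- c(
    unparseable_productive = n_unparse,
    non_productive = sum(!rec$productive, na.rm = TRUE),
    non_tr_locus = 0L, empty_cdr3 = 0L, non_acgt = 0L, length_mismatch = 0L
  )
  keep <- !is.na(rec$productive) & rec$productive
  rec <- rec[keep, , drop = FALSE]
  ok <- rec$chain %in% c("TRA", "TRB")
  drops["non_tr_locus"] <- sum(!ok)
  rec <- rec[ok, , drop = FALSE]
  ok <- nchar(rec$cdr3_aa) > 0 & nchar(rec$cdr3_nt) > 0 &
    !is.na(rec$cdr3_aa) & !is.na(rec$cdr3_nt)
  drops["empty_cdr3"] <- sum(!ok)
  rec <- rec[ok, , drop = FALSE]
  ok <- !grepl("[^ACGT]", rec$cdr3_nt)
  drops["non_acgt"] <- sum(!ok)
  rec <- rec[ok, , drop = FALSE]
  ok <- nchar(rec$cdr3_nt) == 3L * nchar(rec$cdr3_aa)
  drops["length_mismatch"] <- sum(!ok)
  rec <- rec[ok, , drop = FALSE]
  # nt must actually encode aa (stop-free, standard code)
  trans <- vapply(rec$cdr3_nt, function(s) {
    tryCatch(translateCDR3(s), error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
  ok <- !is.na(trans) & trans == rec$cdr3_aa
  drops <- c(drops, translation_mismatch = sum(!ok))
  rec <- rec[ok, , drop = FALSE]
  drops <- drops[drops > 0]
  if (length(drops))
    message("dropped rows: ",
            paste(sprintf("%s=%d", names(drops), drops), collapse = ", "))
  rec$productive <- NULL
  rec$umis[is.na(rec$umis)] <- 0L
  rownames(rec) <- NULL
  rec
}

#' Write contig records in either dialect
#'
#' Inverse of \code{\link{readContigs}}: emits a 10x-style CSV or AIRR
#' Rearrangement TSV so that reading the file back yields the identical
#' record multiset.
#'
#' @param records data.frame as returned by \code{\link{readContigs}}
#' @param path output file path
#' @param dialect \code{"tenx_csv"} or \code{"airr_tsv"}
#' @return invisibly, the path written
#' @export
writeContigs <- function(records, path, dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tenx_csv") {
    out <- data.frame(
      barcode = records$barcode, is_cell = "True", contig_id = NA,
      high_confidence = "True", length = nchar(records$cdr3_nt),
      chain = records$chain, v_gene = records$v_gene, d_gene = "None",
      j_gene = records$j_gene, c_gene = "None", full_length = "True",
      productive = "True", cdr3 = records$cdr3_aa,
      cdr3_nt = records$cdr3_nt, reads = records$umis * 10L,
      umis = records$umis, stringsAsFactors = FALSE
    )
    out$contig_id <- paste0(records$barcode, "_contig_",
                            stats::ave(seq_len(nrow(records)),
                                       records$barcode, FUN = seq_along))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    out <- data.frame(
      cell_id = records$barcode,
      sequence_id = paste0(records$barcode, "-", seq_len(nrow(records))),
      locus = records$chain, v_call = records$v_gene,
      j_call = records$j_gene, junction = records$cdr3_nt,
      junction_aa = records$cdr3_aa, productive = "T",
      duplicate_count = records$umis, stringsAsFactors = FALSE
    )
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Keep one contig per barcode and locus
#'
#' Single-cell convention: a cell contributes at most one TRA and one TRB
#' call. Within each \code{(barcode, chain)} pair the record with the
#' highest UMI count is kept; ties are broken by the lexicographically
#' smallest \code{cdr3_nt}, so the result is deterministic.
#'
#' @param records data.frame of contig records
#' @return the deduplicated records, in stable (barcode, chain) order
#' @export
dedupePerBarcode <- function(records) {
  ord <- order(records$barcode, records$chain, -records$umis, records$cdr3_nt)
  rec <- records[ord, , drop = FALSE]
  keep <- !duplicated(paste(rec$barcode, rec$chain, sep = "\r"))
  rec <- rec[keep, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Build the clonotype table of a repertoire
#'
#' Groups deduplicated contig records into clones keyed by
#' \code{(chain, cdr3_aa)} — amino-acid identity defines the clone; V/J
#' genes and nucleotide variants are aggregated per clone but are not part
#' of the key (they feed the convergence analysis). Per-barcode metadata
#' attaches each cell to a sample and phenotypic subset; sample metadata
#' attaches each sample to a condition.
#'
#' @param records deduplicated contig records
#'   (\code{\link{dedupePerBarcode}})
#' @param cells data.frame with columns \code{barcode}, \code{sample_id}
#'   and optionally \code{subset}; every record barcode must appear
#' @param samples data.frame with columns \code{sample_id},
#'   \code{condition} (plus covariates); every cell's sample must appear
#' @return a \code{\linkS4class{TCRRepertoire}}
#' @examples
#' rec <- data.frame(
#'   barcode = c("bc1", "bc2", "bc3"), chain = "TRB",
#'   v_gene = "TRBV19", j_gene = "TRBJ2-7",
#'   cdr3_nt = c("TGTGCCAGCAGC", "TGCGCCAGCAGC", "TGTGCCAGCAGC"),
#'   cdr3_aa = "CASS", umis = 3L
#' )
#' cells <- data.frame(barcode = c("bc1", "bc2", "bc3"), sample_id = "s1",
#'                     subset = "CD8 GZMK+")
#' samples <- data.frame(sample_id = "s1", condition = "case")
#' rep <- buildClones(rec, cells, samples)
#' clones(rep)
#' @export
buildClones <- function(records, cells, samples) {
  stopifnot(all(c("barcode", "sample_id") %in% names(cells)),
            all(c("sample_id", "condition") %in% names(samples)))
  if (!"subset" %in% names(cells)) cells$subset <- NA_character_
  orphan_bc <- setdiff(records$barcode, cells$barcode)
  if (length(orphan_bc))
    stop("barcode(s) absent from cell metadata: ",
         paste(utils::head(orphan_bc, 5), collapse = ", "),
         if (length(orphan_bc) > 5) ", ...")
  idx <- match(records$barcode, cells$barcode)
  records$sample_id <- cells$sample_id[idx]
  records$subset <- cells$subset[idx]
  orphan <- setdiff(records$sample_id, samples$sample_id)
  if (length(orphan))
    stop("sample_id(s) absent from sample metadata: ",
         paste(orphan, collapse = ", "))
  records$condition <- samples$condition[match(records$sample_id,
                                               samples$sample_id)]
  records <- records[order(records$chain, records$cdr3_aa, records$barcode), ,
                     drop = FALSE]
  rownames(records) <- NULL
  key <- paste(records$chain, records$cdr3_aa, sep = "\r")
  agg_one <- function(x, f) vapply(split(x, key), f, character(1))
  joinset <- function(x) paste(sort(unique(x)), collapse = ";")
  cl <- data.frame(
    chain = vapply(split(records$chain, key), `[`, character(1), 1L),
    cdr3_aa = vapply(split(records$cdr3_aa, key), `[`, character(1), 1L),
    n_cells = as.integer(table(key)[unique(key)]),
    stringsAsFactors = FALSE
  )
  # table() reorders; recompute counts aligned with split() order instead
  cl$n_cells <- vapply(split(records$barcode, key), length, integer(1))
  cl$nt_variants <- agg_one(records$cdr3_nt, joinset)
  cl$n_nt_variants <- vapply(strsplit(cl$nt_variants, ";"), length, integer(1))
  cl$v_genes <- agg_one(records$v_gene, joinset)
  cl <- cl[order(cl$chain, cl$cdr3_aa), , drop = FALSE]
  rownames(cl) <- NULL
  samples <- samples[order(samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  new("TCRRepertoire", contigs = records, clones = cl, samples = samples)
}
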