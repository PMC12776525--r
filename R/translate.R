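# Standard genetic code, built once at load from the 64 codons.
.GENETIC_CODE <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  # codons enumerated T/C/A/G in the conventional table order (first base
  # slowest): TTT, TTC, TTA, TTG, TCT, ...
  codons <- sort(codons)
  aa <- c(
    AAA = "K", AAC = "N", AAG = "K", AAT = "N",
    ACA = "T", ACC = "T", ACG = "T", ACT = "T",
    AGA = "R", AGC = "S", AGG = "R", AGT = "S",
    ATA = "I", ATC = "I", ATG = "M", ATT = "I",
    CAA = "Q", CAC = "H", CAG = "Q", CAT = "H",
    CCA = "P", CCC = "P", CCG = "P", CCT = "P",
    CGA = "R", CGC = "R", CGG = "R", CGT = "R",
    CTA = "L", CTC = "L", CTG = "L", CTT = "L",
    GAA = "E", GAC = "D", GAG = "E", GAT = "D",
    GCA = "A", GCC = "A", GCG = "A", GCT = "A",
    GGA = "G", GGC = "G", GGG = "G", GGT = "G",
    GTA = "V", GTC = "V", GTG = "V", GTT = "V",
    TAA = "*", TAC = "Y", TAG = "*", TAT = "Y",
    TCA = "S", TCC = "S", TCG = "S", TCT = "S",
    TGA = "*", TGC = "C", TGG = "W", TGT = "C",
    TTA = "L", TTC = "F", TTG = "L", TTT = "F"
  )
  stopifnot(identical(sort(names(aa)), codons))
  aa
})

# codons per amino acid, for synonymous recoding
.CODONS_BY_AA <- local({
  cod <- names(.GENETIC_CODE)[.GENETIC_CODE != "*"]
  split(cod, .GENETIC_CODE[.GENETIC_CODE != "*"])
})

#' Translate CDR3 nucleotide sequences
#'
#' Standard-genetic-code translation for in-frame, stop-free CDR3
#' junctions. Productive rearrangements are stop-free by definition, so a
#' stop codon anywhere is an error, as are frame violations (length not a
#' multiple of 3) and non-ACGT letters. Vectorised.
#'
#' @param nt character vector of DNA sequences over \{A,C,G,T\}
#' @return character vector of amino-acid sequences
#' @examples
#' translateCDR3(c("TGT", "TGC"))   # both "C": codon degeneracy
#' @export
translateCDR3 <- function(nt) {
  vapply(nt, function(s) {
    n <- nchar(s)
    if (n == 0L) return("")
    if (n %% 3L != 0L)
      stop(sprintf("sequence length %d is not a multiple of 3: '%s'", n, s))
    if (grepl("[^ACGT]", s))
      stop(sprintf("non-ACGT letter in '%s'", s))
    cod <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- .GENETIC_CODE[cod]
    stp <- which(aa == "*")
    if (length(stp))
      stop(sprintf("stop codon %s at codon %d of '%s'", cod[stp[1L]], stp[1L], s))
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
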