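#' The standard genetic code as a codon table
#'
#' Builds the lookup used by all codon-level features: the 64 DNA codons in
#' fixed lexicographic order, the amino acid (or `"*"` for stop) each codon
#' encodes under the standard genetic code, and the fold-degeneracy of each
#' codon's synonymous family (1, 2, 3, 4 or 6; the three stop codons form a
#' 3-fold family).
#'
#' @return An object of class `codon_table`: a list with elements
#'   \describe{
#'     \item{codons}{character(64), lexicographic order (AAA, AAC, ...).}
#'     \item{aa}{named character(64), codon -> amino-acid symbol or `"*"`.}
#'     \item{degeneracy}{named integer(64), codon -> family size.}
#'     \item{amino_acids}{character(20), the canonical residues in
#'       alphabetical order.}
#'     \item{preferred}{named character over families: the lexicographically
#'       first codon of each family (used as the up-weighted codon by the
#'       synthetic generator).}
#'   }
#' @examples
#' ct <- codon_table()
#' sum(ct$aa == "*")        # 3 stop codons
#' ct$degeneracy[["CTG"]]   # leucine, 6-fold
#' @export
codon_table <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- sort(do.call(paste0, expand.grid(bases, bases, bases,
                                             stringsAsFactors = FALSE)))
  gc <- Biostrings::GENETIC_CODE
  aa <- vapply(codons, function(cd) unname(gc[[cd]]), character(1))
  deg <- vapply(aa, function(a) sum(aa == a), integer(1))
  names(deg) <- codons
  fams <- split(codons, aa[codons])
  preferred <- vapply(fams, function(f) sort(f)[1], character(1))
  structure(list(
    codons = codons,
    aa = aa,
    degeneracy = deg,
    amino_acids = sort(setdiff(unique(aa), "*")),
    preferred = preferred
  ), class = "codon_table")
}

#' @export
print.codon_table <- function(x, ...) {
  cat("Standard genetic code:", length(x$codons), "codons,",
      length(x$amino_acids), "amino acids,", sum(x$aa == "*"),
      "stop codons\n")
  invisible(x)
}
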