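# Sequence-derived features: codon usage, RSCU, CAI, GC content, lengths and
# amino-acid composition. These 89 features (68 nucleotide-derived, 21
# protein-derived) form the "S" feature block of the predictor.

#' Count codons in a coding sequence
#'
#' Reads non-overlapping in-frame triplets from position 1 of the CDS
#' (`step = 3`, the default); a trailing 1-2 nucleotides are ignored and any
#' triplet containing a symbol outside `A/C/G/T` (e.g. `N`) is skipped.
#' A literal sliding-window mode (`step = 1`) is available for comparison but
#' does not correspond to codon usage on a CDS.
#'
#' @param cds A single nucleotide string over `A/C/G/T/N` (case-insensitive).
#' @param step Window step in nucleotides; 3 reads the frame, 1 slides.
#' @return Named integer vector of length 64 (all codons present), summing to
#'   the number of complete unambiguous windows read.
#' @examples
#' count_codons("ATGAAAT")[c("ATG", "AAA")]  # trailing "T" dropped
#' @export
count_codons <- function(cds, step = 3L) {
  if (!is.character(cds) || length(cds) != 1 || is.na(cds))
    stopf("`cds` must be a single string")
  if (!nzchar(cds)) stopf("`cds` is empty")
  ct <- codon_table()
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 3) {
    counts <- integer(64)
    names(counts) <- ct$codons
    return(counts)
  }
  starts <- seq.int(1L, n - 2L, by = as.integer(step))
  tri <- substring(cds, starts, starts + 2L)
  tri <- tri[!grepl("[^ACGT]", tri)]
  counts <- as.integer(table(factor(tri, levels = ct$codons)))
  names(counts) <- ct$codons
  counts
}

#' Normalized codon frequencies
#'
#' @param counts Named 64-vector of codon counts (see [count_codons()]).
#' @return Named numeric(64) of frequencies summing to 1.
#' @export
codon_frequencies <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stopf("no complete codons to normalize")
  counts / total
}

#' Relative synonymous codon usage (RSCU)
#'
#' For codon i in an n-fold synonymous family with counts X, RSCU_i is the
#' observed count divided by the count expected under uniform usage within
#' the family: `RSCU_i = X_i / ((1/n) * sum(X_family))`. Families that never
#' occur get RSCU 0 for all members. Single-codon families (Met, Trp) have
#' RSCU 1 whenever observed.
#'
#' @param counts Named 64-vector of codon counts.
#' @param table A [codon_table()].
#' @return List with `values` (named numeric(64)) and `rscu_max`
#'   (the maximum over all 64 codons).
#' @examples
#' cc <- count_codons("AAAAAAAAAAAAAAG")  # Lys family counts (AAA=4, AAG=1)
#' rscu_profile(cc)$values[c("AAA", "AAG")]
#' @export
rscu_profile <- function(counts, table = codon_table()) {
  if (length(counts) != 64 || is.null(names(counts)))
    stopf("`counts` must be a named 64-vector")
  counts <- counts[table$codons]
  fam_tot <- tapply(counts, table$aa[table$codons], sum)
  expected <- as.numeric(fam_tot[table$aa[table$codons]]) / table$degeneracy
  values <- as.numeric(ifelse(expected > 0, counts / expected, 0))
  names(values) <- table$codons
  list(values = values, rscu_max = max(values))
}

#' Relative adaptiveness weights for CAI
#'
#' Within each synonymous family, `w_i = RSCU_i / max(RSCU_family)`, so the
#' family-preferred codon has weight 1. Weights may be derived from a single
#' gene's own counts (`self` mode) or from the pooled counts of a reference
#' gene set (`reference` mode; pass the summed counts).
#'
#' @inheritParams rscu_profile
#' @return Named numeric(64) of weights in \[0, 1\]; codons of unobserved
#'   families get weight 0.
#' @export
cai_weights <- function(counts, table = codon_table()) {
  rs <- rscu_profile(counts, table)$values
  fam_max <- tapply(rs, table$aa[table$codons], max)
  denom <- as.numeric(fam_max[table$aa[table$codons]])
  w <- as.numeric(ifelse(denom > 0, rs / denom, 0))
  names(w) <- table$codons
  w
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of relative adaptiveness values r_i over the L codon
#' occurrences of a gene, excluding methionine, tryptophan and stop codons
#' (whose usage carries no synonymous choice). Computed in log space.
#'
#' With `weights = NULL` (self mode) the weights come from the gene's own
#' RSCU, in which case an occurring codon always has r > 0. Under external
#' reference weights a codon absent from the reference would contribute
#' r = 0 and collapse the geometric mean; such occurrences are floored at
#' `r_floor` (default 0.01 in reference mode).
#'
#' @param counts Named 64-vector of codon counts for the gene.
#' @param weights Optional named 64-vector from [cai_weights()]; `NULL` for
#'   self mode.
#' @param table A [codon_table()].
#' @param r_floor Floor applied to zero weights of occurring codons; `NULL`
#'   (the self-mode default) errors instead of flooring.
#' @return CAI in \[0, 1\].
#' @export
cai <- function(counts, weights = NULL, table = codon_table(),
                r_floor = if (is.null(weights)) NULL else 0.01) {
  if (is.null(weights)) weights <- cai_weights(counts, table)
  counts <- counts[table$codons]
  weights <- weights[table$codons]
  excluded <- table$aa[table$codons] %in% c("M", "W", "*")
  use <- !excluded & counts > 0
  L <- sum(counts[use])
  if (L == 0) stopf("CAI undefined: no eligible codons (all Met/Trp/stop)")
  r <- weights[use]
  if (any(r <= 0)) {
    if (is.null(r_floor))
      stopf("CAI undefined: occurring codon with zero weight (set `r_floor`)")
    r <- pmax(r, r_floor)
  }
  exp(sum(counts[use] * log(r)) / L)
}

#' GC content of a nucleotide sequence
#'
#' Fraction (G + C) / (A + C + G + T); ambiguous symbols are excluded from
#' both numerator and denominator.
#'
#' @param cds A single nucleotide string.
#' @return GC fraction in \[0, 1\].
#' @export
gc_content <- function(cds) {
  if (!is.character(cds) || length(cds) != 1 || !nzchar(cds))
    stopf("`cds` must be a nonempty string")
  ch <- strsplit(toupper(cds), "", fixed = TRUE)[[1]]
  acgt <- ch[ch %in% c("A", "C", "G", "T")]
  if (!length(acgt)) stopf("no unambiguous bases in sequence")
  sum(acgt %in% c("G", "C")) / length(acgt)
}

#' Amino-acid frequencies of a protein sequence
#'
#' Frequencies over the 20 canonical residues; non-canonical symbols
#' (X, B, Z, U, `*`, ...) are excluded from numerator and denominator.
#'
#' @param protein A single amino-acid string.
#' @return Named numeric(20) summing to 1, alphabetical residue order.
#' @export
aa_frequencies <- function(protein) {
  if (!is.character(protein) || length(protein) != 1 || !nzchar(protein))
    stopf("`protein` must be a nonempty string")
  aas <- codon_table()$amino_acids
  ch <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  ch <- ch[ch %in% aas]
  if (!length(ch)) stopf("no canonical residues in protein")
  tab <- table(factor(ch, levels = aas))
  freq <- as.numeric(tab) / length(ch)
  names(freq) <- aas
  freq
}

#' Build the 89-column sequence feature matrix
#'
#' One row per gene, fixed column order: the 64 codon frequencies, GC
#' content, gene length (nucleotides), CAI, maximum RSCU (68
#' nucleotide-derived columns), then the 20 amino-acid frequencies and the
#' protein length (21 protein-derived columns). Lengths are raw character
#' counts, measured before any window skipping.
#'
#' @param genes Data frame with character columns `gene_id`, `cds`,
#'   `protein` (one row per gene), e.g. the `genes` element of
#'   [simulate_cohort()].
#' @param table A [codon_table()].
#' @param cai_mode `"self"` (weights from each gene's own RSCU) or
#'   `"reference"` (shared weights from `reference_weights`).
#' @param reference_weights Named 64-vector from [cai_weights()]; required in
#'   reference mode.
#' @return Numeric matrix `n x 89`, rownames = gene ids, with attributes
#'   `nucleotide_cols` and `protein_cols` giving the two column blocks.
#' @examples
#' cohort <- simulate_cohort(sim_params(n_genes = 5, seed = 1))
#' m <- build_feature_matrix(cohort$genes)
#' dim(m)  # 5 x 89
#' @export
build_feature_matrix <- function(genes, table = codon_table(),
                                 cai_mode = c("self", "reference"),
                                 reference_weights = NULL) {
  cai_mode <- match.arg(cai_mode)
  if (!all(c("gene_id", "cds", "protein") %in% names(genes)))
    stopf("`genes` needs columns gene_id, cds, protein")
  if (cai_mode == "reference" && is.null(reference_weights))
    stopf("reference CAI mode needs `reference_weights`")
  cols <- c(paste0("codon_", table$codons), "gc_content", "gene_length",
            "cai", "rscu_max", paste0("aa_", table$amino_acids),
            "protein_length")
  out <- matrix(NA_real_, nrow = nrow(genes), ncol = length(cols),
                dimnames = list(genes$gene_id, cols))
  for (i in seq_len(nrow(genes))) {
    row <- tryCatch({
      counts <- count_codons(genes$cds[i])
      rs <- rscu_profile(counts, table)
      w <- if (cai_mode == "self") NULL else reference_weights
      c(codon_frequencies(counts),
        gc_content(genes$cds[i]),
        nchar(genes$cds[i]),
        cai(counts, weights = w, table = table),
        rs$rscu_max,
        aa_frequencies(genes$protein[i]),
        nchar(genes$protein[i]))
    }, error = function(e) {
      stopf("gene %s: %s", genes$gene_id[i], conditionMessage(e))
    })
    out[i, ] <- row
  }
  attr(out, "nucleotide_cols") <- 1:68
  attr(out, "protein_cols") <- 69:89
  out
}

#' Fit / apply a column standardizer
#'
#' `fit_standardizer()` records per-column mean and population standard
#' deviation over `fit_rows` (training rows only, by default the whole
#' matrix for the paper-literal global scaling); `apply_standardizer()` maps
#' each column to mean 0, sd 1 over the fitted rows. Constant columns are
#' mapped to all-zero.
#'
#' @param x Numeric matrix.
#' @param fit_rows Row indices to fit on (default: all rows).
#' @return `fit_standardizer()`: an object of class `standardizer` with
#'   fields `mean`, `sd`, `fit_scope`; `apply_standardizer()`: the
#'   transformed matrix.
#' @export
fit_standardizer <- function(x, fit_rows = seq_len(nrow(x))) {
  if (!length(fit_rows)) stopf("`fit_rows` is empty")
  xs <- x[fit_rows, , drop = FALSE]
  m <- colMeans(xs)
  sd <- sqrt(colMeans(sweep(xs, 2, m)^2))  # population sd
  structure(list(mean = m, sd = sd,
                 fit_scope = if (length(fit_rows) == nrow(x)) "all"
                             else "train_only"),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param params A fitted `standardizer`.
#' @export
apply_standardizer <- function(x, params) {
  stopifnot(inherits(params, "standardizer"))
  sd <- ifelse(params$sd > 0, params$sd, 1)
  out <- sweep(sweep(x, 2, params$mean), 2, sd, "/")
  out[, params$sd == 0] <- 0
  out
}
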