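# Seeded synthetic cohorts: toy genomes with class-dependent codon usage,
# hub-biased interaction networks, and screening-dataset membership tables.
# These emulate the statistical structure essentiality predictors exploit
# (codon bias in essential genes; the centrality-lethality effect) so every
# downstream stage can be exercised offline.

#' Parameters for the synthetic cohort generator
#'
#' Defaults define the reference simulation conditions used throughout the
#' package's tests: 1000 genes of which 20% are essential, a strong planted
#' codon bias (preferred codon up-weighted 3x) and a strong hub bias
#' (essential genes with 4x the expected degree).
#'
#' @param n_genes Number of genes.
#' @param essential_fraction Fraction of essential genes, strictly in (0, 1).
#' @param codon_bias_strength Nonnegative; essential genes draw each
#'   synonymous codon with the family-preferred codon up-weighted by
#'   `1 + codon_bias_strength` (0 = both classes share the uniform codon
#'   distribution).
#' @param cds_length_range Integer pair: min/max CDS length in codons
#'   (including start and stop; lower bound at least 10).
#' @param hub_bias Nonnegative; essential genes have expected degree
#'   `mean_degree * (1 + hub_bias)` (0 = degree independent of label).
#' @param mean_degree Expected degree of a nonessential gene.
#' @param assortativity Relative affinity of essential-essential pairs
#'   (>= 1; 1 = pure degree bias). Class propensities are renormalized so
#'   expected degrees stay at their targets whatever the affinity;
#'   values above 1 make essential genes cluster, emulating the protein
#'   complexes essential genes occupy in real interactomes and giving
#'   random-walk embeddings a recoverable signal.
#' @param n_datasets Number of simulated essentiality screens for the
#'   membership table.
#' @param membership_rate_essential,membership_rate_nonessential Per-screen
#'   inclusion probabilities for essential / nonessential genes.
#' @param seed Master seed; split internally into independent substreams for
#'   sequences, network and membership.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(n_genes = 1000, essential_fraction = 0.2,
                       codon_bias_strength = 2,
                       cds_length_range = c(100L, 400L),
                       hub_bias = 3, mean_degree = 10, assortativity = 3,
                       n_datasets = 16,
                       membership_rate_essential = 0.75,
                       membership_rate_nonessential = 0.01,
                       seed = 1L) {
  if (!is_count(n_genes) || n_genes < 2) stopf("`n_genes` must be a count >= 2")
  if (!(essential_fraction > 0 && essential_fraction < 1))
    stopf("`essential_fraction` must be strictly between 0 and 1")
  if (codon_bias_strength < 0) stopf("`codon_bias_strength` must be >= 0")
  if (length(cds_length_range) != 2 || cds_length_range[1] < 10 ||
      cds_length_range[2] < cds_length_range[1])
    stopf("`cds_length_range` must be an increasing pair with lower bound >= 10 codons")
  if (hub_bias < 0) stopf("`hub_bias` must be >= 0")
  if (mean_degree <= 0) stopf("`mean_degree` must be positive")
  if (assortativity < 1) stopf("`assortativity` must be >= 1")
  if (!is_count(n_datasets)) stopf("`n_datasets` must be a positive count")
  structure(list(
    n_genes = as.integer(n_genes),
    essential_fraction = essential_fraction,
    codon_bias_strength = codon_bias_strength,
    cds_length_range = as.integer(cds_length_range),
    hub_bias = hub_bias,
    mean_degree = mean_degree,
    assortativity = assortativity,
    n_datasets = as.integer(n_datasets),
    membership_rate_essential = membership_rate_essential,
    membership_rate_nonessential = membership_rate_nonessential,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic cohort parameters: %d genes (%.0f%% essential), codon bias %.2g,\n",
    "  hub bias %.2g, mean degree %.3g, %d screens, seed %d\n"),
    x$n_genes, 100 * x$essential_fraction, x$codon_bias_strength,
    x$hub_bias, x$mean_degree, x$n_datasets, x$seed))
  invisible(x)
}

# Assign essential/nonessential labels (seeded stream shared with sequences).
sim_labels <- function(params) {
  n_ess <- max(1L, round(params$n_genes * params$essential_fraction))
  ids <- sprintf("g%05d", seq_len(params$n_genes))
  lab <- rep("nonessential", params$n_genes)
  lab[sample.int(params$n_genes, n_ess)] <- "essential"
  names(lab) <- ids
  lab
}

# Sample one codon per amino-acid occurrence, grouped by residue, with the
# family-preferred codon weighted (1 + bias) : 1.
sample_codons <- function(aa_vec, bias, ct) {
  out <- character(length(aa_vec))
  for (a in unique(aa_vec)) {
    idx <- which(aa_vec == a)
    fam <- ct$codons[ct$aa[ct$codons] == a]
    wt <- rep(1, length(fam))
    wt[fam == ct$preferred[[a]]] <- 1 + bias
    out[idx] <- sample(fam, length(idx), replace = TRUE, prob = wt / sum(wt))
  }
  out
}

#' Generate a labelled synthetic gene set
#'
#' Each gene gets a protein sampled uniformly over the 20 residues (first
#' residue fixed to Met) and a CDS built by choosing, per residue, a codon
#' from its synonymous family: essential genes tilt each family towards its
#' preferred codon by factor `1 + codon_bias_strength`, nonessential genes
#' use the uniform family distribution. The same tilt applies to the
#' appended stop codon's 3-fold family. The CDS therefore always starts with
#' ATG, ends with a stop, has length a multiple of 3, and translates exactly
#' to the protein (minus the stop).
#'
#' @param params A [sim_params()].
#' @return List with `genes` (data frame `gene_id`, `cds`, `protein`) and
#'   `labels` (named character vector, `essential`/`nonessential`).
#' @export
generate_gene_set <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  ct <- codon_table()
  with_seed_(derive_seed(params$seed, 1L), {
    labels <- sim_labels(params)
    n <- params$n_genes
    len <- sample(params$cds_length_range[1]:params$cds_length_range[2],
                  n, replace = TRUE)  # total codons incl. start + stop
    body_len <- len - 2L
    # Sample all body residues for all genes at once, then codons per class.
    body_aa <- sample(ct$amino_acids, sum(body_len), replace = TRUE)
    gene_of <- rep.int(seq_len(n), body_len)
    is_ess <- labels == "essential"
    aa_codon <- character(length(body_aa))
    for (cls in c(TRUE, FALSE)) {
      sel <- is_ess[gene_of] == cls
      bias <- if (cls) params$codon_bias_strength else 0
      aa_codon[sel] <- sample_codons(body_aa[sel], bias, ct)
    }
    stops <- character(n)
    stops[is_ess] <- sample_codons(rep("*", sum(is_ess)),
                                   params$codon_bias_strength, ct)
    stops[!is_ess] <- sample_codons(rep("*", sum(!is_ess)), 0, ct)
    gene_fac <- factor(gene_of, levels = seq_len(n))
    cds <- paste0("ATG",
                  vapply(split(aa_codon, gene_fac), paste, character(1),
                         collapse = ""),
                  stops)
    protein <- paste0("M", vapply(split(body_aa, gene_fac), paste,
                                  character(1), collapse = ""))
    list(genes = data.frame(gene_id = names(labels), cds = cds,
                            protein = protein, stringsAsFactors = FALSE),
         labels = labels)
  })
}

#' Generate a hub-biased random interaction network
#'
#' Independent-edge random graph in the degree-corrected block-model
#' family. Each node carries a class propensity and essential-essential
#' pairs an affinity `assortativity`; the edge probability for pair (i, j)
#' is `c * w_i * w_j * omega_ij` (capped at 1). The essential-class
#' propensity and the global scale are solved in closed form so that the
#' expected degree of a nonessential node is exactly `mean_degree` and that
#' of an essential node exactly `mean_degree * (1 + hub_bias)`, whatever
#' the affinity. No self-loops, no duplicate edges.
#'
#' @param labels Named label vector as produced by [generate_gene_set()].
#' @param params A [sim_params()].
#' @return Data frame with columns `from`, `to` (gene ids).
#' @export
generate_ppi <- function(labels, params) {
  stopifnot(inherits(params, "sim_params"))
  labels <- canonical_labels(labels)
  if (!length(labels)) stopf("`labels` is empty")
  with_seed_(derive_seed(params$seed, 2L), {
    n <- length(labels)
    ess <- labels == "essential"
    n_e <- sum(ess); n_n <- n - n_e
    rho <- 1 + params$hub_bias      # target degree ratio essential:nonessential
    a <- params$assortativity
    # propensity u of essential nodes (nonessential propensity fixed at 1)
    # solves u * (a*u*n_e + n_n) / (u*n_e + n_n) = rho
    disc <- (n_n - rho * n_e)^2 + 4 * a * n_e * rho * n_n
    u <- (-(n_n - rho * n_e) + sqrt(disc)) / (2 * a * n_e)
    w <- ifelse(ess, u, 1)
    scale <- params$mean_degree / (u * n_e + n_n)  # sets E[deg | noness]
    from <- integer(0); to <- integer(0)
    for (i in seq_len(n - 1L)) {
      j <- (i + 1L):n
      omega <- ifelse(ess[i] & ess[j], a, 1)
      p <- pmin(scale * w[i] * w[j] * omega, 1)
      hit <- j[stats::runif(length(j)) < p]
      if (length(hit)) {
        from <- c(from, rep.int(i, length(hit)))
        to <- c(to, hit)
      }
    }
    ids <- names(labels)
    data.frame(from = ids[from], to = ids[to], stringsAsFactors = FALSE)
  })
}

#' Generate a screening-dataset membership table
#'
#' Each gene is included in each of `n_datasets` simulated screens
#' independently, with probability `membership_rate_essential` for essential
#' genes and `membership_rate_nonessential` for nonessential ones, so a
#' consensus rule ("essential if seen in at least 5 screens") approximately
#' recovers the planted labels.
#'
#' @inheritParams generate_ppi
#' @return Integer 0/1 matrix, genes x datasets (columns `ds1..dsK`).
#' @export
generate_membership <- function(labels, params) {
  stopifnot(inherits(params, "sim_params"))
  labels <- canonical_labels(labels)
  with_seed_(derive_seed(params$seed, 3L), {
    n <- length(labels)
    k <- params$n_datasets
    p <- ifelse(labels == "essential", params$membership_rate_essential,
                params$membership_rate_nonessential)
    m <- matrix(stats::rbinom(n * k, 1L, rep(p, k)), nrow = n, ncol = k,
                dimnames = list(names(labels), paste0("ds", seq_len(k))))
    m
  })
}

#' Simulate a full synthetic cohort
#'
#' Runs [generate_gene_set()], [generate_ppi()] and [generate_membership()]
#' on independent substreams of the master seed, so regenerating one
#' component does not perturb the others.
#'
#' @param params A [sim_params()].
#' @return Object of class `synthetic_cohort`: list with `genes`, `labels`,
#'   `edges`, `membership`, `params`.
#' @examples
#' cohort <- simulate_cohort(sim_params(n_genes = 50, seed = 7))
#' table(cohort$labels)
#' @export
simulate_cohort <- function(params = sim_params()) {
  gs <- generate_gene_set(params)
  edges <- generate_ppi(gs$labels, params)
  membership <- generate_membership(gs$labels, params)
  structure(list(genes = gs$genes, labels = gs$labels, edges = edges,
                 membership = membership, params = params),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d genes (%d essential), %d edges, %d screens\n",
              nrow(x$genes), sum(x$labels == "essential"), nrow(x$edges),
              ncol(x$membership)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits `cds.fasta`, `protein.fasta` (matching identifiers), `edges.tsv`
#' (two columns, no header), `labels.csv` (`gene_id,label`) and
#' `membership.csv` (`gene_id` plus one 0/1 column per screen).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cds = file.path(dir, "cds.fasta"),
             protein = file.path(dir, "protein.fasta"),
             edges = file.path(dir, "edges.tsv"),
             labels = file.path(dir, "labels.csv"),
             membership = file.path(dir, "membership.csv"))
  dna <- Biostrings::DNAStringSet(stats::setNames(cohort$genes$cds,
                                                  cohort$genes$gene_id))
  Biostrings::writeXStringSet(dna, paths[["cds"]])
  aa <- Biostrings::AAStringSet(stats::setNames(cohort$genes$protein,
                                                cohort$genes$gene_id))
  Biostrings::writeXStringSet(aa, paths[["protein"]])
  utils::write.table(cohort$edges, paths[["edges"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.csv(data.frame(gene_id = names(cohort$labels),
                              label = unname(cohort$labels)),
                   paths[["labels"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(gene_id = rownames(cohort$membership),
                              cohort$membership, check.names = FALSE),
                   paths[["membership"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
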