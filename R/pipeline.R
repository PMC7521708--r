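# End-to-end orchestration: consensus label assembly from multi-screen
# membership, feature assembly/intersection, declarative run configuration
# and the run-all driver.

#' Assemble labels from a dataset-membership table
#'
#' A gene is called essential when it appears in at least `min_datasets`
#' screens. Genes seen in at least one screen but below the threshold are
#' excluded entirely — they are neither essential nor admitted to the
#' nonessential pool. Genes in no screen form the nonessential pool.
#'
#' @param membership Binary 0/1 matrix or data frame, genes x screens
#'   (rownames or a `gene_id` column give the identifiers).
#' @param min_datasets Consensus threshold (default 5).
#' @return List with `essential`, `nonessential`, `excluded` (identifier
#'   vectors) and `labels` (named vector over the first two groups).
#' @export
assemble_labels <- function(membership, min_datasets = 5L) {
  if (is.data.frame(membership)) {
    if ("gene_id" %in% names(membership)) {
      rn <- membership$gene_id
      membership <- as.matrix(membership[setdiff(names(membership), "gene_id")])
      rownames(membership) <- rn
    } else membership <- as.matrix(membership)
  }
  if (!all(membership %in% c(0, 1))) stopf("membership entries must be 0/1")
  if (is.null(rownames(membership))) stopf("membership needs gene identifiers")
  counts <- rowSums(membership)
  essential <- rownames(membership)[counts >= min_datasets]
  excluded <- rownames(membership)[counts >= 1 & counts < min_datasets]
  nonessential <- rownames(membership)[counts == 0]
  labels <- c(stats::setNames(rep("essential", length(essential)), essential),
              stats::setNames(rep("nonessential", length(nonessential)),
                              nonessential))
  list(essential = essential, nonessential = nonessential,
       excluded = excluded, labels = labels)
}

feature_set_blocks <- function(feature_set) {
  switch(feature_set,
         "S" = list(seq = TRUE, net = "none"),
         "N" = list(seq = FALSE, net = "embedding"),
         "N+S" = list(seq = TRUE, net = "embedding"),
         "S+DC" = list(seq = TRUE, net = "DC"),
         "S+BC" = list(seq = TRUE, net = "BC"),
         "S+EC" = list(seq = TRUE, net = "EC"),
         "S+CC" = list(seq = TRUE, net = "CC"),
         stopf("unknown feature_set %s", feature_set))
}

#' Assemble the modelling dataset for a feature set
#'
#' Row-wise concatenation, sequence block first then network block, over
#' the identifier intersection of all required inputs. Widths: 89 for `S`,
#' 64 for `N`, 153 for `N+S`, 90 for `S+` one centrality.
#'
#' @param seq_matrix Sequence feature matrix ([build_feature_matrix()]), or
#'   `NULL` when the feature set does not need it.
#' @param embeddings Embedding matrix ([train_embeddings()]), or `NULL`.
#' @param centrality Centrality data frame ([centralities()]), or `NULL`.
#' @param labels Named label vector.
#' @param feature_set One of `"S"`, `"N"`, `"N+S"`, `"S+DC"`, `"S+BC"`,
#'   `"S+EC"`, `"S+CC"`.
#' @return List with `x` (feature matrix), `labels` (matching rows),
#'   `feature_set` and `dropped` (identifiers lost in the intersection).
#' @export
assemble_features <- function(seq_matrix = NULL, embeddings = NULL,
                              centrality = NULL, labels,
                              feature_set = "N+S") {
  labels <- canonical_labels(labels)
  blocks <- feature_set_blocks(feature_set)
  ids <- names(labels)
  if (blocks$seq) {
    if (is.null(seq_matrix)) stopf("%s needs the sequence matrix", feature_set)
    ids <- intersect(ids, rownames(seq_matrix))
  }
  if (blocks$net == "embedding") {
    if (is.null(embeddings)) stopf("%s needs embeddings", feature_set)
    ids <- intersect(ids, rownames(embeddings))
  } else if (blocks$net != "none") {
    if (is.null(centrality)) stopf("%s needs centrality scores", feature_set)
    ids <- intersect(ids, centrality$gene_id)
  }
  if (!length(ids)) stopf("empty identifier intersection")
  parts <- list()
  if (blocks$seq) parts$seq <- seq_matrix[ids, , drop = FALSE]
  if (blocks$net == "embedding") {
    parts$net <- embeddings[ids, , drop = FALSE]
  } else if (blocks$net != "none") {
    v <- centrality[[blocks$net]][match(ids, centrality$gene_id)]
    parts$net <- matrix(v, ncol = 1, dimnames = list(ids, blocks$net))
  }
  x <- do.call(cbind, parts)
  rownames(x) <- ids
  dropped <- setdiff(names(labels), ids)
  list(x = x, labels = labels[ids], feature_set = feature_set,
       dropped = dropped)
}

#' Build a run configuration
#'
#' Declarative configuration for [run_all()]: either a YAML file path or a
#' named list; missing entries fall back to the defaults below (which hold
#' every protocol constant — consensus threshold 5, negative ratio 1:4,
#' class weight 4, 128/256/512 architecture, dropout 0.2, 64 embedding
#' dimensions, 10 repetitions).
#'
#' @param config YAML path or named list of overrides.
#' @return Object of class `essnet_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    simulate = TRUE, sim = list(), paths = list(),
    min_datasets = 5L, labels_from = "planted",  # or "membership"
    feature_set = "N+S",
    hidden = c(128L, 256L, 512L), dropout = 0.2,
    class_weight = c(nonessential = 1, essential = 4),
    node2vec = list(),
    n_reps = 10L, neg_ratio = 4, threshold = 0.5,
    seed = 1L, outdir = NULL
  )
  cfg <- utils::modifyList(defaults, config)
  cfg$class_weight <- unlist(cfg$class_weight)
  structure(cfg, class = "essnet_config")
}

write_json_report <- function(report, path) {
  jsonlite::write_json(list(means = as.list(report$means),
                            n_undefined = as.list(report$n_undefined),
                            per_rep = report$per_rep,
                            config = report$config),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
}

#' Run the full pipeline
#'
#' Simulate (or load) a cohort, extract sequence features, learn network
#' embeddings and/or centralities as the feature set requires, assemble the
#' dataset, and run the repeated-holdout evaluation. When `outdir` is set,
#' writes the feature matrix, embeddings, labels, the evaluation report
#' (JSON) and a manifest with seeds and MD5 content hashes of every output.
#'
#' @param config An [run_config()] (or anything it accepts).
#' @return The `eval_report`, invisibly, with the assembled dataset attached
#'   as attribute `"dataset"`.
#' @export
run_all <- function(config = run_config()) {
  cfg <- if (inherits(config, "essnet_config")) config else run_config(config)
  seed <- cfg$seed

  if (isTRUE(cfg$simulate)) {
    params <- do.call(sim_params, utils::modifyList(list(seed = seed), cfg$sim))
    cohort <- simulate_cohort(params)
    genes <- cohort$genes
    edges <- cohort$edges
    labels <- cohort$labels
    membership <- cohort$membership
  } else {
    p <- cfg$paths
    cds <- Biostrings::readDNAStringSet(p$cds)
    prot <- Biostrings::readAAStringSet(p$protein)
    ids <- intersect(names(cds), names(prot))
    if (length(ids) < max(length(cds), length(prot)))
      warning("identifier mismatch between FASTA files; intersecting")
    genes <- data.frame(gene_id = ids,
                        cds = as.character(cds[ids]),
                        protein = as.character(prot[ids]),
                        stringsAsFactors = FALSE)
    edges <- read_edge_list(p$edges)
    if (!is.null(p$membership)) {
      membership <- utils::read.csv(p$membership, check.names = FALSE)
      labels <- NULL
    } else {
      lab_df <- utils::read.csv(p$labels)
      labels <- stats::setNames(lab_df$label, lab_df$gene_id)
      membership <- NULL
    }
  }
  if (identical(cfg$labels_from, "membership") ||
      (is.null(labels) && !is.null(membership))) {
    labels <- assemble_labels(membership, cfg$min_datasets)$labels
  }
  labels <- canonical_labels(labels)

  blocks <- feature_set_blocks(cfg$feature_set)
  seq_matrix <- if (blocks$seq) {
    keep <- genes$gene_id %in% names(labels)
    build_feature_matrix(genes[keep, , drop = FALSE])
  } else NULL
  g <- NULL; emb <- NULL; cent <- NULL
  if (blocks$net == "embedding") {
    g <- ppi_network(edges)
    n2v <- do.call(node2vec_params,
                   utils::modifyList(list(seed = derive_seed(seed, 31L)),
                                     cfg$node2vec))
    emb <- node2vec_embed(g, n2v)
  } else if (blocks$net != "none") {
    g <- ppi_network(edges)
    cent <- centralities(g)
  }
  ds <- assemble_features(seq_matrix, emb, cent, labels, cfg$feature_set)

  plans <- make_splits(ds$labels, n_reps = cfg$n_reps,
                       neg_ratio = cfg$neg_ratio,
                       seed = derive_seed(seed, 41L))
  report <- run_experiment(ds$x, ds$labels, plans,
                           default_model_factory(
                             hidden = cfg$hidden, dropout = cfg$dropout,
                             class_weight = cfg$class_weight),
                           threshold = cfg$threshold)

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    out <- character(0)
    f <- function(name) file.path(cfg$outdir, name)
    utils::write.table(data.frame(gene_id = rownames(ds$x), ds$x,
                                  check.names = FALSE),
                       f("features.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out <- c(out, f("features.tsv"))
    if (!is.null(emb)) { write_embeddings(emb, f("embeddings.txt"))
      out <- c(out, f("embeddings.txt")) }
    utils::write.csv(data.frame(gene_id = names(ds$labels),
                                label = unname(ds$labels)),
                     f("labels.csv"), row.names = FALSE, quote = FALSE)
    out <- c(out, f("labels.csv"))
    write_json_report(report, f("report.json"))
    out <- c(out, f("report.json"))
    manifest <- list(seed = seed, feature_set = cfg$feature_set,
                     n_genes = nrow(ds$x),
                     r_version = as.character(getRversion()),
                     files = as.list(tools::md5sum(out)))
    jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  attr(report, "dataset") <- ds
  invisible(report)
}
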