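# Imbalanced-learning evaluation: confusion-matrix rates, ROC-AUC, average
# precision, repeated stratified holdouts with negative downsampling, axis
# sweeps (class weight / dropout / depth / feature set) and the top-K
# centrality baseline.

#' Confusion counts
#'
#' Cross-tabulates binary predictions against truth; essential is the
#' positive class.
#'
#' @param y_true,y_pred Equal-length label vectors (any coding accepted by
#'   the package: `essential`/`nonessential`, factor, or 0/1).
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stopf("length mismatch")
  yt <- canonical_labels(y_true) == "essential"
  yp <- canonical_labels(y_pred) == "essential"
  c(TP = sum(yt & yp), FP = sum(!yt & yp),
    TN = sum(!yt & !yp), FN = sum(yt & !yp))
}

#' Sensitivity, specificity, PPV and accuracy
#'
#' `Sn = TP/(TP+FN)`, `Sp = TN/(FP+TN)`, `PPV = TP/(TP+FP)`,
#' `Ac = (TP+TN)/(TP+FN+TN+FP)`. A zero denominator yields `NA` (an
#' explicit undefined marker) rather than 0, so undefined cells never
#' silently deflate averages.
#'
#' @param counts Named vector with `TP`, `FP`, `TN`, `FN` (see
#'   [confusion_counts()]).
#' @return Named numeric `c(Sn, Sp, PPV, Ac)`.
#' @export
classification_rates <- function(counts) {
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  with(as.list(counts), c(
    Sn = safe_div(TP, TP + FN),
    Sp = safe_div(TN, FP + TN),
    PPV = safe_div(TP, TP + FP),
    Ac = safe_div(TP + TN, TP + FN + TN + FP)
  ))
}

#' ROC curve and AUC
#'
#' AUC via the rank (Wilcoxon) formulation — the probability that a random
#' positive outscores a random negative, with ties counting one half — plus
#' the full threshold-sweep ROC polygon.
#'
#' @param y_true Labels (essential = positive).
#' @param scores Numeric scores, higher = more essential.
#' @return List with `auc` and `roc` (data frame `fpr`, `tpr`,
#'   `threshold`).
#' @export
roc_auc <- function(y_true, scores) {
  yt <- canonical_labels(y_true) == "essential"
  if (length(yt) != length(scores)) stopf("length mismatch")
  n_pos <- sum(yt); n_neg <- sum(!yt)
  if (n_pos == 0 || n_neg == 0) stopf("both classes must be present")
  r <- rank(scores)  # mid-ranks: ties count 1/2 in the U statistic
  auc <- (sum(r[yt]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  ys <- yt[ord]; ss <- scores[ord]
  keep <- rev(!duplicated(rev(ss)))  # last element of each tie group
  tpr <- cumsum(ys)[keep] / n_pos
  fpr <- cumsum(!ys)[keep] / n_neg
  list(auc = auc,
       roc = data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                        threshold = c(Inf, ss[keep])))
}

#' Precision-recall curve and average precision
#'
#' Step-interpolated sum over descending-score thresholds:
#' `AP = sum_k (R_k - R_{k-1}) * P_k` with ties processed as one threshold
#' group (no linear interpolation).
#'
#' @inheritParams roc_auc
#' @return List with `ap` and `pr` (data frame `recall`, `precision`,
#'   `threshold`).
#' @export
average_precision <- function(y_true, scores) {
  yt <- canonical_labels(y_true) == "essential"
  if (length(yt) != length(scores)) stopf("length mismatch")
  n_pos <- sum(yt)
  if (n_pos == 0) stopf("at least one positive required")
  ord <- order(scores, decreasing = TRUE)
  ys <- yt[ord]; ss <- scores[ord]
  keep <- rev(!duplicated(rev(ss)))  # end of each tie group
  cum_tp <- cumsum(ys)[keep]
  k <- seq_along(ys)[keep]
  recall <- cum_tp / n_pos
  precision <- cum_tp / k
  ap <- sum(diff(c(0, recall)) * precision)
  list(ap = ap,
       pr = data.frame(recall = recall, precision = precision,
                       threshold = ss[keep]))
}

split_stratified <- function(idx, fractions) {
  n <- length(idx)
  idx <- idx[sample.int(n)]
  n_tr <- round(n * fractions[1])
  n_va <- round(n * fractions[2])
  list(train = idx[seq_len(n_tr)],
       validation = idx[n_tr + seq_len(min(n_va, n - n_tr))],
       test = idx[setdiff(seq_len(n), seq_len(n_tr + n_va))])
}

#' Repeated stratified holdout plans with negative downsampling
#'
#' Per repetition: a fresh seeded downsample of the nonessential pool to
#' `neg_ratio` times the number of essential genes, then a stratified
#' train/validation/test partition (default 80/10/10) preserving the class
#' ratio in each part. Repetitions differ in their random draws but the
#' whole plan list is a pure function of `seed`.
#'
#' @param labels Named label vector over all candidate genes.
#' @param n_reps Number of repetitions (default 10).
#' @param neg_ratio Negatives kept per positive (default 4).
#' @param fractions Train/validation/test fractions, summing to 1.
#' @param seed Master seed.
#' @return List of `n_reps` plans; each plan has integer index vectors
#'   `train`, `validation`, `test` (into `labels`), plus `rep`, `seed` and
#'   the downsampling record `negatives_used`.
#' @export
make_splits <- function(labels, n_reps = 10L, neg_ratio = 4,
                        fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  labels <- canonical_labels(labels)
  if (abs(sum(fractions) - 1) > 1e-8) stopf("`fractions` must sum to 1")
  pos <- which(labels == "essential")
  neg <- which(labels == "nonessential")
  n_neg <- round(neg_ratio * length(pos))
  if (!length(pos)) stopf("no essential genes in `labels`")
  if (length(neg) < n_neg)
    stopf("need %d nonessential genes for ratio %g, have %d", n_neg,
          neg_ratio, length(neg))
  lapply(seq_len(n_reps), function(r) {
    rs <- derive_seed(seed, 100L + r)
    with_seed_(rs, {
      neg_r <- sample(neg, n_neg)
      sp_pos <- split_stratified(pos, fractions)
      sp_neg <- split_stratified(neg_r, fractions)
      structure(list(train = c(sp_pos$train, sp_neg$train),
                     validation = c(sp_pos$validation, sp_neg$validation),
                     test = c(sp_pos$test, sp_neg$test),
                     negatives_used = neg_r, rep = r, seed = rs),
                class = "split_plan")
    })
  })
}

default_model_factory <- function(hidden = c(128, 256, 512), dropout = 0.2,
                                  class_weight = c(nonessential = 1,
                                                   essential = 4), ...) {
  function(x_train, y_train, x_val, y_val, seed) {
    essnet_mlp(x_train, y_train, hidden = hidden, dropout = dropout,
               class_weight = class_weight,
               validation = list(x = x_val, y = y_val), seed = seed, ...)
  }
}

#' Run the repeated-holdout evaluation protocol
#'
#' Per plan: the standardizer is fit on the training rows only, the model is
#' trained with validation-based early stopping, held-out test rows are
#' scored, and all six metrics (Sn, Sp, PPV, Ac at the decision threshold;
#' AUC; AP) are computed. Means are arithmetic means over repetitions;
#' undefined (0/0) cells are skipped with their count recorded.
#'
#' @param x Feature matrix (rows = genes matching `labels`).
#' @param labels Named label vector.
#' @param plans Output of [make_splits()].
#' @param model_factory `function(x_train, y_train, x_val, y_val, seed)`
#'   returning an object with a `predict(object, newdata)` score method;
#'   defaults to the reference MLP configuration.
#' @param threshold Decision threshold for the binary metrics.
#' @param standardize Refit the feature standardizer inside each repetition
#'   (leakage-safe, default) or use the paper-literal global scaling fitted
#'   on all rows.
#' @return Object of class `eval_report`: `per_rep` data frame, `means`,
#'   `n_undefined`, ROC/PR curve points of each repetition, and a
#'   configuration echo.
#' @export
run_experiment <- function(x, labels, plans, model_factory = NULL,
                           threshold = 0.5, standardize = c("train_only", "all")) {
  labels <- canonical_labels(labels)
  standardize <- match.arg(standardize)
  if (nrow(x) != length(labels)) stopf("x rows must match labels")
  if (is.null(model_factory)) model_factory <- default_model_factory()
  global_sp <- if (standardize == "all") fit_standardizer(x) else NULL
  per_rep <- vector("list", length(plans))
  curves <- vector("list", length(plans))
  for (i in seq_along(plans)) {
    pl <- plans[[i]]
    sp <- global_sp %||% fit_standardizer(x, pl$train)
    xt <- apply_standardizer(x, sp)
    y1 <- as.integer(labels == "essential")
    model <- model_factory(xt[pl$train, , drop = FALSE], y1[pl$train],
                           xt[pl$validation, , drop = FALSE],
                           y1[pl$validation], seed = pl$seed)
    scores <- predict(model, xt[pl$test, , drop = FALSE])
    y_test <- y1[pl$test]
    rates <- classification_rates(
      confusion_counts(y_test, as.integer(scores >= threshold)))
    roc <- roc_auc(y_test, scores)
    pr <- average_precision(y_test, scores)
    per_rep[[i]] <- data.frame(rep = pl$rep, t(rates), AUC = roc$auc,
                               AP = pr$ap)
    curves[[i]] <- list(roc = roc$roc, pr = pr$pr)
  }
  per_rep <- do.call(rbind, per_rep)
  metric_cols <- c("Sn", "Sp", "PPV", "Ac", "AUC", "AP")
  means <- colMeans(per_rep[metric_cols], na.rm = TRUE)
  structure(list(per_rep = per_rep, means = means,
                 n_undefined = colSums(is.na(per_rep[metric_cols])),
                 curves = curves,
                 config = list(threshold = threshold,
                               standardize = standardize,
                               n_reps = length(plans))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d repetitions (threshold %.2f):\n",
              x$config$n_reps, x$config$threshold))
  print(round(x$means, 4))
  if (any(x$n_undefined > 0))
    cat("  undefined cells skipped:",
        paste(sprintf("%s=%d", names(x$n_undefined),
                      x$n_undefined)[x$n_undefined > 0], collapse = ", "),
        "\n")
  invisible(x)
}

#' Sweep one experimental axis
#'
#' Reruns the full protocol for each value of one axis, sharing the same
#' split plans so comparisons are paired: `class_weight` (weight on the
#' essential class), `dropout`, `depth` (list of hidden-width vectors) or
#' `feature_set` (named list of feature matrices, e.g. `N`, `S`, `N+S`,
#' `S+DC`).
#'
#' @param x Feature matrix, or for `axis = "feature_set"` a named list of
#'   matrices (all with rows matching `labels`).
#' @param labels Named label vector.
#' @param axis One of `"class_weight"`, `"dropout"`, `"depth"`,
#'   `"feature_set"`.
#' @param values Axis values (for `feature_set`, names into `x`).
#' @param plans Shared split plans from [make_splits()].
#' @param ... Extra arguments to the default model factory (e.g. `hidden`).
#' @return Object of class `eval_sweep`: data frame of mean metrics per
#'   value plus the full `eval_report` list.
#' @export
sweep_experiment <- function(x, labels, axis = c("class_weight", "dropout",
                                                 "depth", "feature_set"),
                             values, plans, ...) {
  axis <- match.arg(axis)
  reports <- vector("list", length(values))
  for (i in seq_along(values)) {
    v <- if (is.list(values)) values[[i]] else values[i]
    if (axis == "feature_set") {
      stopifnot(is.list(x), v %in% names(x))
      rep_i <- run_experiment(x[[v]], labels, plans,
                              default_model_factory(...))
    } else {
      factory <- switch(axis,
        class_weight = default_model_factory(
          class_weight = c(nonessential = 1, essential = as.numeric(v)), ...),
        dropout = default_model_factory(dropout = as.numeric(v), ...),
        depth = default_model_factory(hidden = v, ...))
      rep_i <- run_experiment(if (is.list(x)) x[["N+S"]] %||% x[[1]] else x,
                              labels, plans, factory)
    }
    reports[[i]] <- rep_i
  }
  value_lab <- vapply(seq_along(values), function(i) {
    v <- if (is.list(values)) values[[i]] else values[i]
    paste(v, collapse = "-")
  }, character(1))
  tab <- cbind(data.frame(axis = axis, value = value_lab,
                          stringsAsFactors = FALSE),
               do.call(rbind, lapply(reports, function(r) as.data.frame(t(r$means)))))
  structure(list(table = tab, reports = stats::setNames(reports, value_lab),
                 axis = axis), class = "eval_sweep")
}

#' @export
print.eval_sweep <- function(x, ...) {
  cat("Sweep over", x$axis, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Top-K centrality baseline
#'
#' For each centrality measure: rank genes by descending score (ties broken
#' by gene identifier for reproducibility), label the top `k` as predicted
#' essential, and report accuracy, PPV and sensitivity against the true
#' labels.
#'
#' @param scores Data frame from [centralities()] (`gene_id` + one column
#'   per measure).
#' @param labels Named label vector covering the scored genes.
#' @param k Number of top-ranked genes to call essential (typically the
#'   number of known essential genes).
#' @return Data frame with one row per measure: `measure`, `Ac`, `PPV`,
#'   `Sn`.
#' @export
topk_centrality_eval <- function(scores, labels, k) {
  labels <- canonical_labels(labels)
  ids <- scores$gene_id
  if (!all(ids %in% names(labels))) stopf("labels missing for some scored genes")
  if (!is_count(k) || k > nrow(scores)) stopf("`k` must be a count <= number of nodes")
  yt <- labels[ids]
  measures <- setdiff(names(scores), "gene_id")
  rows <- lapply(measures, function(m) {
    ord <- order(-scores[[m]], ids)
    pred <- rep("nonessential", length(ids))
    pred[ord[seq_len(k)]] <- "essential"
    r <- classification_rates(confusion_counts(yt, pred))
    data.frame(measure = m, Ac = r[["Ac"]], PPV = r[["PPV"]], Sn = r[["Sn"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
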