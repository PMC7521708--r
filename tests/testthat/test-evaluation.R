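# Metrics, split protocol and the centrality baseline evaluation.

test_that("confusion counts cross-tabulate with essential as positive", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(cc, c(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  cc <- confusion_counts(c("essential", "nonessential"),
                         c("essential", "nonessential"))
  expect_equal(unname(cc[c("FP", "FN")]), c(0L, 0L))
  cc <- confusion_counts(c(1, 0, 0), c(1, 1, 1))
  expect_equal(unname(cc[c("TN", "FP")]), c(0L, 2L))
  expect_error(confusion_counts(c(1, 0), 1), "length")
})

test_that("rates match the defining ratios, with NA for 0/0", {
  expect_equal(classification_rates(c(TP = 9, FP = 0, TN = 0, FN = 1))[["Sn"]],
               0.9)
  r <- classification_rates(c(TP = 3, FP = 1, TN = 5, FN = 1))
  expect_equal(r[["PPV"]], 0.75)
  expect_equal(r[["Ac"]], 0.8)
  r0 <- classification_rates(c(TP = 0, FP = 0, TN = 4, FN = 2))
  expect_true(is.na(r0[["PPV"]]))
  expect_false(is.na(r0[["Sp"]]))
})

test_that("rates agree with direct formula evaluation exhaustively", {
  grid <- expand.grid(TP = 0:8, FP = 0:8, TN = 0:8, FN = 0:8)
  got <- t(apply(as.matrix(grid), 1, classification_rates))
  div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  expect_equal(got[, "Sn"], div(grid$TP, grid$TP + grid$FN))
  expect_equal(got[, "Sp"], div(grid$TN, grid$FP + grid$TN))
  expect_equal(got[, "PPV"], div(grid$TP, grid$TP + grid$FP))
  expect_equal(got[, "Ac"],
               div(grid$TP + grid$TN, grid$TP + grid$FP + grid$TN + grid$FN))
})

test_that("AUC matches hand cases and the pairwise oracle", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2))$auc, 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2))$auc, 0.75)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
  set.seed(21)
  for (i in 1:1000) {
    n <- sample(3:12, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # forces ties
    expect_equal(roc_auc(y, s)$auc, oracle_auc(y, s), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(22)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- runif(n)
    a <- roc_auc(y, s)$auc
    expect_equal(roc_auc(y, exp(3 * s))$auc, a, tolerance = 1e-12)
    expect_equal(roc_auc(y, 5 * s - 2)$auc, a, tolerance = 1e-12)
  }
})

test_that("average precision matches hand cases and the sweep oracle", {
  expect_equal(average_precision(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2))$ap, 1.0)
  # one positive ranked second of four
  expect_equal(average_precision(c(0, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1))$ap, 0.5)
  expect_error(average_precision(c(0, 0), c(0.1, 0.2)), "positive")
  set.seed(23)
  for (i in 1:1000) {
    n <- sample(3:12, 1)
    y <- c(1, sample(0:1, n - 1, replace = TRUE))
    s <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    expect_equal(average_precision(y, s)$ap, oracle_ap(y, s),
                 tolerance = 1e-12)
  }
})

test_that("AP of random scores concentrates near prevalence", {
  set.seed(24)
  ap <- replicate(300, {
    y <- c(rep(1, 20), rep(0, 80))
    average_precision(y, runif(100))$ap
  })
  expect_lt(abs(mean(ap) - 0.2), 0.03)
})

test_that("ROC and PR curves are valid threshold sweeps", {
  set.seed(25)
  y <- sample(0:1, 30, replace = TRUE, prob = c(0.7, 0.3))
  s <- runif(30)
  roc <- roc_auc(y, s)$roc
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  pr <- average_precision(y, s)$pr
  expect_true(all(pr$precision >= 0 & pr$precision <= 1))
  expect_equal(pr$recall[nrow(pr)], 1)
})

test_that("split plans downsample, stratify and stay disjoint", {
  labels <- setNames(c(rep("essential", 100), rep("nonessential", 1000)),
                     paste0("g", 1:1100))
  plans <- make_splits(labels, n_reps = 5, neg_ratio = 4, seed = 3)
  expect_length(plans, 5)
  for (pl in plans) {
    used <- c(pl$train, pl$validation, pl$test)
    expect_equal(length(used), 500)  # 100 + 400
    expect_equal(anyDuplicated(used), 0L)
    # stratification within one sample of the global 20% rate
    for (part in list(pl$train, pl$validation, pl$test)) {
      frac <- mean(labels[part] == "essential")
      expect_lt(abs(frac - 0.2), 1 / length(part) + 1e-9)
    }
  }
  # repetitions resample negatives independently
  expect_false(identical(sort(plans[[1]]$negatives_used),
                         sort(plans[[2]]$negatives_used)))
  expect_identical(plans, make_splits(labels, n_reps = 5, neg_ratio = 4,
                                      seed = 3))
  expect_error(make_splits(labels, neg_ratio = 11), "nonessential")
})

test_that("run_experiment aggregates per-repetition metrics", {
  set.seed(26)
  x <- matrix(rnorm(1100 * 3), ncol = 3)
  labels <- setNames(c(rep("essential", 100), rep("nonessential", 1000)),
                     paste0("g", 1:1100))
  rownames(x) <- names(labels)
  plans <- make_splits(labels, n_reps = 3, seed = 4)
  constant_factory <- function(x_train, y_train, x_val, y_val, seed) {
    structure(list(), class = "constant_scorer")
  }
  assign("predict.constant_scorer",
         function(object, newdata, ...) rep(0.5, nrow(newdata)),
         envir = globalenv())
  on.exit(rm("predict.constant_scorer", envir = globalenv()))
  rep <- run_experiment(x, labels, plans, constant_factory)
  expect_equal(unname(rep$means[["AUC"]]), 0.5)
  expect_equal(nrow(rep$per_rep), 3)
  # all-0.5 scores are called essential at the default threshold
  expect_equal(unname(rep$means[["Sn"]]), 1)
  expect_equal(unname(rep$means[["Sp"]]), 0)
  expect_equal(unname(rep$means[["Ac"]]), 0.2, tolerance = 1e-9)
  # means are arithmetic means of the per-repetition values
  expect_equal(unname(rep$means[["AP"]]),
               mean(rep$per_rep$AP))
})

test_that("top-K centrality ranking scores the hub hypothesis", {
  labels <- setNames(c("essential", "essential", "nonessential",
                       "nonessential", "nonessential"), paste0("g", 1:5))
  scores <- data.frame(gene_id = paste0("g", 1:5),
                       DC = c(5, 4, 3, 2, 1))
  r <- topk_centrality_eval(scores, labels, k = 2)
  expect_equal(r$Ac, 1); expect_equal(r$PPV, 1); expect_equal(r$Sn, 1)
  # k = all nodes: sensitivity forced to 1, PPV to prevalence
  r_all <- topk_centrality_eval(scores, labels, k = 5)
  expect_equal(r_all$Sn, 1)
  expect_equal(r_all$PPV, 0.4)
  expect_error(topk_centrality_eval(scores, labels, k = 9), "k")
  # random scores: expected PPV near prevalence (hypergeometric)
  set.seed(27)
  labs <- setNames(sample(c("essential", "nonessential"), 200, TRUE,
                          prob = c(0.25, 0.75)), paste0("g", 1:200))
  ppv <- replicate(200, {
    sc <- data.frame(gene_id = names(labs), DC = runif(200))
    topk_centrality_eval(sc, labs, k = 50)$PPV
  })
  expect_lt(abs(mean(ppv) - mean(labs == "essential")), 0.03)
})

test_that("class-weight sweep shares plans across values", {
  co <- tiny_cohort(n = 120, seed = 17)
  m <- build_feature_matrix(co$genes)
  plans <- make_splits(co$labels, n_reps = 1, seed = 5)
  sw <- sweep_experiment(m, co$labels, axis = "class_weight",
                         values = c(1, 4), plans = plans,
                         hidden = c(8), max_epochs = 10)
  expect_s3_class(sw, "eval_sweep")
  expect_equal(nrow(sw$table), 2)
  expect_equal(sw$table$value, c("1", "4"))
  # a singleton axis reproduces a plain run_experiment
  sw1 <- sweep_experiment(m, co$labels, axis = "class_weight",
                          values = 4, plans = plans,
                          hidden = c(8), max_epochs = 10)
  direct <- run_experiment(m, co$labels, plans,
                           essnet:::default_model_factory(
                             class_weight = c(nonessential = 1, essential = 4),
                             hidden = c(8), max_epochs = 10))
  expect_equal(sw1$reports[[1]]$means, direct$means, tolerance = 1e-12)
})
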