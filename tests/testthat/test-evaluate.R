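# Confusion matrices, the one-vs-rest metric suite and ROC/PR summaries.

test_that("confusion matrices count (true, predicted) pairs", {
  y <- rep(0:3, each = 3)
  cm <- confusion(y, y)
  expect_equal(unname(diag(cm)), rep(3L, 4))
  expect_equal(sum(cm), 12L)

  cm0 <- confusion(y, rep(0L, 12))
  expect_equal(unname(cm0[, 1]), rep(3L, 4))
  expect_equal(sum(cm0[, -1]), 0L)

  cmh <- confusion(c(0, 0, 1, 1, 2), c(0, 1, 1, 1, 2))
  expect_equal(unname(cmh[1, ]), c(1L, 1L, 0L, 0L))
  expect_equal(unname(cmh[2, ]), c(0L, 2L, 0L, 0L))
  expect_equal(unname(cmh[3, ]), c(0L, 0L, 1L, 0L))

  expect_error(confusion(c(0, 9), c(0, 0)), class = "invalid_input")
  expect_error(confusion(0:2, 0:1), class = "invalid_input")
})

test_that("per-class metrics match hand-computed counts", {
  cm <- matrix(c(5, 1, 2, 4), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  rep <- per_class_metrics(cm)
  a <- rep$per_class[1, ]
  expect_equal(c(a$TP, a$FP, a$FN, a$TN), c(5, 2, 1, 4))
  expect_equal(a$Pre, 71.43)
  expect_equal(a$Sen, 83.33)
  expect_equal(a$Spe, 66.67)
  expect_equal(a$Acc, 75.00)
})

test_that("metrics equal the literal one-line formulas on random matrices", {
  set.seed(4)
  for (trial in 1:500) {
    cm <- matrix(rpois(16, 8), 4)
    if (sum(cm) == 0) next
    mine <- per_class_metrics(cm, digits = NULL)
    for (cls in 1:4) {
      ora <- literal_ovr_metrics(cm, cls)
      got <- unlist(mine$per_class[cls, c("Pre", "Sen", "Spe", "F1", "Acc")])
      ok <- !is.na(ora)
      expect_equal(unname(got[ok]), unname(ora[ok]), tolerance = 1e-12)
    }
    expect_equal(mine$overall$Acc, 100 * sum(diag(cm)) / sum(cm),
                 tolerance = 1e-12)
  }
})

test_that("perfect classification scores 100 everywhere and zero cells give NA", {
  rep <- per_class_metrics(diag(4) * 5)
  expect_true(all(unlist(rep$per_class[, c("Pre", "Sen", "Spe", "F1", "Acc")]) == 100))
  # a class that is never predicted nor present yields NA, not NaN
  cm <- diag(c(4, 4, 4, 0))
  r2 <- per_class_metrics(cm)
  expect_true(is.na(r2$per_class$Pre[4]))
  expect_false(any(is.nan(unlist(r2$per_class))))
  expect_error(per_class_metrics(matrix(0, 4, 4)), class = "invalid_input")
})

test_that("ROC/PR summaries behave at the extremes and match concordance", {
  # perfectly separated scores
  y <- c(0, 0, 1, 1, 2, 2, 3, 3)
  s <- ppgfusion:::one_hot(y, 4) * 0.94 + 0.015
  rp <- roc_pr(y, s)
  expect_equal(unname(rp$per_class_auc), rep(1, 4))
  expect_equal(rp$micro_auc, 1)
  expect_equal(rp$micro_ap, 1)

  # label-independent scores: chance-level micro AUC
  s0 <- matrix(0.25, 8, 4)
  expect_equal(roc_pr(y, s0)$micro_auc, 0.5)

  # 2 negatives x 4 positives with one inversion: AUC 7/8
  lab <- c(1, 1, 1, 1, 0, 0)
  sc <- c(0.9, 0.8, 0.7, 0.3, 0.5, 0.1)
  expect_equal(ppgfusion:::roc_auc_binary(lab, sc), 0.875)
  expect_equal(ppgfusion:::roc_auc_binary(lab, sc), concordance_auc(lab, sc))

  # exhaustive small cases match the pairwise-concordance oracle
  set.seed(5)
  for (trial in 1:50) {
    n <- sample(4:8, 1)
    lab <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    sc <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # forces ties too
    expect_equal(ppgfusion:::roc_auc_binary(lab, sc), concordance_auc(lab, sc),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  lab <- sample(c(0, 1), 60, replace = TRUE)
  sc <- runif(60) + 0.4 * lab
  expect_equal(ppgfusion:::roc_auc_binary(lab, sc),
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("evaluate_model assembles report, ROC and confusion coherently", {
  cfg <- tiny_model_config()
  b <- tiny_batch(cfg, n = 20, seed = 8)
  y <- rep(rhythm_classes(), 5)
  m <- fusion_dma(b$x[1:16, ], y[1:16],
                  ssm = b$ssm[1:16, , ], config = cfg,
                  train = train_config(epochs = 1, batch_size = 8))
  rep <- evaluate_model(m, b$x[17:20, ], y[17:20], ssm = b$ssm[17:20, , ])
  expect_s3_class(rep, "eval_report")
  expect_equal(sum(rep$confusion), 4)
  expect_length(rep$roc$per_class_auc, 4)
  expect_output(print(rep), "micro-average")
})
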