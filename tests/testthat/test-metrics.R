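test_that("metrics agree with hand-computed confusion-table values", {
  # TP = 50, FP = 10, FN = 5, TN = 35
  labels <- rep(c(1, 1, 0, 0), c(50, 5, 10, 35))
  probs <- rep(c(0.9, 0.1, 0.9, 0.1), c(50, 5, 10, 35))
  m <- classification_metrics(labels, probs)
  expect_equal(m$precision, 50 / 60)
  expect_equal(m$recall, 50 / 55)
  expect_equal(m$accuracy, 85 / 100)
  expect_equal(unname(m$confusion["1", "1"]), 50)
  expect_equal(unname(m$confusion["0", "1"]), 10)
})

test_that("perfect predictions score 1 on every metric", {
  labels <- rep(c(0, 1), 25)
  m <- classification_metrics(labels, labels * 0.8 + 0.1)
  for (k in c("accuracy", "precision", "recall", "f1", "kappa", "mcc",
              "roc_auc", "pr_auc"))
    expect_equal(m[[k]], 1, info = k)
})

test_that("metrics match independent reference implementations", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(30:120, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    probs <- runif(n)
    if (i %% 3 == 0) probs <- round(probs, 1)  # force ties
    m <- classification_metrics(labels, probs)
    ref_auc <- as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE,
                                              direction = "<")))
    expect_equal(m$roc_auc, ref_auc, tolerance = 1e-9)
    # reference formulas recomputed from the raw confusion table
    tab <- table(factor(labels, 0:1), factor(as.integer(probs >= 0.5), 0:1))
    tn <- tab[1, 1]; fp <- tab[1, 2]; fn <- tab[2, 1]; tp <- tab[2, 2]
    expect_equal(m$accuracy, (tp + tn) / n, tolerance = 1e-9)
    po <- (tp + tn) / n
    pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
    expect_equal(m$kappa, (po - pe) / (1 - pe), tolerance = 1e-9)
    expect_equal(m$mcc,
                 (tp * tn - fp * fn) /
                   sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)),
                 tolerance = 1e-9)
  }
})

test_that("PR-AUC matches scikit-learn average precision", {
  set.seed(12)
  cases <- lapply(1:20, function(i) {
    n <- sample(30:100, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    probs <- if (i %% 2) runif(n) else round(runif(n), 1)
    list(labels = labels, probs = probs)
  })
  infile <- withr::local_tempfile(fileext = ".json")
  outfile <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cases, infile, digits = NA)
  code <- paste(
    "import json, sys",
    "from sklearn.metrics import average_precision_score, roc_auc_score",
    sprintf("cases = json.load(open('%s'))", infile),
    "out = [{'ap': average_precision_score(c['labels'], c['probs']),",
    "        'auc': roc_auc_score(c['labels'], c['probs'])} for c in cases]",
    sprintf("json.dump(out, open('%s', 'w'))", outfile),
    sep = "\n")
  status <- system2(Sys.which("python"), "-", input = code)
  expect_equal(status, 0L)
  ref <- jsonlite::read_json(outfile, simplifyVector = TRUE)
  for (i in seq_along(cases)) {
    expect_equal(pr_auc(cases[[i]]$probs, cases[[i]]$labels), ref$ap[i],
                 tolerance = 1e-9)
    expect_equal(roc_auc(cases[[i]]$probs, cases[[i]]$labels), ref$auc[i],
                 tolerance = 1e-9)
  }
})

test_that("random scores give chance-level ROC-AUC", {
  set.seed(2)
  labels <- rep(0:1, each = 5000)
  expect_equal(roc_auc(runif(10000), labels), 0.5, tolerance = 0.02)
})

test_that("degenerate inputs are handled explicitly", {
  one_class <- classification_metrics(rep(1, 10), runif(10))
  expect_true(is.na(one_class$roc_auc))
  expect_true(is.na(one_class$pr_auc))
  expect_false(is.na(one_class$accuracy))
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
  rm <- regression_metrics(c(1, 2, 3), c(1.5, 2, 2.5))
  expect_equal(rm$mae, 1 / 3)
  expect_equal(rm$pearson_r, cor(c(1, 2, 3), c(1.5, 2, 2.5)))
})
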