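# Brute-force oracles live in helper-oracles.R.

test_that("label grouping follows the ASCO/CAP-derived schemes", {
  g3 <- group_labels(c("0", "1+", "2+", "3+"), "three_class")
  expect_identical(as.character(g3$labels),
                   c("negative", "negative", "borderline", "positive"))
  expect_true(all(g3$keep))
  gb <- group_labels(c("0", "1+", "2+", "3+"), "binary")
  expect_identical(as.character(gb$labels),
                   c("negative", "negative", "positive"))
  expect_identical(gb$keep, c(TRUE, TRUE, FALSE, TRUE))
  g4 <- group_labels(c("3+", "0"), "four_class")
  expect_identical(levels(g4$labels), c("0", "1+", "2+", "3+"))
  ge <- group_labels(character(), "binary")
  expect_identical(length(ge$labels), 0L)
  expect_error(group_labels(c("5+"), "binary"), "unknown HER2 score")
})

test_that("the binary worked example reproduces the textbook values", {
  # TP = 45, FN = 5, FP = 10, TN = 40 with 'positive' the class of interest
  cm <- matrix(c(40, 10, 5, 45), 2, 2, byrow = TRUE,
               dimnames = list(c("neg", "pos"), c("neg", "pos")))
  d <- data_for_confusion(cm)
  rep <- confusion_and_summary(d$y, d$prob)
  pos <- rep$per_class[rep$per_class$class == "b", ]
  expect_equal(pos$precision, 45 / 55, tolerance = 1e-12)       # 81.8%
  expect_equal(pos$recall, 0.90, tolerance = 1e-12)
  expect_equal(pos$f1, 2 * (45 / 55) * 0.9 / (45 / 55 + 0.9),
               tolerance = 1e-12)                               # 85.7%
  expect_equal(rep$accuracy, 85, tolerance = 1e-12)
  expect_equal(round(rep$mcc, 4), 0.7035)
})

test_that("MCC honors its boundary conventions", {
  expect_equal(mcc(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(mcc(c(0, 1, 0, 1), c(1, 1, 1, 1)), 0)   # degenerate -> 0
  expect_error(mcc(1:3, 1:4), "equal length")
  expect_error(mcc(integer(), integer()), "at least one")
})

test_that("perfect predictions give saturated metrics", {
  y <- factor(rep(c("a", "b", "c"), 10))
  prob <- t(vapply(y, function(v) {
    r <- c(0.05, 0.05, 0.05); r[match(v, levels(y))] <- 0.9; r
  }, numeric(3)))
  rep <- confusion_and_summary(y, prob)
  expect_equal(rep$accuracy, 100)
  expect_equal(rep$per_class$f1, rep(1, 3))
  expect_equal(rep$mcc, 1)
  expect_true(all(rep$confusion == diag(10, 3)))
})

test_that("metrics agree with the brute-force oracle on random matrices", {
  set.seed(77)
  for (trial in 1:1000) {
    K <- sample(2:4, 1)
    cm <- matrix(rpois(K * K, 4), K, K)
    diag(cm) <- diag(cm) + rpois(K, 6)
    if (any(rowSums(cm) == 0)) cm <- cm + 1
    d <- data_for_confusion(cm)
    rep <- confusion_and_summary(d$y, d$prob)
    expect_equal(unname(rep$confusion), cm, ignore_attr = TRUE)
    o <- oracle_from_confusion(cm)
    expect_equal(rep$accuracy, 100 * o$accuracy, tolerance = 1e-12)
    expect_equal(rep$precision, 100 * o$precision, tolerance = 1e-12)
    expect_equal(rep$recall, 100 * o$recall, tolerance = 1e-12)
    expect_equal(rep$f1, 100 * o$f1, tolerance = 1e-12)
    expect_equal(rep$mcc, o$mcc, tolerance = 1e-12)
  }
})

test_that("rank AUC equals the pairwise oracle and pROC", {
  e <- asNamespace("her2lite")
  set.seed(101)
  for (trial in 1:50) {
    n <- 30
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2)                  # ties included
    expect_equal(e$auc_binary(y, p), auc_pairwise(y, p), tolerance = 1e-12)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(11)
    y <- rbinom(80, 1, 0.5); p <- runif(80)
    expect_equal(e$auc_binary(y, p),
                 as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))),
                 tolerance = 1e-12)
  }
})

test_that("chance-level probabilities give AUC near 50%", {
  set.seed(55)
  n <- 4000
  y <- factor(rep(c("a", "b"), n / 2))
  p1 <- runif(n)
  rep <- confusion_and_summary(y, cbind(1 - p1, p1))
  expect_lt(abs(rep$auc - 50), 5)
})

test_that("metrics are invariant under consistent class relabeling", {
  set.seed(31)
  for (trial in 1:20) {
    y <- sample(0:3, 60, replace = TRUE)
    pr <- matrix(runif(240), 60, 4)
    pr <- pr / rowSums(pr)
    perm <- sample(4)
    r1 <- confusion_and_summary(factor(y, 0:3), pr)
    r2 <- confusion_and_summary(factor(perm[y + 1], sort(perm)),
                                pr[, order(perm)])
    expect_equal(r1$accuracy, r2$accuracy, tolerance = 1e-12)
    expect_equal(r1$f1, r2$f1, tolerance = 1e-12)
    expect_equal(r1$mcc, r2$mcc, tolerance = 1e-12)
  }
})

test_that("single-class truths yield a missing AUC with a warning", {
  y <- factor(rep("a", 5), levels = c("a", "b"))
  expect_warning(rep <- confusion_and_summary(y, cbind(0.9, 0.1)[rep(1, 5), ]),
                 "AUC undefined")
  expect_true(is.na(rep$auc))
})

test_that("MCC equals 1 only for diagonal confusion matrices", {
  e <- asNamespace("her2lite")
  set.seed(13)
  for (trial in 1:50) {
    K <- sample(2:4, 1)
    cm <- matrix(rpois(K * K, 3), K, K) + diag(2, K)
    m <- e$mcc_from_confusion(cm)
    if (sum(cm) - sum(diag(cm)) > 0) expect_lt(m, 1)
    else expect_equal(m, 1)
  }
})

test_that("reports serialize to JSON and CSV", {
  d <- data_for_confusion(matrix(c(8, 2, 1, 9), 2, 2))
  rep <- confusion_and_summary(d$y, d$prob)
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  write_metrics(rep, jp); write_metrics(rep, cp)
  back <- jsonlite::read_json(jp)
  expect_equal(back$accuracy, rep$accuracy, tolerance = 1e-9)
  expect_identical(nrow(read.csv(cp)), 3L)
  expect_error(write_metrics(rep, tempfile(fileext = ".txt")), "json or")
})
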