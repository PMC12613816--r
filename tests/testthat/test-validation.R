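mkReport <- function(ids, hits, scores = NULL) {
  if (is.null(scores)) scores <- ifelse(hits, 1, -Inf)
  n <- length(ids)
  new("ScreenReport",
      results = data.frame(id = ids, hit = hits,
                           conformer = rep(NA_integer_, n),
                           nMatched = rep(0L, n), nValid = rep(0L, n),
                           rmsd = rep(NA_real_, n), score = scores,
                           stringsAsFactors = FALSE),
      settings = list(), modelLabel = "test")
}

test_that("confusion counts are exact on a hand-countable case", {
  rep <- mkReport(c("a1", "a2", "d1", "d2"),
                  c(TRUE, FALSE, TRUE, FALSE))
  labels <- c(a1 = "active", a2 = "active", d1 = "decoy", d2 = "decoy")
  ev <- evaluateScreen(rep, labels)
  expect_equal(ev[c("TP", "FN", "FP", "TN")],
               list(TP = 1L, FN = 1L, FP = 1L, TN = 1L))
  expect_equal(ev$sensitivity, 0.5)
  expect_equal(ev$specificity, 0.5)
  expect_error(evaluateScreen(rep, labels[1:2]), "unlabeled")
})

test_that("empty reports give zero counts and undefined rates", {
  rep <- mkReport(character(0), logical(0))
  ev <- evaluateScreen(rep, character(0))
  expect_equal(unlist(ev[c("TP", "FP", "TN", "FN")]),
               c(TP = 0L, FP = 0L, TN = 0L, FN = 0L))
  expect_true(is.na(ev$sensitivity))
  expect_true(is.na(ev$specificity))
})

test_that("confusion totals are conserved", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    ids <- sprintf("m%02d", 1:n)
    rep <- mkReport(ids, sample(c(TRUE, FALSE), n, replace = TRUE))
    labels <- stats::setNames(
      sample(c("active", "inactive", "decoy"), n, replace = TRUE), ids)
    ev <- evaluateScreen(rep, labels)
    expect_equal(ev$TP + ev$FP + ev$TN + ev$FN, n)
  }
})

test_that("ROC handles perfect separation and degenerate inputs", {
  scores <- c(5, 4, 3, 2, 1)
  labels <- c("active", "active", "decoy", "decoy", "decoy")
  roc <- rocCurve(scores, labels)
  expect_equal(roc$auc, 1.0)
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
  expect_error(rocCurve(scores, rep("active", 5)), "at least one")
})

test_that("AUC equals the Mann-Whitney pair-counting oracle", {
  set.seed(19)
  for (i in 1:200) {
    n <- sample(8:40, 1)
    scores <- sample(round(rnorm(n), 1))  # ties likely
    labels <- sample(c("active", "decoy"), n, replace = TRUE,
                     prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2L) next
    expect_equal(rocCurve(scores, labels)$auc, oracleAUC(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC and survives monotone score transforms", {
  skip_if_not_installed("pROC")
  set.seed(29)
  scores <- rnorm(300) + rep(c(1, 0), c(100, 200))
  labels <- rep(c("active", "decoy"), c(100, 200))
  auc <- rocCurve(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels == "active", predictor = scores, quiet = TRUE,
    direction = "<")))
  expect_equal(auc, ref, tolerance = 1e-12)
  expect_equal(rocCurve(exp(scores), labels)$auc, auc, tolerance = 1e-12)
  expect_equal(rocCurve(rank(scores), labels)$auc, auc, tolerance = 1e-12)
})

test_that("enrichment factors follow the top-fraction definition", {
  scores <- 10:1
  labels <- c(rep("active", 3), rep("decoy", 7))  # all actives on top
  roc <- rocCurve(scores, labels, efFractions = c(0.1, 0.3, 1))
  expect_equal(unname(roc$ef[["EF10"]]), 1 / 0.3)       # top-1 all active
  expect_equal(unname(roc$ef[["EF30"]]), 1 / 0.3)       # top-3 all active
  expect_equal(unname(roc$ef[["EF100"]]), 1)            # whole library
})

test_that("decoy picking honours tolerances, ratios and shortfalls", {
  actives <- data.frame(id = c("a1", "a2"), mw = c(300, 400),
                        apolar_frac = 0.4, hba = 2, hbd = 1, rotb = 4,
                        charge = 1)
  # exact property copies: any requested count honoured
  pool <- do.call(rbind, lapply(1:20, function(i) {
    p <- actives[(i %% 2) + 1, ]
    p$id <- sprintf("p%02d", i)
    p
  }))
  res <- pickDecoys(actives, pool, ratio = 5)
  expect_equal(res$selected, 10L)
  expect_equal(res$shortfall, 0L)
  expect_false(any(duplicated(res$decoys$id)))
  # zero tolerances and a disjoint pool: full shortfall, no padding
  off <- pool; off$mw <- off$mw + 1000
  tol0 <- lapply(decoyTolerances(), function(x) 0)
  res0 <- pickDecoys(actives, off, tolerances = tol0, ratio = 5)
  expect_equal(res0$selected, 0L)
  expect_equal(res0$shortfall, 10L)
  # known in-tolerance subset: selection is exactly bounded by it
  mixed <- pool
  mixed$mw <- mixed$mw + rep(c(0, 1000), 10)
  inTol <- mixed$id[abs(mixed$mw - 300) <= 25 | abs(mixed$mw - 400) <= 25]
  resM <- pickDecoys(actives, mixed, ratio = 20)
  expect_true(all(resM$decoys$id %in% inTol))
  expect_equal(resM$selected, min(length(inTol), 40L))
  # post-hoc property-match assertion
  for (j in seq_len(nrow(resM$decoys))) {
    act <- actives[actives$id == resM$matchedActive[j], ]
    expect_lte(abs(resM$decoys$mw[j] - act$mw), 25)
  }
  # deterministic under a fixed seed
  expect_identical(pickDecoys(actives, pool, ratio = 3, seed = 4)$decoys$id,
                   pickDecoys(actives, pool, ratio = 3, seed = 4)$decoys$id)
})
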