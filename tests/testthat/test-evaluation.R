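# Metric battery: ROC/AUC, operating points, PRC, bootstrap, confusion,
# SERS utility formulas.

# Pair-counting concordance oracle: ties count one half.
pair_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

test_that("trapezoidal AUC equals pair-counting concordance", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)

  set.seed(3)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    sc <- sample(round(runif(n), 1))          # coarse grid forces ties
    lb <- c(0, 1, rbinom(n - 2, 1, 0.4))
    expect_equal(roc_auc(sc, lb)$auc, pair_auc(sc, lb))
  }
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms and the
           curve is monotone", {
  set.seed(4)
  sc <- runif(40); lb <- rbinom(40, 1, 0.5); lb[1:2] <- c(0, 1)
  a <- roc_auc(sc, lb)
  expect_equal(roc_auc(qlogis(pmin(pmax(sc, 1e-6), 1 - 1e-6)), lb)$auc, a$auc)
  expect_equal(roc_auc(sc * 100 - 3, lb)$auc, a$auc)
  expect_true(all(diff(a$fpr) >= 0))
  expect_true(all(diff(a$tpr) >= 0))
  expect_gte(a$auc, 0); expect_lte(a$auc, 1)
})

test_that("operating points agree with exhaustive threshold search", {
  brute <- function(scores, labels, starget, ttarget) {
    cand <- c(sort(unique(scores)), Inf)
    sens <- sapply(cand, function(t)
      sum(scores > t & labels == 1) / sum(labels == 1))
    spec <- sapply(cand, function(t)
      sum(scores <= t & labels == 0) / sum(labels == 0))
    list(sas = max(c(0, sens[spec >= starget])),
         ssa = max(c(0, spec[sens >= ttarget])))
  }
  s <- c(0.2, 0.3, 0.6, 0.9); l <- c(0, 0, 1, 1)
  op <- operating_points(s, l)
  b <- brute(s, l, 0.99, 0.99)
  expect_equal(op$sens_at_spec, b$sas)
  expect_equal(op$spec_at_sens, b$ssa)
  expect_equal(op$optimal$sensitivity, 1)
  expect_equal(op$optimal$specificity, 1)
  expect_equal(op$optimal$accuracy, 1)

  set.seed(9)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    sc <- round(runif(n), 1)
    lb <- c(0, 1, rbinom(n - 2, 1, 0.5))
    op <- operating_points(sc, lb, 0.8, 0.8)
    b <- brute(sc, lb, 0.8, 0.8)
    expect_equal(op$sens_at_spec, b$sas)
    expect_equal(op$spec_at_sens, b$ssa)
  }

  # under the null, sensitivity at 99 % specificity collapses toward zero
  set.seed(10)
  sc <- runif(4000); lb <- rbinom(4000, 1, 0.5)
  expect_lt(operating_points(sc, lb)$sens_at_spec, 0.05)
})

test_that("precision-recall metrics match hand enumeration", {
  expect_equal(pr_metrics(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auprc, 1)

  # constant scores: a single point at precision = prevalence, recall = 1
  pm <- pr_metrics(rep(0.4, 10), c(rep(1, 3), rep(0, 7)))
  expect_equal(pm$auprc, 0.3)

  # 4-point toy curve, hand-enumerated: scores sorted 0.9(+) 0.7(-) 0.4(+)
  # 0.2(-) -> precision 1, 1/2, 2/3, 2/4 at recall 1/2, 1/2, 1, 1
  pm <- pr_metrics(c(0.2, 0.4, 0.7, 0.9), c(0, 1, 0, 1))
  expect_equal(pm$curve$precision, c(1, 1 / 2, 2 / 3, 2 / 4))
  expect_equal(pm$curve$recall, c(1 / 2, 1 / 2, 1, 1))
  expect_equal(pm$auprc, 0.5 * 1 + 0 + 0.5 * (2 / 3) + 0)
  expect_equal(pm$f1, max(2 * c(1, 1/2, 2/3, 1/2) * c(1/2, 1/2, 1, 1) /
                            (c(1, 1/2, 2/3, 1/2) + c(1/2, 1/2, 1, 1))))
  expect_error(pr_metrics(c(0.1, 0.2), c(0, 0)), "no positive")
})

test_that("stratified bootstrap CIs are deterministic, consistent and
           shrink with n", {
  # zero-variance metric: degenerate interval
  ci <- bootstrap_ci(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), "auc",
                     n_boot = 200L, seed = 1L)
  expect_equal(ci, c(1, 1))

  set.seed(5)
  s <- c(rnorm(100, 0), rnorm(100, 1)); l <- rep(c(0, 1), each = 100)
  ci1 <- bootstrap_ci(s, l, "auc", n_boot = 300L, seed = 7L)
  ci2 <- bootstrap_ci(s, l, "auc", n_boot = 300L, seed = 7L)
  expect_identical(ci1, ci2)
  a <- roc_auc(s, l)$auc
  expect_lte(ci1[1], a); expect_gte(ci1[2], a)

  ci_small <- bootstrap_ci(c(rnorm(25, 0), rnorm(25, 1)),
                           rep(c(0, 1), each = 25), "auc",
                           n_boot = 300L, seed = 8L)
  expect_gt(diff(ci_small), diff(ci1))

  expect_error(bootstrap_ci(s, l, "auc", n_boot = 50L), "n_boot")
})

test_that("confusion matrices tally decisions against truth", {
  mk <- function(id, cls, status = "ok") {
    structure(list(sample_id = id, presence_score = 0.5,
                   positive = cls != "non-cancer", too_scores = NULL,
                   predicted_class = cls, status = status),
              class = "decision_result")
  }
  dec <- list(mk("a", "lung"), mk("b", "lung"), mk("c", "non-cancer"),
              mk("d", "breast"), mk("e", "non-cancer"), mk("f", "stomach"),
              mk("g", "liver"), mk("h", "non-cancer"), mk("i", "lung"),
              mk("j", "pancreatic"))
  truth <- c(a = "lung", b = "lung", c = "HC", d = "breast", e = "lung",
             f = "stomach", g = "liver", h = "HC", i = "colorectal",
             j = "pancreatic")
  M <- confusion_matrix(dec, truth)
  expect_equal(sum(M), 10L)
  expect_equal(M["lung", "lung"], 2L)
  expect_equal(M["lung", "non-cancer"], 1L)
  expect_equal(M["colorectal", "lung"], 1L)
  expect_equal(M["HC", "non-cancer"], 2L)
  expect_equal(unname(rowSums(M)[c("lung", "HC")]), c(3L, 2L))

  expect_equal(sum(confusion_matrix(list(), truth)), 0L)
  expect_error(confusion_matrix(list(mk("zz", "lung")), truth), "unknown")
})

test_that("SERS utility formulas evaluate exactly", {
  expect_equal(enhancement_factor(10, 5, 10, 5), 1)
  expect_equal(enhancement_factor(1000, 1, 10, 100), 1e4)
  expect_equal(enhancement_factor(3 * 1000, 1, 3 * 10, 100), 1e4)
  expect_error(enhancement_factor(0, 1, 1, 1), "positive")

  expect_equal(coefficient_of_variation(rep(5, 10)), 0)
  expect_equal(coefficient_of_variation(c(8, 10, 12)), 20)
  expect_error(coefficient_of_variation(c(-2, 2)), "positive")
  expect_error(coefficient_of_variation(3), "two values")
})
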