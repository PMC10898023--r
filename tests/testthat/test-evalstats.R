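test_that("largest-remainder splitting apportions exactly", {
  sp <- split_dataset(10, c(5, 1, 4), seed = 1)
  expect_equal(lengths(sp), c(training = 5, validation = 1, test = 4))
  expect_setequal(unlist(sp), 1:10)
  # conservation and disjointness across arbitrary n
  for (n in c(3, 7, 11, 100, 1048)) {
    sp <- split_dataset(n, c(5, 1, 4), seed = n)
    expect_equal(sum(lengths(sp)), n)
    expect_equal(anyDuplicated(unlist(sp)), 0)
  }
  expect_error(split_dataset(2, c(5, 1, 4)), "at least as many")
})

test_that("stratified splits follow the apportionment oracle per class", {
  labs <- rep(bmd_classes, times = c(621, 296, 131))
  sp <- split_dataset(labs, c(5, 1, 4), stratify = TRUE, seed = 7)
  # oracle: largest-remainder apportionment enumerated per class
  apportion <- function(m, ratios) {
    q <- m * ratios / sum(ratios)
    base <- floor(q)
    left <- m - sum(base)
    if (left > 0) {
      extra <- order(q - base, decreasing = TRUE)[seq_len(left)]
      base[extra] <- base[extra] + 1
    }
    base
  }
  for (cl in bmd_classes) {
    expected <- apportion(sum(labs == cl), c(5, 1, 4))
    got <- vapply(sp, function(ii) sum(labs[ii] == cl), 1.0)
    expect_equal(unname(got), expected, label = cl)
  }
  # per-part class proportions within 1 item of the global proportion
  for (j in seq_along(sp)) {
    for (cl in bmd_classes) {
      exp_n <- length(sp[[j]]) * mean(labs == cl)
      expect_lt(abs(sum(labs[sp[[j]]] == cl) - exp_n), 1 + 1e-9)
    }
  }
  # same seed reproduces the split exactly
  expect_identical(sp, split_dataset(labs, c(5, 1, 4), stratify = TRUE,
                                     seed = 7))
  expect_warning(split_dataset(c("a", "a", "b", rep("a", 5)), c(5, 1, 4),
                               stratify = TRUE, seed = 1), "fewer members")
})

test_that("AUC equals the exhaustive concordant-pair count", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.3, 8), rep(c(0, 1), 4)), 0.5)
  set.seed(42)
  for (r in 1:20) {
    n <- sample(6:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n), 1)  # coarse scores force ties
    pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
    oracle <- mean((s[pairs$i] > s[pairs$j]) + 0.5 * (s[pairs$i] == s[pairs$j]))
    expect_equal(roc_auc(s, y), oracle)
    expect_equal(roc_auc(s, y) + roc_auc(-s, y), 1)  # complement identity
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC agrees with pROC as an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  y <- rbinom(80, 1, 0.4)
  s <- rnorm(80) + y
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
  ci <- auc_ci(s, y)
  pci <- as.numeric(pROC::ci.auc(pROC::roc(y, s, quiet = TRUE),
                                 method = "delong"))
  expect_equal(c(ci$lower, ci$auc, ci$upper), pci, tolerance = 1e-9)
})

test_that("DeLong interval brackets the AUC and narrows with n", {
  set.seed(6)
  mk <- function(n) {
    y <- rep(c(0, 1), each = n / 2)
    list(y = y, s = rnorm(n) + 1.19 * y)
  }
  d1 <- mk(60); d2 <- mk(600)
  c1 <- auc_ci(d1$s, d1$y); c2 <- auc_ci(d2$s, d2$y)
  expect_true(c1$lower <= c1$auc && c1$auc <= c1$upper)
  expect_lt(c2$upper - c2$lower, c1$upper - c1$lower)
})

test_that("DeLong variance matches the naive structural-components loop", {
  set.seed(7)
  for (r in 1:10) {
    n <- sample(10:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n) + 0.8 * y, 1)
    nv <- naive_delong(s, y)
    cp <- delong_components(s, y)
    expect_equal(cp$auc, nv$auc, tolerance = 1e-12)
    expect_equal(stats::var(cp$v10) / cp$m + stats::var(cp$v01) / cp$n,
                 nv$var, tolerance = 1e-12)
  }
})

test_that("the paired DeLong test behaves as a test should", {
  set.seed(8)
  y <- rbinom(100, 1, 0.5)
  x <- rnorm(100) + y
  s1 <- x + rnorm(100, 0, 0.3)
  s2 <- x + rnorm(100, 0, 0.3)
  # identical scores: Z = 0, P = 1
  d0 <- delong_test(s1, s1, y)
  expect_equal(d0$z, 0)
  expect_equal(d0$p.value, 1)
  # antisymmetry
  d12 <- delong_test(s1, s2, y)
  d21 <- delong_test(s2, s1, y)
  expect_equal(d12$z, -d21$z)
  expect_equal(d12$p.value, d21$p.value)
  expect_equal(d12$auc1, roc_auc(s1, y))
  # degenerate: zero variance with unequal AUCs is flagged
  yy <- c(0, 0, 1, 1)
  expect_warning(dd <- delong_test(c(1, 2, 3, 4), c(4, 3, 2, 1), yy),
                 "degenerate")
  expect_true(dd$degenerate)
})

test_that("the paired DeLong test agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(9)
  y <- rbinom(120, 1, 0.5)
  x <- rnorm(120) + 1.2 * y
  s1 <- x + rnorm(120, 0, 0.4)
  s2 <- 0.8 * x + rnorm(120, 0, 0.5)
  d <- delong_test(s1, s2, y)
  p <- pROC::roc.test(pROC::roc(y, s1, quiet = TRUE),
                      pROC::roc(y, s2, quiet = TRUE), method = "delong")
  expect_equal(abs(d$z), abs(as.numeric(p$statistic)), tolerance = 1e-9)
  expect_equal(d$p.value, as.numeric(p$p.value), tolerance = 1e-9)
})

test_that("confusion metrics reproduce direct ratios", {
  p <- c("a", "a", "b", "b")
  t <- c("a", "a", "b", "b")
  expect_equal(unname(confusion_metrics(p, t, "a")), rep(1, 5))
  # all-negative predictions
  t2 <- c("a", "a", "b", "b", "b")
  p2 <- rep("b", 5)
  m <- confusion_metrics(p2, t2, "a")
  expect_equal(unname(m["se"]), 0)
  expect_equal(unname(m["sp"]), 1)
  expect_true(is.na(m["ppv"]))  # zero predicted positives: undefined, not 0
  expect_equal(unname(m["npv"]), 3 / 5)
  # stated counts TP=48, FN=3, FP=17, TN=350
  truth <- rep(c("pos", "pos", "neg", "neg"), c(48, 3, 17, 350))
  pred <- rep(c("pos", "neg", "pos", "neg"), c(48, 3, 17, 350))
  m2 <- confusion_metrics(pred, truth, "pos")
  expect_equal(unname(m2["se"]), 48 / 51)
  expect_equal(unname(m2["sp"]), 350 / 367)
  expect_equal(unname(m2["ppv"]), 48 / 65)
  expect_equal(unname(m2["npv"]), 350 / 353)
  expect_equal(unname(m2["ac"]), 398 / 418)
})

test_that("chi-square homogeneity is uncorrected Pearson with margin checks", {
  tab <- rbind(c(10, 20), c(30, 40))
  r <- chi_square_homogeneity(tab)
  expect_s3_class(r, "htest")
  # invariant to transpose and row/column permutation
  expect_equal(r$statistic, chi_square_homogeneity(t(tab))$statistic)
  expect_equal(r$statistic,
               chi_square_homogeneity(tab[2:1, 2:1])$statistic)
  # proportional rows give exactly zero
  expect_equal(unname(chi_square_homogeneity(rbind(c(10, 20, 30),
                                                   c(20, 40, 60)))$statistic),
               0)
  expect_error(chi_square_homogeneity(rbind(c(0, 0), c(3, 4))), "margin")
  expect_error(chi_square_homogeneity(rbind(c(-1, 2), c(3, 4))),
               "non-negative")
})

test_that("summary t test matches a moment-matched raw-data t test", {
  g1 <- summary_group(20, 10.0, 2.0)
  g2 <- summary_group(25, 11.5, 2.5)
  x1 <- exact_sample(20, 10.0, 2.0, seed = 1)
  x2 <- exact_sample(25, 11.5, 2.5, seed = 2)
  for (m in c("welch", "pooled")) {
    ours <- t_from_summary(g1, g2, method = m)
    ref <- stats::t.test(x2, x1, var.equal = (m == "pooled"))
    expect_equal(unname(ours$statistic), unname(ref$statistic),
                 tolerance = 1e-10)
    expect_equal(unname(ours$parameter), unname(ref$parameter),
                 tolerance = 1e-10)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  }
  # equal means give t = 0 under either method
  ga <- summary_group(10, 5, 1)
  gb <- summary_group(12, 5, 3)
  expect_equal(unname(t_from_summary(ga, gb, "welch")$statistic), 0)
  expect_equal(unname(t_from_summary(ga, gb, "pooled")$statistic), 0)
  expect_error(t_from_summary(summary_group(1, 0, 1), gb), "n >= 2")
})

test_that("summary ANOVA matches moment-matched raw-data ANOVA", {
  gs <- list(summary_group(12, 10, 2), summary_group(15, 12, 3),
             summary_group(9, 9, 1.5))
  ours <- anova_f_from_summary(gs)
  xs <- list(exact_sample(12, 10, 2, 3), exact_sample(15, 12, 3, 4),
             exact_sample(9, 9, 1.5, 5))
  dat <- data.frame(y = unlist(xs),
                    g = factor(rep(seq_along(xs), times = lengths(xs))))
  ref <- stats::oneway.test(y ~ g, dat, var.equal = TRUE)
  expect_equal(unname(ours$statistic), unname(ref$statistic),
               tolerance = 1e-10)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  # identical means: F = 0
  expect_equal(unname(anova_f_from_summary(
    list(summary_group(5, 7, 1), summary_group(8, 7, 2)))$statistic), 0)
  # two groups: F equals the square of the pooled t
  g1 <- summary_group(10, 4, 1.2)
  g2 <- summary_group(14, 5, 1.4)
  expect_equal(unname(anova_f_from_summary(list(g1, g2))$statistic),
               unname(t_from_summary(g1, g2, "pooled")$statistic)^2,
               tolerance = 1e-12)
  expect_error(anova_f_from_summary(list(summary_group(1, 1, 0),
                                         summary_group(1, 2, 0))),
               "degrees of freedom")
})

test_that("classification reports are well-formed", {
  set.seed(10)
  n <- 90
  labs <- sample(bmd_classes, n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  probs <- matrix(runif(3 * n), n, 3, dimnames = list(NULL, bmd_classes))
  probs <- probs / rowSums(probs)
  rep_ <- classification_report(probs, labs, dataset = "test")
  expect_equal(nrow(rep_), 3)
  num <- as.matrix(rep_[, c("auc", "ci_low", "ci_high", "se", "sp", "ppv",
                            "npv", "ac")])
  expect_true(all(num >= 0 & num <= 1, na.rm = TRUE))
  expect_true(all(rep_$ci_low <= rep_$auc & rep_$auc <= rep_$ci_high,
                  na.rm = TRUE))
  # perfectly separating scores give AUC 1 per class
  oh <- matrix(0, n, 3, dimnames = list(NULL, bmd_classes))
  oh[cbind(seq_len(n), match(labs, bmd_classes))] <- 1
  perfect <- classification_report(oh, labs)
  expect_equal(perfect$auc, rep(1, 3))
  # a class absent from the data is flagged
  flagged <- classification_report(probs[labs != "osteoporosis", ],
                                   labs[labs != "osteoporosis"])
  expect_true(flagged$flagged[flagged$class == "osteoporosis"])
})
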