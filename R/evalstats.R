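#' Ratio-based dataset splitting with largest-remainder apportionment
#'
#' Splits `n` items (optionally stratified by a label vector) into parts
#' sized by largest-remainder apportionment of the given ratios, after a
#' seeded shuffle. For divisible `n` the apportionment is exact (n = 10 at
#' 5:1:4 gives 5/1/4); ties in the fractional remainders are broken in part
#' order.
#'
#' @param x either a single integer (the number of items) or a vector of
#'   per-item labels.
#' @param ratios positive part ratios, default `c(5, 1, 4)`
#'   (training : validation : test).
#' @param stratify if `TRUE` and `x` is a label vector, apportion within
#'   each label so per-part class proportions track the global ones.
#' @param seed integer seed for the shuffle.
#' @param part_names names of the returned parts.
#' @return named list of disjoint, exhaustive index vectors.
#' @export
split_dataset <- function(x, ratios = c(5, 1, 4), stratify = FALSE,
                          seed = 1L,
                          part_names = c("training", "validation", "test")) {
  if (any(ratios <= 0)) stop("ratios must be positive")
  k <- length(ratios)
  if (length(part_names) != k) stop("part_names must match ratios")
  n <- if (length(x) == 1L && is.numeric(x)) as.integer(x) else length(x)
  if (n < k) stop("need at least as many items as parts")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  apportion <- function(m) {
    q <- m * ratios / sum(ratios)
    base <- floor(q)
    left <- m - sum(base)
    if (left > 0) {
      extra <- order(q - base, decreasing = TRUE)[seq_len(left)]
      base[extra] <- base[extra] + 1
    }
    as.integer(base)
  }
  assign_parts <- function(idx) {
    sizes <- apportion(length(idx))
    idx <- sample(idx)
    split(idx, rep(seq_len(k), times = sizes))
  }
  if (stratify && length(x) > 1L) {
    labs <- as.character(x)
    parts <- rep(list(integer()), k)
    for (lv in unique(labs)) {
      ii <- which(labs == lv)
      if (length(ii) < k) {
        warning("class '", lv, "' has fewer members (", length(ii),
                ") than parts; its items fill the parts in ratio order")
      }
      pp <- assign_parts(ii)
      for (j in seq_along(pp)) {
        jj <- as.integer(names(pp)[j])
        parts[[jj]] <- c(parts[[jj]], pp[[j]])
      }
    }
    parts <- lapply(parts, sort)
  } else {
    pp <- assign_parts(seq_len(n))
    parts <- rep(list(integer()), k)
    for (j in seq_along(pp)) parts[[as.integer(names(pp)[j])]] <- sort(pp[[j]])
  }
  names(parts) <- part_names
  parts
}

as_binary_labels <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels) && all(labels %in% c(0, 1))) {
    return(as.integer(labels))
  }
  if (is.null(positive)) {
    stop("labels must be logical/0-1, or supply `positive`")
  }
  as.integer(as.character(labels) == positive)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random positive outscores a random negative, with
#' ties counted one half, computed from midranks.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels binary labels (logical, 0/1, or anything with `positive`).
#' @param positive the positive-class value when `labels` is categorical.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  y <- as_binary_labels(labels, positive)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  m <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (m == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1L]) - m * (m + 1) / 2) / (m * n0)
}

# DeLong structural components via midranks
delong_components <- function(scores, y) {
  pos <- y == 1L
  m <- sum(pos)
  n0 <- sum(!pos)
  r_all <- rank(scores)
  v10 <- (r_all[pos] - rank(scores[pos])) / n0
  v01 <- 1 - (r_all[!pos] - rank(scores[!pos])) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n0)
}

#' DeLong confidence interval for an AUC
#'
#' Normal-approximation interval using the DeLong structural-components
#' variance estimate, clipped to `[0, 1]`.
#'
#' @inheritParams roc_auc
#' @param level confidence level.
#' @return list (class `oppscreen_auc_ci`) with `auc`, `lower`, `upper`,
#'   `se`, `level`.
#' @export
auc_ci <- function(scores, labels, level = 0.95, positive = NULL) {
  y <- as_binary_labels(labels, positive)
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L) {
    stop("both classes must be present")
  }
  cp <- delong_components(scores, y)
  v <- stats::var(cp$v10) / cp$m + stats::var(cp$v01) / cp$n
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(auc = cp$auc, lower = max(0, cp$auc - z * se),
                 upper = min(1, cp$auc + z * se), se = se, level = level),
            class = "oppscreen_auc_ci")
}

#' @export
print.oppscreen_auc_ci <- function(x, ...) {
  cat(sprintf("AUC %.3f (%d%% CI %.3f-%.3f)\n", x$auc, round(100 * x$level),
              x$lower, x$upper))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two models scoring the same items, using the paired
#' structural-components estimate of `var(AUC1 - AUC2)` and a two-sided
#' normal reference for `Z = (AUC1 - AUC2) / sqrt(var)`.
#'
#' @param scores1,scores2 per-item scores from the two models.
#' @inheritParams roc_auc
#' @return list (class `oppscreen_delong`) with `auc1`, `auc2`, `z`,
#'   `p.value`, `var_diff`, `degenerate`.
#' @export
delong_test <- function(scores1, scores2, labels, positive = NULL) {
  y <- as_binary_labels(labels, positive)
  if (length(scores1) != length(y) || length(scores2) != length(y)) {
    stop("both models must score the same items")
  }
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L) {
    stop("both classes must be present")
  }
  c1 <- delong_components(scores1, y)
  c2 <- delong_components(scores2, y)
  s10 <- stats::cov(cbind(c1$v10, c2$v10))
  s01 <- stats::cov(cbind(c1$v01, c2$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / c1$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / c1$n
  d <- c1$auc - c2$auc
  degenerate <- FALSE
  if (!is.finite(v)) {
    # a single positive or negative leaves the component variance undefined
    degenerate <- TRUE
    z <- NA_real_; p <- NA_real_
    warning("DeLong variance undefined (a class has a single member); ",
            "result flagged degenerate")
  } else if (v <= .Machine$double.eps) {
    if (abs(d) <= .Machine$double.eps^0.5) {
      z <- 0; p <- 1
    } else {
      degenerate <- TRUE
      z <- sign(d) * Inf; p <- 0
      warning("zero DeLong variance with unequal AUCs; result flagged ",
              "degenerate")
    }
  } else {
    z <- d / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc1 = c1$auc, auc2 = c2$auc, z = z, p.value = p,
                 var_diff = v, degenerate = degenerate),
            class = "oppscreen_delong")
}

#' @export
print.oppscreen_delong <- function(x, ...) {
  cat(sprintf("DeLong paired AUC comparison: AUC1 %.3f vs AUC2 %.3f\n",
              x$auc1, x$auc2))
  cat(sprintf("  Z = %.3f, two-sided P = %.4g%s\n", x$z, x$p.value,
              if (x$degenerate) " (degenerate: zero variance)" else ""))
  invisible(x)
}

#' One-vs-rest confusion-matrix metrics
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' accuracy for one positive class against the rest. Ratios with a zero
#' denominator are reported as `NA`, never silently as 0.
#'
#' @param predicted,truth label vectors of equal length.
#' @param positive the positive class.
#' @return named numeric vector `se`, `sp`, `ppv`, `npv`, `ac`.
#' @export
confusion_metrics <- function(predicted, truth, positive) {
  if (length(predicted) != length(truth) || length(truth) == 0L) {
    stop("predicted and truth must be non-empty and of equal length")
  }
  if (!positive %in% truth) stop("positive class absent from truth")
  p <- predicted == positive
  t <- truth == positive
  tp <- sum(p & t); fn <- sum(!p & t); fp <- sum(p & !t); tn <- sum(!p & !t)
  rat <- function(a, b) if (b == 0) NA_real_ else a / b
  c(se = rat(tp, tp + fn), sp = rat(tn, tn + fp), ppv = rat(tp, tp + fp),
    npv = rat(tn, tn + fn), ac = (tp + tn) / length(truth))
}

#' Pearson chi-square test of homogeneity
#'
#' Uncorrected Pearson chi-square on a contingency table of counts, with
#' expected counts from the row/column margins and
#' `df = (r - 1)(c - 1)`. No continuity correction is applied (the printed
#' cohort statistics only reproduce uncorrected).
#'
#' @param tab matrix of non-negative counts.
#' @return an object of class `htest`.
#' @export
chi_square_homogeneity <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(!is.finite(tab))) stop("counts must be finite and non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero row or column margin")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0)) stop("all expected counts must be positive")
  suppressWarnings(stats::chisq.test(tab, correct = FALSE))
}

#' Summary statistics of one group
#'
#' @param n group size (>= 1).
#' @param mean,sd sample mean and standard deviation.
#' @return list of class `summary_group`.
#' @export
summary_group <- function(n, mean, sd) {
  if (n < 1 || sd < 0 || !is.finite(mean)) stop("invalid summary statistics")
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "summary_group")
}

#' Two-sample t test from group summaries
#'
#' Computes `t = (mean2 - mean1) / se` from summary statistics alone,
#' either with the Welch standard error and Welch-Satterthwaite degrees of
#' freedom, or with the classical pooled variance. The method is an
#' explicit argument because published tables mix both conventions.
#'
#' @param g1,g2 [summary_group()] objects (n >= 2 each).
#' @param method `"welch"` or `"pooled"`.
#' @return an object of class `htest` with `statistic`, `parameter` (df)
#'   and `p.value`.
#' @export
t_from_summary <- function(g1, g2, method = c("welch", "pooled")) {
  method <- match.arg(method)
  stopifnot(inherits(g1, "summary_group"), inherits(g2, "summary_group"))
  if (g1$n < 2 || g2$n < 2) stop("need n >= 2 in each group")
  if (method == "welch") {
    se2 <- g1$sd^2 / g1$n + g2$sd^2 / g2$n
    tt <- (g2$mean - g1$mean) / sqrt(se2)
    df <- se2^2 / ((g1$sd^2 / g1$n)^2 / (g1$n - 1) +
                     (g2$sd^2 / g2$n)^2 / (g2$n - 1))
  } else {
    sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / (g1$n + g2$n - 2)
    tt <- (g2$mean - g1$mean) / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
    df <- g1$n + g2$n - 2
  }
  structure(list(statistic = c(t = tt), parameter = c(df = df),
                 p.value = 2 * stats::pt(-abs(tt), df),
                 estimate = c(`mean difference` = g2$mean - g1$mean),
                 method = paste0(if (method == "welch") "Welch" else "Pooled",
                                 " two-sample t test from summary statistics"),
                 data.name = "group summaries"),
            class = "htest")
}

#' One-way ANOVA F test from group summaries
#'
#' Between- and within-group mean squares are reconstructed from each
#' group's size, mean and SD; `F` is referred to an
#' `(k - 1, N - k)` F distribution.
#'
#' @param groups list of [summary_group()] objects (>= 2 groups).
#' @return an object of class `htest`.
#' @export
anova_f_from_summary <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  stopifnot(all(vapply(groups, inherits, TRUE, "summary_group")))
  ns <- vapply(groups, `[[`, 1, "n")
  ms <- vapply(groups, `[[`, 1, "mean")
  ss <- vapply(groups, `[[`, 1, "sd")
  N <- sum(ns)
  k <- length(groups)
  if (N - k < 1) stop("no within-group degrees of freedom (all n = 1)")
  grand <- sum(ns * ms) / N
  ssb <- sum(ns * (ms - grand)^2)
  ssw <- sum((ns - 1) * ss^2)
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  structure(list(statistic = c(F = f), parameter = c(df1 = k - 1, df2 = N - k),
                 p.value = stats::pf(f, k - 1, N - k, lower.tail = FALSE),
                 method = "One-way ANOVA from summary statistics",
                 data.name = "group summaries"),
            class = "htest")
}

#' Per-class classification report
#'
#' One-vs-rest AUC with DeLong 95\% CI per class, plus
#' sensitivity/specificity/PPV/NPV/accuracy at the arg-max prediction.
#'
#' @param probs N x 3 probability matrix with columns named by
#'   [bmd_classes].
#' @param labels true labels.
#' @param dataset optional dataset tag recorded in the output.
#' @return data frame (class `oppscreen_report`), one row per class.
#' @export
classification_report <- function(probs, labels, dataset = NA_character_) {
  labels <- as.character(labels)
  if (is.null(colnames(probs))) colnames(probs) <- bmd_classes
  pred <- colnames(probs)[max.col(probs)]
  rows <- lapply(bmd_classes, function(cl) {
    y <- labels == cl
    if (!any(y)) {
      return(data.frame(dataset = dataset, class = cl, n = 0L, auc = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, se = NA_real_,
                        sp = NA_real_, ppv = NA_real_, npv = NA_real_,
                        ac = NA_real_, flagged = TRUE))
    }
    cm <- confusion_metrics(pred, labels, cl)
    if (all(y)) {
      # one-vs-rest AUC undefined without negatives: flag, keep the counts
      return(data.frame(dataset = dataset, class = cl, n = sum(y),
                        auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        se = cm[["se"]], sp = cm[["sp"]], ppv = cm[["ppv"]],
                        npv = cm[["npv"]], ac = cm[["ac"]], flagged = TRUE))
    }
    ci <- auc_ci(probs[, cl], labels, positive = cl)
    data.frame(dataset = dataset, class = cl, n = sum(y),
               auc = ci$auc, ci_low = ci$lower, ci_high = ci$upper,
               se = cm[["se"]], sp = cm[["sp"]], ppv = cm[["ppv"]],
               npv = cm[["npv"]], ac = cm[["ac"]], flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("oppscreen_report", "data.frame")
  out
}

#' Evaluate a trained classifier on a labeled dataset
#'
#' @param model a trained `oppscreen_classifier`.
#' @param data list with `images` and `labels`.
#' @param dataset optional dataset tag.
#' @return a [classification_report()] data frame.
#' @export
evaluate_model <- function(model, data, dataset = NA_character_) {
  probs <- predict(model, data$images, type = "prob")
  classification_report(probs, data$labels, dataset = dataset)
}
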