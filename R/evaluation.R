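# Blind-test / prospective-style evaluation: ROC AUC, PPV-by-threshold tables,
# Kaplan-Meier curves by risk group with a log-rank test, mean outcome-window
# ED visit counts per group, and shrunken-difference feature diagnostics.

#' ROC curve and AUC
#'
#' Sweeps every distinct score as a threshold and integrates the ROC curve by
#' the trapezoid rule, which equals the fraction of (case, control) pairs in
#' which the case outscores the control, with ties credited one half.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (both classes must be present).
#' @return A list with `auc` and `curve` (data.frame `threshold`, `fpr`, `tpr`).
#' @export
#' @examples
#' roc_auc(c(0.9, 0.1), c(1, 0))$auc
roc_auc <- function(scores, labels) {
  if (length(unique(labels)) < 2L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  keep <- !duplicated(s, fromLast = TRUE)  # last row of each tie block
  tpr <- c(0, cumsum(y == 1)[keep] / n_pos)
  fpr <- c(0, cumsum(y == 0)[keep] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc,
       curve = data.frame(threshold = c(Inf, s[keep]), fpr = fpr, tpr = tpr))
}

#' PPV by risk-index threshold
#'
#' For each threshold `t`, flags all patients with index at or above `t` and
#' reports how many were flagged, how many truly had the outcome, the PPV, and
#' the false-flag rate (1 - PPV). A threshold flagging nobody reports `NA`
#' rather than zero.
#'
#' @param indices Risk indices on the 0-100 scale.
#' @param labels Binary outcomes.
#' @param thresholds Thresholds to tabulate (default 30, 50, 70, 80).
#' @return A data.frame with columns `threshold`, `n_flagged`, `n_true`,
#'   `n_false`, `ppv`, `false_flag_rate` (`ppv` in percent).
#' @export
ppv_table <- function(indices, labels, thresholds = c(30, 50, 70, 80)) {
  if (any(thresholds < 0 | thresholds > 100))
    stop("thresholds must lie in [0, 100]", call. = FALSE)
  rows <- lapply(thresholds, function(t) {
    flagged <- indices >= t
    n_flagged <- sum(flagged)
    n_true <- sum(labels[flagged] == 1)
    data.frame(threshold = t,
               n_flagged = n_flagged,
               n_true = n_true,
               n_false = n_flagged - n_true,
               ppv = if (n_flagged > 0) 100 * n_true / n_flagged else NA_real_,
               false_flag_rate = if (n_flagged > 0)
                 100 * (n_flagged - n_true) / n_flagged else NA_real_)
  })
  do.call(rbind, rows)
}

#' Kaplan-Meier curves per risk group
#'
#' Product-limit estimator per group via [survival::survfit()], with
#' censoring at the horizon handled as right censoring. Empty groups are
#' omitted with a warning.
#'
#' @param time_to_event Days to event or censoring.
#' @param event_flags Binary event indicators.
#' @param group_labels Group label per patient.
#' @return Named list of data.frames (`day`, `survival`) per group.
#' @export
km_curve <- function(time_to_event, event_flags, group_labels) {
  grp <- factor(group_labels)
  empty <- setdiff(levels(grp), unique(as.character(grp)))
  if (length(empty))
    warning("omitting empty group(s): ", paste(empty, collapse = ", "),
            call. = FALSE)
  out <- list()
  for (g in levels(droplevels(grp))) {
    i <- grp == g
    sf <- survival::survfit(survival::Surv(time_to_event[i], event_flags[i]) ~ 1)
    out[[g]] <- data.frame(day = sf$time, survival = sf$surv)
  }
  out
}

#' k-group log-rank test
#'
#' Standard log-rank chi-square with k - 1 degrees of freedom, via
#' [survival::survdiff()].
#'
#' @inheritParams km_curve
#' @return A list with `statistic`, `df`, and `p_value`.
#' @export
logrank_test <- function(time_to_event, event_flags, group_labels) {
  grp <- factor(group_labels)
  grp <- droplevels(grp)
  if (nlevels(grp) < 2L)
    stop("log-rank test requires at least 2 non-empty groups", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time_to_event, event_flags) ~ grp)
  df <- nlevels(grp) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = pchisq(unname(sd$chisq), df, lower.tail = FALSE))
}

#' Mean outcome-window ED visit counts per risk group
#'
#' @param outcome_ed_counts Non-negative ED visit counts in the outcome window.
#' @param risk_groups Group label per patient; empty groups are omitted.
#' @return Named numeric vector of per-group means.
#' @export
mean_ed_by_group <- function(outcome_ed_counts, risk_groups) {
  if (any(outcome_ed_counts < 0))
    stop("counts must be non-negative", call. = FALSE)
  tapply(outcome_ed_counts, droplevels(factor(risk_groups)), mean)
}

#' Shrunken differences between class means and the overall mean
#'
#' Nearest-shrunken-centroid style diagnostic: for feature `j` and class `k`,
#' `d = (class mean - overall mean) / (m_k * (s_j + s0))` where `s_j` is the
#' pooled within-class standard deviation, `s0` the median of all `s_j`, and
#' `m_k = sqrt(1/n_k + 1/n)`; `|d|` is then soft-thresholded by `shrinkage`
#' toward zero, preserving sign.
#'
#' @param X Numeric matrix (patients x features) with column names.
#' @param class_labels Class label per patient (at least two classes).
#' @param shrinkage Non-negative soft-threshold amount (default 0: plain
#'   standardized differences, a diagnostic display).
#' @return Feature x class matrix of shrunken differences.
#' @export
shrunken_difference <- function(X, class_labels, shrinkage = 0) {
  if (shrinkage < 0) stop("shrinkage must be non-negative", call. = FALSE)
  cls <- droplevels(factor(class_labels))
  if (nlevels(cls) < 2L)
    stop("at least two classes required", call. = FALSE)
  n <- nrow(X)
  K <- nlevels(cls)
  nk <- table(cls)
  overall <- colMeans(X)
  centroids <- do.call(rbind, lapply(levels(cls), function(g)
    colMeans(X[cls == g, , drop = FALSE])))
  rownames(centroids) <- levels(cls)
  ## pooled within-class sd per feature
  ss <- matrix(0, 1, ncol(X))
  for (g in levels(cls)) {
    Xi <- X[cls == g, , drop = FALSE]
    ss <- ss + colSums(sweep(Xi, 2L, centroids[g, ], "-")^2)
  }
  s_j <- sqrt(as.numeric(ss) / (n - K))
  s0 <- median(s_j)
  denom_zero <- s_j + s0 == 0
  if (any(denom_zero))
    warning("feature(s) with zero pooled SD and zero s0 reported as 0: ",
            paste(colnames(X)[denom_zero], collapse = ", "), call. = FALSE)
  d <- matrix(0, ncol(X), K, dimnames = list(colnames(X), levels(cls)))
  for (g in levels(cls)) {
    m_k <- sqrt(1 / nk[[g]] + 1 / n)
    num <- centroids[g, ] - overall
    dk <- num / (m_k * (s_j + s0))
    dk[denom_zero] <- 0
    d[, g] <- dk
  }
  if (shrinkage > 0)
    d <- sign(d) * pmax(abs(d) - shrinkage, 0)
  d
}

#' Full evaluation report
#'
#' Assembles the blind-test / prospective-style report: ROC AUC, the PPV table
#' at the configured index thresholds, Kaplan-Meier curves and a log-rank test
#' across risk groups, mean outcome-window ED counts per risk group, and
#' shrunken differences of each feature across risk classes.
#'
#' @param fm An `ed_feature_matrix` (the evaluation rows).
#' @param raw_scores Raw model scores for those rows.
#' @param map A `calibration_map`.
#' @param thresholds Index thresholds for the PPV table.
#' @param shrinkage Passed to [shrunken_difference()].
#' @return An object of class `ed_evaluation`.
#' @export
evaluate_risk <- function(fm, raw_scores, map, thresholds = c(30, 50, 70, 80),
                          shrinkage = 0) {
  idx <- risk_index(map, raw_scores)
  grp <- assign_risk_group(idx, map$t_medium, map$t_high)
  roc <- roc_auc(raw_scores, fm$outcome)
  lr <- if (length(unique(grp)) >= 2L)
    logrank_test(fm$time_to_event, fm$event, grp) else NULL
  structure(list(
    auc = roc$auc,
    roc_curve = roc$curve,
    ppv_table = ppv_table(idx, fm$outcome, thresholds),
    km_curves = km_curve(fm$time_to_event, fm$event, grp),
    logrank = lr,
    mean_ed_by_group = mean_ed_by_group(fm$outcome_ed_count, grp),
    shrunken = shrunken_difference(fm$X, grp, shrinkage),
    risk_index = idx,
    risk_group = grp,
    n = length(raw_scores)),
    class = "ed_evaluation")
}

#' @export
print.ed_evaluation <- function(x, ...) {
  cat("ED risk evaluation on", x$n, "patients\n")
  cat(sprintf("  ROC AUC: %.3f\n", x$auc))
  if (!is.null(x$logrank))
    cat(sprintf("  log-rank: chi-square %.1f on %d df, p %s\n",
                x$logrank$statistic, x$logrank$df,
                format.pval(x$logrank$p_value, digits = 3)))
  print(x$ppv_table, row.names = FALSE)
  invisible(x)
}
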