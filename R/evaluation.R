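#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a uniformly random positive outranks a uniformly
#' random negative, with ties counted one half — computed from midranks, so
#' it is exact and invariant under any strictly increasing transform of the
#' scores.
#'
#' @param labels Binary vector in {0, 1}.
#' @param scores Numeric vector, higher = more positive.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(labels, scores) {
  check_binary_metric_input(labels, scores)
  pos <- labels == 1
  r <- rank(scores, ties.method = "average")
  n1 <- sum(pos)
  n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_binary_metric_input <- function(labels, scores, both_classes = TRUE) {
  if (length(labels) != length(scores)) {
    stop("`labels` and `scores` must have equal length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) {
    stop("`labels` must be binary 0/1", call. = FALSE)
  }
  if (both_classes && length(unique(labels)) < 2L) {
    stop("metric undefined: only one class present", call. = FALSE)
  }
  invisible(TRUE)
}

#' Area under the precision-recall curve (step-wise average precision)
#'
#' Computed by the step-wise rule
#' \eqn{\sum_k (R_k - R_{k-1}) P_k} over the distinct score thresholds in
#' decreasing order, where \eqn{P_k}, \eqn{R_k} are precision and recall at
#' threshold \eqn{k}; tied scores enter as one threshold group. For random
#' scores the value approaches the positive prevalence.
#'
#' @param labels Binary vector in {0, 1} with at least one positive.
#' @param scores Numeric score vector.
#' @return AUPRC in (0, 1\].
#' @export
auprc <- function(labels, scores) {
  check_binary_metric_input(labels, scores, both_classes = FALSE)
  if (sum(labels == 1) == 0L) {
    stop("metric undefined: no positives", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  nseen <- seq_along(lab)
  last_of_group <- c(diff(sc) != 0, TRUE)  # threshold = end of each tie group
  tp_k <- tp[last_of_group]
  n_k <- nseen[last_of_group]
  prec <- tp_k / n_k
  rec <- tp_k / sum(lab)
  sum(diff(c(0, rec)) * prec)
}

#' Percentile bootstrap confidence interval for a scan-level metric
#'
#' Resamples observations (scans) with replacement `n_boot` times,
#' recomputes the metric, and reports the percentile interval. Degenerate
#' resamples on which the metric is undefined (one class) are skipped and
#' counted in `attr(, "n_degenerate")`. Deterministic given `seed`.
#'
#' @param metric A function `(labels, scores) -> value`, e.g. [auroc()].
#' @param labels,scores Observed data.
#' @param n_boot Number of resamples (>= 100).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Numeric `c(lower, upper)` with attribute `n_degenerate`.
#' @export
bootstrap_ci <- function(metric, labels, scores, n_boot = 1000, level = 0.95,
                         seed = 1L) {
  stopifnot(n_boot >= 100, level > 0, level < 1)
  set.seed(seed)
  n <- length(labels)
  vals <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    vals[b] <- tryCatch(metric(labels[idx], scores[idx]),
                        error = function(e) NA_real_)
  }
  ok <- !is.na(vals)
  alpha <- (1 - level) / 2
  ci <- stats::quantile(vals[ok], c(alpha, 1 - alpha), names = FALSE,
                        type = 7)
  attr(ci, "n_degenerate") <- sum(!ok)
  ci
}

delong_components <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong test for two correlated AUROCs
#'
#' Compares the AUROCs of two score vectors evaluated on the same
#' observations using DeLong's structural-components estimate of
#' \eqn{\mathrm{var}(\widehat{AUC}_a - \widehat{AUC}_b)} for paired data;
#' the statistic \eqn{z = \Delta AUC / \sqrt{\mathrm{var}}} is referred to
#' the standard normal, two-sided. When the variance is zero and the AUROCs
#' are equal (e.g. identical predictors) the p-value is 1 by convention; a
#' zero-variance nonzero difference yields p = 0.
#'
#' @param labels Binary labels (both classes present).
#' @param scores_a,scores_b Paired score vectors on the same observations.
#' @return List: `p_value`, `z`, `auc_a`, `auc_b`, `var_diff`.
#' @export
delong_pvalue <- function(labels, scores_a, scores_b) {
  check_binary_metric_input(labels, scores_a)
  if (length(scores_a) != length(scores_b)) {
    stop("`scores_a` and `scores_b` must be paired (equal length)",
         call. = FALSE)
  }
  ca <- delong_components(labels, scores_a)
  cb <- delong_components(labels, scores_b)
  m <- length(ca$v10)
  n <- length(ca$v01)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  dauc <- ca$auc - cb$auc
  if (!is.finite(var_diff) || var_diff <= 0) {
    p <- if (abs(dauc) < .Machine$double.eps^0.5) 1 else 0
    return(list(p_value = p, z = if (p == 1) 0 else sign(dauc) * Inf,
                auc_a = ca$auc, auc_b = cb$auc, var_diff = max(var_diff, 0)))
  }
  z <- dauc / sqrt(var_diff)
  list(p_value = 2 * stats::pnorm(-abs(z)), z = z,
       auc_a = ca$auc, auc_b = cb$auc, var_diff = var_diff)
}

#' Subgroup index sets from scan-level predictions
#'
#' Builds the four evaluation cohorts from each scan's pair group id
#' (single-scan units are excluded): Cohort 1 = progression pairs (set1);
#' Cohort 2 = set1 and set2 (stable negatives); Cohort 3 = set1 and set3
#' (stable positives); Cohort 4 = set2 and set3. Both scans of each
#' qualifying pair are included. By construction C1 is contained in C2 and
#' in C3.
#'
#' @param pred Data.frame of scan-level predictions with a `set_id` column
#'   (see [predict_scan_risks()]).
#' @return List of four logical index vectors `C1`..`C4` over `pred` rows.
#' @export
build_subgroups <- function(pred) {
  sid <- pred$set_id
  list(C1 = sid == "set1",
       C2 = sid %in% c("set1", "set2"),
       C3 = sid %in% c("set1", "set3"),
       C4 = sid %in% c("set2", "set3"))
}

#' AUROC stratified by ordinal grade
#'
#' Computes the AUROC separately among the scans of each grade 0-4; grades
#' in which only one class is present are reported as `NA` (undefined),
#' never as 0 or 0.5.
#'
#' @param labels,scores Scan-level labels and risks.
#' @param grades Integer grades in 0..4.
#' @return Named numeric vector of length 5 (`grade0`..`grade4`).
#' @export
per_grade_auroc <- function(labels, scores, grades) {
  stopifnot(all(grades %in% 0:4))
  out <- vapply(0:4, function(g) {
    i <- grades == g
    tryCatch(auroc(labels[i], scores[i]), error = function(e) NA_real_)
  }, numeric(1))
  names(out) <- paste0("grade", 0:4)
  out
}

metric_cell <- function(labels, scores, n_boot, level, seed) {
  point_auroc <- tryCatch(auroc(labels, scores), error = function(e) NA_real_)
  point_auprc <- tryCatch(auprc(labels, scores), error = function(e) NA_real_)
  ci_auroc <- ci_auprc <- c(NA_real_, NA_real_)
  if (!is.na(point_auroc) && n_boot > 0) {
    ci_auroc <- bootstrap_ci(auroc, labels, scores, n_boot, level, seed)
    ci_auprc <- bootstrap_ci(auprc, labels, scores, n_boot, level,
                             derive_seed(seed, 1L))
  }
  list(auroc = point_auroc, auroc_ci = as.numeric(ci_auroc),
       auprc = point_auprc, auprc_ci = as.numeric(ci_auprc),
       n = length(labels), n_pos = sum(labels == 1))
}

#' Scan-level evaluation report
#'
#' For each formulation present in the predictions: AUROC and AUPRC with
#' percentile-bootstrap confidence intervals, DeLong p-values for the
#' requested model contrasts (paired on the common scans), subgroup (Cohort
#' 1-4) metrics, and per-grade AUROC. All metrics are scan-level: every
#' scan's risk is scored against its own horizon label, pooling first and
#' second scans.
#'
#' @param pred Data.frame of scan-level predictions for one horizon with
#'   columns `formulation`, `subject_id`, `scan_index`, `risk`, `label`,
#'   `grade`, `set_id`.
#' @param contrasts List of 2-element character vectors naming formulation
#'   pairs for the DeLong test (default: baseline vs riskform2 when both
#'   are present).
#' @param n_boot Bootstrap resamples (0 disables CIs).
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return An object of class `eval_report` (nested list).
#' @export
eval_report <- function(pred, contrasts = NULL, n_boot = 1000, level = 0.95,
                        seed = 1L) {
  stopifnot(all(c("formulation", "subject_id", "scan_index", "risk",
                  "label", "grade", "set_id") %in% names(pred)))
  forms <- unique(pred$formulation)
  if (is.null(contrasts) && all(c("baseline", "riskform2") %in% forms)) {
    contrasts <- list(c("baseline", "riskform2"))
  }
  per_form <- lapply(forms, function(fm) {
    p <- pred[pred$formulation == fm, , drop = FALSE]
    cell <- metric_cell(p$label, p$risk, n_boot, level, seed)
    groups <- build_subgroups(p)
    sub <- lapply(groups, function(i) {
      metric_cell(p$label[i], p$risk[i], n_boot, level, seed)
    })
    cell$subgroups <- sub
    cell$per_grade_auroc <- as.list(per_grade_auroc(p$label, p$risk, p$grade))
    cell
  })
  names(per_form) <- forms

  delong <- list()
  for (ct in contrasts %||% list()) {
    a <- pred[pred$formulation == ct[1], , drop = FALSE]
    b <- pred[pred$formulation == ct[2], , drop = FALSE]
    key_a <- paste(a$subject_id, a$scan_index)
    key_b <- paste(b$subject_id, b$scan_index)
    common <- intersect(key_a, key_b)
    ia <- match(common, key_a)
    ib <- match(common, key_b)
    res <- delong_pvalue(a$label[ia], a$risk[ia], b$risk[ib])
    delong[[paste(ct, collapse = "_vs_")]] <- res
  }
  structure(list(models = per_form, delong = delong,
                 n_boot = n_boot, level = level, seed = seed),
            class = "eval_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report\n")
  for (fm in names(x$models)) {
    m <- x$models[[fm]]
    cat(sprintf("  %-10s AUROC %.3f (%.3f, %.3f)  AUPRC %.3f (%.3f, %.3f)  n=%d (%d pos)\n",
                fm, m$auroc, m$auroc_ci[1], m$auroc_ci[2],
                m$auprc, m$auprc_ci[1], m$auprc_ci[2], m$n, m$n_pos))
  }
  for (nm in names(x$delong)) {
    cat(sprintf("  DeLong %s: p = %.3g\n", nm, x$delong[[nm]]$p_value))
  }
  invisible(x)
}

#' Write an evaluation report as JSON and a formatted CSV table
#'
#' The CSV mirrors the usual approach-by-metric comparison layout:
#' one row per formulation and evaluation cohort, columns
#' `metric (ci_lower, ci_upper)`.
#'
#' @param report An [eval_report()].
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @export
write_eval_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  if (!is.null(csv_path)) {
    fmt <- function(cell) {
      c(sprintf("%.3f (%.3f, %.3f)", cell$auroc, cell$auroc_ci[1],
                cell$auroc_ci[2]),
        sprintf("%.3f (%.3f, %.3f)", cell$auprc, cell$auprc_ci[1],
                cell$auprc_ci[2]),
        cell$n, cell$n_pos)
    }
    rows <- list()
    for (fm in names(report$models)) {
      m <- report$models[[fm]]
      rows[[length(rows) + 1L]] <- c(fm, "all", fmt(m))
      for (cg in names(m$subgroups)) {
        rows[[length(rows) + 1L]] <- c(fm, cg, fmt(m$subgroups[[cg]]))
      }
    }
    tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    colnames(tab) <- c("formulation", "cohort", "auroc_ci", "auprc_ci",
                       "n_scans", "n_positive")
    utils::write.csv(tab, csv_path, row.names = FALSE)
  }
  invisible(report)
}
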