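# Classification metrics: one-vs-rest TP/TN/FP/FN reductions per class,
# SEN/SPE/PRE/F1, per-class accuracy (TP+TN)/(TP+TN+FP+FN), the headline
# multiclass accuracy trace/total, and mean +/- sd aggregation over
# cross-validation runs.

#' Per-class metrics from a confusion matrix
#'
#' Each class is reduced one-vs-rest: TP is the diagonal entry, FN/FP the
#' off-diagonal row/column sums, TN the remainder.  `SEN = TP/(TP+FN)`,
#' `SPE = TN/(TN+FP)`, `PRE = TP/(TP+FP)`, `F1 = 2*PRE*SEN/(PRE+SEN)`, and
#' the per-class accuracy is `(TP+TN)/(TP+TN+FP+FN)`.  Undefined 0/0 ratios
#' are reported as `NA`, never silently zeroed.  The overall multiclass
#' accuracy (trace/total) is reported alongside.
#'
#' @param cm square non-negative confusion matrix, true classes in rows.
#' @return a `class_metrics` list: `per_class` data.frame, `accuracy`
#'   (trace/total), `n` (total test samples).
#' @export
confusion_to_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("confusion matrix must be non-negative")
  n <- sum(cm)
  classes <- rownames(cm) %||% paste0("C", seq_len(nrow(cm)))
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  safe_div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  sen <- safe_div(tp, tp + fn)
  spe <- safe_div(tn, tn + fp)
  pre <- safe_div(tp, tp + fp)
  f1 <- ifelse(!is.na(pre) & !is.na(sen) & (pre + sen) > 0,
               2 * pre * sen / (pre + sen), NA_real_)
  acc <- (tp + tn) / n
  structure(list(
    per_class = data.frame(class = classes, TP = tp, TN = tn, FP = fp,
                           FN = fn, SEN = sen, SPE = spe, PRE = pre,
                           F1 = f1, ACC = acc, row.names = NULL),
    accuracy = sum(tp) / n,
    n = n), class = "class_metrics")
}

format_pm <- function(mean_pct, sd_pct) {
  sprintf("(%.2f±%.2f)%%", mean_pct, sd_pct)
}

#' Aggregate metrics over cross-validation runs
#'
#' Arithmetic mean and sample standard deviation of each per-class metric
#' and of the overall accuracy across runs, reported as percentages with
#' two decimals in `(mean±sd)%` form.
#'
#' @param runs list of `class_metrics` (>= 2 runs, identical class sets).
#' @return list with `table` (class x metric means/sds) and `overall`
#'   (multiclass accuracy mean, sd, formatted string).
#' @export
aggregate_runs <- function(runs) {
  if (length(runs) < 2) stop("need >= 2 runs to aggregate")
  classes <- runs[[1]]$per_class$class
  for (r in runs)
    if (!identical(r$per_class$class, classes))
      stop("heterogeneous class sets across runs")
  metrics <- c("SEN", "SPE", "PRE", "F1", "ACC")
  rows <- list()
  for (ci in seq_along(classes)) {
    for (m in metrics) {
      vals <- vapply(runs, function(r) r$per_class[[m]][ci], 0) * 100
      rows[[length(rows) + 1L]] <- data.frame(
        class = classes[ci], metric = m,
        mean_pct = mean(vals), sd_pct = sd(vals),
        formatted = format_pm(mean(vals), sd(vals)))
    }
  }
  acc <- vapply(runs, function(r) r$accuracy, 0) * 100
  list(table = do.call(rbind, rows),
       overall = list(mean_pct = mean(acc), sd_pct = sd(acc),
                      formatted = format_pm(mean(acc), sd(acc))))
}

#' Mean row-normalized confusion matrix
#'
#' Elementwise mean over runs, then each row divided by its sum; zero rows
#' become `NA` rows.
#'
#' @param cms a confusion matrix or list of them.
#' @return row-normalized matrix (rows sum to 1 where defined).
#' @export
normalize_confusion <- function(cms) {
  if (is.matrix(cms)) cms <- list(cms)
  m <- Reduce(`+`, lapply(cms, function(x) as.matrix(x) * 1)) / length(cms)
  rs <- rowSums(m)
  out <- m / rs
  out[rs == 0, ] <- NA_real_
  out
}
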