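# HER2 label groupings and the evaluation metric suite. Scores follow the
# ASCO/CAP categories "0", "1+", "2+", "3+"; grouping schemes map them to
# 4-class (identity), 3-class (negative 0/1+, borderline 2+, positive 3+) or
# binary (negative 0/1+ vs positive 3+, with the equivocal 2+ excluded).

her2_scores <- c("0", "1+", "2+", "3+")

#' HER2 label grouping schemes
#'
#' @param name `"four_class"`, `"three_class"` or `"binary"`.
#' @return A `label_scheme` object: the scheme name, its class levels, and the
#'   score-to-class mapping (`NA` marks scores excluded from the scheme).
#' @export
#' @examples
#' label_scheme("binary")
label_scheme <- function(name = c("four_class", "three_class", "binary")) {
  name <- match.arg(name)
  map <- switch(name,
    four_class = c("0" = "0", "1+" = "1+", "2+" = "2+", "3+" = "3+"),
    three_class = c("0" = "negative", "1+" = "negative",
                    "2+" = "borderline", "3+" = "positive"),
    binary = c("0" = "negative", "1+" = "negative",
               "2+" = NA, "3+" = "positive"))
  structure(list(name = name, levels = unique(stats::na.omit(unname(map))),
                 map = map),
            class = "label_scheme")
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("HER2 label scheme '", x$name, "':\n", sep = "")
  for (s in names(x$map))
    cat("  ", s, "->", if (is.na(x$map[s])) "EXCLUDED" else x$map[s], "\n")
  invisible(x)
}

#' Group HER2 scores under a labeling scheme
#'
#' @param scores Character vector of HER2 scores (`"0"`, `"1+"`, `"2+"`,
#'   `"3+"`).
#' @param scheme A [label_scheme()] or its name.
#' @return A list: `labels`, a factor of grouped class labels for the
#'   surviving samples, and `keep`, a logical mask over the input marking
#'   which samples survive (excluded scores are dropped).
#' @export
#' @examples
#' group_labels(c("0", "1+", "2+", "3+"), "binary")
group_labels <- function(scores, scheme = "four_class") {
  if (is.character(scheme)) scheme <- label_scheme(scheme)
  scores <- as.character(scores)
  bad <- setdiff(unique(scores), her2_scores)
  if (length(bad))
    stop("unknown HER2 score(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(her2_scores, collapse = ", "), ")")
  mapped <- scheme$map[scores]
  keep <- unname(!is.na(mapped))
  list(labels = factor(unname(mapped[keep]), levels = scheme$levels),
       keep = keep)
}

# rank-based AUC (equals the Mann-Whitney statistic); ties get average ranks
auc_binary <- function(y, p) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Matthews correlation coefficient
#'
#' Multiclass MCC in covariance form over the confusion matrix; for two
#' classes this reduces to the familiar
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. A degenerate zero
#' denominator (e.g. all predictions in one class) yields 0 by convention.
#'
#' @param y_true,y_pred Vectors of equal length (factors or atomic).
#' @return A number in `[-1, 1]`.
#' @export
#' @examples
#' mcc(c(0, 0, 1, 1), c(0, 0, 1, 0))
mcc <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (length(y_true) < 1) stop("need at least one sample")
  lev <- union(as.character(y_true), as.character(y_pred))
  cm <- table(factor(y_true, lev), factor(y_pred, lev))
  mcc_from_confusion(unclass(cm))
}

mcc_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  s <- sum(cm); c0 <- sum(diag(cm))
  tk <- rowSums(cm); pk <- colSums(cm)
  num <- c0 * s - sum(pk * tk)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  if (den == 0) return(0)
  num / den
}

#' Confusion matrix and full metric report
#'
#' Derives hard predictions from probabilities (argmax for multiclass, a 0.5
#' threshold on the positive-class probability for binary), then computes the
#' confusion matrix, overall accuracy, per-class and macro-averaged precision,
#' recall and F1, AUC (standard rank-based AUC for two classes, macro
#' one-vs-rest for more), and the Matthews correlation coefficient. Accuracy,
#' precision, recall, F1 and AUC are reported in percent; MCC on `[-1, 1]`.
#'
#' @param y_true Factor (or vector) of true class labels.
#' @param y_prob Probability matrix (N x K, rows summing to 1) whose columns
#'   follow the levels of `y_true`, or a vector of positive-class
#'   probabilities for the binary case.
#' @return A `metrics_report` list: `confusion`, `accuracy`, `precision`,
#'   `recall`, `f1`, `auc`, `mcc`, `per_class`.
#' @export
confusion_and_summary <- function(y_true, y_prob) {
  y_true <- as.factor(y_true)
  lev <- levels(y_true)
  K <- length(lev)
  if (is.null(dim(y_prob))) {
    if (K > 2) stop("probability vector supplied for a ", K, "-class problem")
    p1 <- as.numeric(y_prob)
    y_prob <- cbind(1 - p1, p1)
  }
  if (ncol(y_prob) != K)
    stop("y_prob has ", ncol(y_prob), " columns but y_true has ", K, " levels")
  pred <- factor(lev[max.col(y_prob, ties.method = "first")], levels = lev)
  if (K == 2) pred <- factor(lev[1 + (y_prob[, 2] >= 0.5)], levels = lev)
  cm <- unclass(table(true = y_true, pred = pred))

  tp <- diag(cm); fn <- rowSums(cm) - tp; fp <- colSums(cm) - tp
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))

  single <- length(unique(y_true)) < 2
  if (single) {
    warning("AUC undefined: y_true contains a single class")
    auc <- NA_real_
  } else if (K == 2) {
    auc <- auc_binary(as.integer(y_true == lev[2]), y_prob[, 2])
  } else {
    aucs <- vapply(seq_len(K), function(k)
      auc_binary(as.integer(y_true == lev[k]), y_prob[, k]), 0)
    auc <- mean(aucs, na.rm = TRUE)
  }
  structure(list(
    confusion = cm,
    accuracy = 100 * sum(tp) / sum(cm),
    precision = 100 * mean(prec),
    recall = 100 * mean(rec),
    f1 = 100 * mean(f1),
    auc = if (is.na(auc)) NA_real_ else 100 * auc,
    mcc = mcc_from_confusion(cm),
    per_class = data.frame(class = lev, precision = prec, recall = rec,
                           f1 = f1, support = rowSums(cm),
                           row.names = NULL)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  cat("Confusion matrix (rows = true, cols = predicted):\n")
  print(x$confusion)
  cat(sprintf(paste0("Accuracy %.", digits, "f%% | Precision %.", digits,
                     "f%% | Recall %.", digits, "f%% | F1 %.", digits,
                     "f%% | AUC %s | MCC %.4f\n"),
              x$accuracy, x$precision, x$recall, x$f1,
              if (is.na(x$auc)) "NA" else sprintf(paste0("%.", digits, "f%%"),
                                                  x$auc),
              x$mcc))
  invisible(x)
}

#' Serialize a metrics report
#'
#' Writes the report as JSON (full structure) or CSV (summary row plus
#' per-class rows), chosen by the file extension.
#'
#' @param report A `metrics_report`.
#' @param path Output path ending in `.json` or `.csv`.
#' @export
write_metrics <- function(report, path) {
  if (grepl("\\.json$", path)) {
    out <- unclass(report)
    out$confusion <- as.data.frame.matrix(report$confusion)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else if (grepl("\\.csv$", path)) {
    summary_row <- data.frame(class = "macro",
                              precision = report$precision / 100,
                              recall = report$recall / 100,
                              f1 = report$f1 / 100,
                              support = sum(report$confusion))
    utils::write.csv(rbind(report$per_class, summary_row), path,
                     row.names = FALSE)
  } else stop("path must end in .json or .csv")
  invisible(path)
}

#' Plot a confusion matrix heat map
#'
#' @param x A `metrics_report`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.metrics_report <- function(x, ...) {
  cm <- x$confusion
  K <- nrow(cm)
  pal <- grDevices::colorRampPalette(c("white", "steelblue"))(64)
  graphics::image(seq_len(K), seq_len(K), t(cm[K:1, , drop = FALSE]),
                  col = pal, axes = FALSE, xlab = "Predicted", ylab = "True",
                  ...)
  graphics::axis(1, seq_len(K), colnames(cm))
  graphics::axis(2, seq_len(K), rev(rownames(cm)))
  for (i in seq_len(K)) for (j in seq_len(K))
    graphics::text(j, K - i + 1, cm[i, j])
  invisible(x)
}
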