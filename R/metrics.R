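#' Pixelwise confusion counts
#'
#' @param pred_mask,gt_mask binary/logical matrices of identical dims.
#' @return list (`confusion`) with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(pred_mask, gt_mask) {
  if (!all(dim(pred_mask) == dim(gt_mask))) stop_bad("mask dimensions differ")
  p <- pred_mask > 0; g <- gt_mask > 0
  structure(list(TP = sum(p & g), FP = sum(p & !g),
                 FN = sum(!p & g), TN = sum(!p & !g)), class = "confusion")
}

#' Precision, recall and F1 from confusion counts
#'
#' `R = TP/(TP+FN)`, `P = TP/(TP+FP)`, `F1 = 2PR/(P+R)`; undefined ratios
#' (zero denominators) are reported as 0 with a warning.
#'
#' @param c a [confusion()] object or list with `TP`, `FP`, `FN`.
#' @return Named vector `(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(c) {
  safe <- function(num, den, what) {
    if (den == 0) { warning(sprintf("%s undefined (0/0); reporting 0", what)); 0 }
    else num / den
  }
  P <- safe(c$TP, c$TP + c$FP, "precision")
  R <- safe(c$TP, c$TP + c$FN, "recall")
  F1 <- if (P + R == 0) 0 else 2 * P * R / (P + R)
  c(precision = P, recall = R, f1 = F1)
}

#' Jaccard index (intersection over union)
#'
#' `|S ∩ M| / |S ∪ M|`, identically `TP/(TP+FP+FN)`.  Two empty masks agree
#' perfectly and score 1 by convention.
#'
#' @param pred_mask,gt_mask binary/logical matrices of identical dims.
#' @export
jaccard <- function(pred_mask, gt_mask) {
  if (!all(dim(pred_mask) == dim(gt_mask))) stop_bad("mask dimensions differ")
  p <- pred_mask > 0; g <- gt_mask > 0
  u <- sum(p | g)
  if (u == 0) return(1)
  sum(p & g) / u
}

#' Per-class slide accuracy table
#'
#' Accuracy within each true class (percent), in the conventional
#' normal/macro/micro/ITC layout; classes absent from the truth are reported
#' as `NA` and excluded from the tumor average.
#'
#' @param pred_labels,true_labels character vectors over
#'   `c("negative", "itc", "micro", "macro")`.
#' @return data frame `class, n, accuracy` with attribute `tumor_average`.
#' @export
evaluate_slide_set <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels)) stop_bad("length mismatch")
  bad <- setdiff(unique(c(pred_labels, true_labels)), SLIDE_LABELS)
  if (length(bad)) stop_bad("unknown slide label: %s", paste(bad, collapse = ", "))
  classes <- c("negative", "macro", "micro", "itc")
  acc <- vapply(classes, function(cl) {
    sel <- true_labels == cl
    if (!any(sel)) return(NA_real_)
    100 * mean(pred_labels[sel] == cl)
  }, numeric(1))
  out <- data.frame(class = classes,
                    n = vapply(classes, function(cl) sum(true_labels == cl),
                               numeric(1)),
                    accuracy = acc, row.names = NULL)
  attr(out, "tumor_average") <- tumor_average(acc)
  out
}

#' Average accuracy over the tumor classes
#'
#' The mean of the macro, micro and ITC class accuracies (the negative class
#' is excluded); `NA` entries (empty classes) are dropped.
#'
#' @param acc named numeric vector of per-class accuracies or the table from
#'   [evaluate_slide_set()].
#' @export
tumor_average <- function(acc) {
  if (is.data.frame(acc)) acc <- stats::setNames(acc$accuracy, acc$class)
  if (is.null(names(acc))) return(mean(acc, na.rm = TRUE))
  mean(acc[intersect(names(acc), c("macro", "micro", "itc", "itcs"))],
       na.rm = TRUE)
}

#' Render an accuracy table as Markdown
#' @param tab value of [evaluate_slide_set()].
#' @export
accuracy_markdown <- function(tab) {
  fmt <- function(x) ifelse(is.na(x), "n/a", sprintf("%.1f", x))
  c("| Class | n | Accuracy (%) |", "|---|---|---|",
    sprintf("| %s | %d | %s |", tab$class, tab$n, fmt(tab$accuracy)),
    sprintf("| tumor average |  | %.2f |", attr(tab, "tumor_average")))
}
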