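#' @title Residue-level evaluation metrics
#' @description AUROC (Mann-Whitney formulation, ties count 1/2), AUPRC
#'   (average precision over distinct score thresholds), and accuracy with
#'   confusion counts at the uniform 0.5 decision threshold.
#' @name metrics
NULL

#' Area under the ROC curve
#'
#' Mann-Whitney formulation via midranks; tied score pairs contribute 1/2.
#' Invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric vector.
#' @param labels binary 0/1 vector of the same length.
#' @return AUROC in `[0, 1]`, or `NA` (with a warning) when only one
#'   class is present.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    warning("AUROC undefined: need at least one positive and one negative")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise summation over distinct score thresholds (descending):
#' `AP = sum_k (R_k - R_{k-1}) * P_k`, where tied scores enter as one
#' threshold block.
#'
#' @param scores numeric vector.
#' @param labels binary 0/1 vector.
#' @return AUPRC in `[0, 1]`, or `NA` (with a warning) when there are no
#'   positives.
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  P <- sum(labels == 1)
  if (P == 0) {
    warning("AUPRC undefined: no positive labels")
    return(NA_real_)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # block boundaries at distinct scores
  last_of_block <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_block]
  n <- seq_along(s)[last_of_block]
  prec <- tp / n
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Accuracy and confusion counts at a decision threshold
#'
#' A residue is called positive when its score is strictly greater than
#' the threshold (0.5 uniformly by default).
#'
#' @param scores numeric vector.
#' @param labels binary 0/1 vector.
#' @param threshold decision threshold (default 0.5).
#' @return list: `acc = (TP+TN)/(TP+TN+FP+FN)` and `confusion`
#'   (named TP/TN/FP/FN integer vector).
#' @export
accuracy_score <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  call <- scores > threshold
  TP <- sum(call & labels == 1); TN <- sum(!call & labels == 0)
  FP <- sum(call & labels == 0); FN <- sum(!call & labels == 1)
  list(acc = (TP + TN) / length(labels),
       confusion = c(TP = TP, TN = TN, FP = FP, FN = FN))
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y log p + (1-y) log(1-p))` over unmasked entries, with
#' probabilities clipped at 1e-7 for stability.
#'
#' @param probs,labels numeric matrices of equal shape; labels in {0,1}.
#' @param mask optional 0/1 matrix; defaults to all ones.
#' @return scalar loss.
#' @export
bce_loss <- function(probs, labels, mask = NULL) {
  if (is.null(mask)) mask <- array(1, dim(as.matrix(probs)))
  probs <- as.matrix(probs); labels <- as.matrix(labels)
  mask <- as.matrix(mask)
  n <- sum(mask)
  if (n == 0) stop("BCE undefined: all entries masked")
  p <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
  ll <- -(labels * log(p) + (1 - labels) * log(1 - p))
  sum(ll * mask) / n
}

#' Evaluate a model on a labeled, featurized set
#'
#' Residues of all chains are pooled per task (micro average) by default;
#' `pooling = "macro"` averages per-chain metrics instead.  Chains lacking
#' positives for a task are excluded from that task's AUROC/AUPRC under
#' macro pooling (and contribute only negatives under micro pooling).
#'
#' @param model an `egnn_model`.
#' @param items list of `list(graph, labels)` pairs (labels: L x 5).
#' @param threshold decision threshold (default 0.5).
#' @param pooling `"micro"` (default) or `"macro"`.
#' @return a `metrics_report`: per-task AUROC, AUPRC, Acc, confusion
#'   counts, n_pos, n_neg.
#' @export
evaluate_model <- function(model, items, threshold = 0.5,
                           pooling = c("micro", "macro")) {
  pooling <- match.arg(pooling)
  if (!length(items)) stop("empty evaluation set")
  preds <- lapply(items, function(it) predict_graph(model, it$graph)$probs)
  labs <- lapply(items, function(it) it$labels)
  tasks <- TASKS[seq_len(ncol(preds[[1]]))]
  per_task <- lapply(seq_along(tasks), function(t) {
    if (pooling == "micro") {
      s <- unlist(lapply(preds, function(p) p[, t]))
      y <- unlist(lapply(labs, function(l) l[, t]))
      au <- if (sum(y == 1) > 0 && sum(y == 0) > 0) auroc(s, y) else NA_real_
      ap <- if (sum(y == 1) > 0) auprc(s, y) else NA_real_
      ac <- accuracy_score(s, y, threshold)
      list(auroc = au, auprc = ap, acc = ac$acc, confusion = ac$confusion,
           n_pos = sum(y == 1), n_neg = sum(y == 0))
    } else {
      rows <- lapply(seq_along(preds), function(k) {
        s <- preds[[k]][, t]; y <- labs[[k]][, t]
        c(au = if (sum(y == 1) > 0 && sum(y == 0) > 0) auroc(s, y) else NA,
          ap = if (sum(y == 1) > 0) auprc(s, y) else NA)
      })
      M <- do.call(rbind, rows)
      s <- unlist(lapply(preds, function(p) p[, t]))
      y <- unlist(lapply(labs, function(l) l[, t]))
      ac <- accuracy_score(s, y, threshold)
      list(auroc = mean(M[, "au"], na.rm = TRUE),
           auroc_sd = stats::sd(M[, "au"], na.rm = TRUE),
           auprc = mean(M[, "ap"], na.rm = TRUE),
           auprc_sd = stats::sd(M[, "ap"], na.rm = TRUE),
           acc = ac$acc, confusion = ac$confusion,
           n_pos = sum(y == 1), n_neg = sum(y == 0))
    }
  })
  names(per_task) <- tasks
  structure(list(tasks = per_task, pooling = pooling,
                 threshold = threshold), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> (", x$pooling, " pooling, threshold ",
      x$threshold, ")\n", sep = "")
  for (t in names(x$tasks)) {
    m <- x$tasks[[t]]
    cat(sprintf("  %-8s AUROC=%s AUPRC=%s Acc=%.4f (pos=%d neg=%d)\n", t,
                formatC(m$auroc, digits = 4, format = "f"),
                formatC(m$auprc, digits = 4, format = "f"),
                m$acc, m$n_pos, m$n_neg))
  }
  invisible(x)
}

#' Export ROC and PR curve points
#'
#' Raw (FPR, TPR) and (recall, precision) points at every distinct score
#' threshold, for plotting.
#'
#' @param scores,labels as in [auroc()].
#' @return list of two data.frames: `roc`, `pr`.
#' @export
curve_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last]; n <- seq_along(s)[last]
  fp <- n - tp
  P <- sum(y == 1); N <- sum(y == 0)
  list(roc = data.frame(threshold = s[last], fpr = fp / max(N, 1),
                        tpr = tp / max(P, 1)),
       pr = data.frame(threshold = s[last], recall = tp / max(P, 1),
                       precision = tp / n))
}
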