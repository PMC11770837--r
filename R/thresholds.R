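## Per-class decision-threshold calibration. Thresholds are fitted on
## validation predictions with a one-vs-rest criterion and applied at
## inference: a non-null class is eligible only if its probability reaches
## its threshold; if no class is eligible the null label is assigned.

ovr_f1 <- function(pred_pos, gold_pos) {
  tp <- sum(pred_pos & gold_pos)
  fp <- sum(pred_pos & !gold_pos)
  fn <- sum(!pred_pos & gold_pos)
  if (tp == 0) return(0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

#' Fit per-class probability thresholds on validation predictions
#'
#' For each non-null class, candidate thresholds are the sorted unique
#' predicted probabilities of that class over the validation set, plus 0.5.
#' The candidate maximizing the one-vs-rest F1 (predict the class iff its
#' probability is >= the threshold) is chosen, ties broken toward the
#' smallest candidate, and the result is floored at 0.5. A class with no
#' positive validation instance defaults to 0.5 with a warning. The null
#' label never competes via a threshold; its entry is fixed at 0.5.
#'
#' @param val_probs n x 23 matrix of validation probabilities (columns in
#'   [relation_labels()] order).
#' @param val_labels length-n character vector of gold labels.
#' @return An object of class \code{threshold_table}: named numeric vector
#'   over all 23 labels, every entry in \[0.5, 1\].
#' @export
fit_thresholds <- function(val_probs, val_labels) {
  labs <- relation_labels()
  val_probs <- as.matrix(val_probs)
  if (nrow(val_probs) == 0L) stop("no validation instances", call. = FALSE)
  if (nrow(val_probs) != length(val_labels)) {
    stop("val_probs and val_labels lengths differ", call. = FALSE)
  }
  keep <- !is.na(val_probs[, 1L])
  val_probs <- val_probs[keep, , drop = FALSE]
  val_labels <- val_labels[keep]
  th <- stats::setNames(rep(0.5, length(labs)), labs)
  for (c_idx in seq_along(labs)) {
    lab <- labs[c_idx]
    if (lab == null_label()) next
    gold_pos <- val_labels == lab
    if (!any(gold_pos)) {
      warning("no positive validation instances for ", lab,
              "; threshold defaults to 0.5", call. = FALSE)
      next
    }
    pc <- val_probs[, c_idx]
    cands <- sort(unique(c(pc, 0.5)))
    f1s <- vapply(cands, function(t) ovr_f1(pc >= t, gold_pos), numeric(1))
    best <- cands[which.max(f1s)]   # which.max returns the first (smallest)
    th[c_idx] <- max(best, 0.5)
  }
  structure(th, class = "threshold_table")
}

#' Apply per-class thresholds to one probability vector
#'
#' Non-null classes whose probability reaches their threshold (inclusive)
#' are eligible; if none is eligible the null label is returned, otherwise
#' the eligible class with maximal probability (ties broken toward the
#' earlier label in schema order).
#'
#' @param probs named length-23 probability vector (or a vector in
#'   [relation_labels()] order).
#' @param table a [fit_thresholds()] result (or named numeric vector).
#' @return A single label.
#' @export
apply_thresholds <- function(probs, table) {
  labs <- relation_labels()
  if (length(probs) != length(labs) || anyNA(probs)) {
    stop("probs must be a complete vector over the 23 labels", call. = FALSE)
  }
  probs <- stats::setNames(as.numeric(probs), labs)
  pos <- positive_labels()
  eligible <- pos[probs[pos] >= as.numeric(table[pos])]
  if (length(eligible) == 0L) return(null_label())
  eligible[which.max(probs[eligible])]
}

#' Apply thresholds to a probability matrix
#' @param probs n x 23 matrix.
#' @param table a threshold table.
#' @return Character vector of n predicted labels (\code{NA} rows of
#'   \code{probs} yield \code{NA}).
#' @export
apply_thresholds_matrix <- function(probs, table) {
  apply(as.matrix(probs), 1L, function(p) {
    if (anyNA(p)) NA_character_ else apply_thresholds(p, table)
  })
}

#' Read a threshold table from TSV
#' @param path two-column TSV (label, threshold) with header.
#' @return A \code{threshold_table}.
#' @export
read_threshold_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  th <- stats::setNames(rep(0.5, length(relation_labels())),
                        relation_labels())
  th[df[[1L]]] <- as.numeric(df[[2L]])
  if (any(th < 0.5 | th > 1)) {
    stop("thresholds must lie in [0.5, 1]", call. = FALSE)
  }
  structure(th, class = "threshold_table")
}

#' Write a threshold table to TSV
#' @param table a threshold table.
#' @param path file path.
#' @export
write_threshold_table <- function(table, path) {
  df <- data.frame(label = names(table), threshold = as.numeric(table),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
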