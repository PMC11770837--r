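## Evaluation: per-class and aggregate precision/recall/F1 excluding the
## null label, macro one-vs-rest AUC, McNemar's paired test, and the
## two-system overlap decomposition of gold relations.

#' F1 score from precision and recall
#' @param precision,recall numeric scalars (or vectors).
#' @return Harmonic mean; 0 where both inputs are 0.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Precision, recall and F1 against gold labels
#'
#' Computes per-class true/false positives and false negatives, per-class
#' precision/recall/F1, and micro and macro aggregates. The null label is
#' excluded from the aggregates: it participates as a source of errors for
#' the other classes (a null-gold instance predicted as class c is a false
#' positive of c; a c-gold instance predicted null is a false negative of
#' c) but contributes no class of its own. Zero-division yields 0 and is
#' flagged in the per-class table. Macro aggregates are unweighted means
#' over the classes in \code{macro_labels} (default: the non-null classes
#' with gold or predicted support, which on fully covered data is all 22).
#'
#' @param gold,pred aligned character vectors of labels.
#' @param macro_labels classes to average for the macro metrics.
#' @return An object of class \code{eval_report}: list with
#'   \code{per_class} (data.frame), \code{micro}, \code{macro} (named
#'   vectors precision/recall/f1) and \code{confusion} (table).
#' @export
prf <- function(gold, pred,
                macro_labels = NULL) {
  if (length(gold) != length(pred)) {
    stop("gold and pred must have equal length", call. = FALSE)
  }
  labs <- relation_labels()
  bad <- setdiff(unique(c(gold, pred)), labs)
  if (length(bad) > 0L) {
    stop("unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  pos <- positive_labels()
  tp <- fp <- fn <- stats::setNames(numeric(length(pos)), pos)
  for (c in pos) {
    tp[c] <- sum(gold == c & pred == c)
    fp[c] <- sum(pred == c & gold != c)
    fn[c] <- sum(gold == c & pred != c)
  }
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- f1_score(prec, rec)
  per_class <- data.frame(
    label = pos, tp = as.numeric(tp), fp = as.numeric(fp),
    fn = as.numeric(fn), support = as.numeric(tp + fn),
    precision = as.numeric(prec), recall = as.numeric(rec),
    f1 = as.numeric(f1),
    zero_division = as.logical((tp + fp == 0) | (tp + fn == 0)),
    stringsAsFactors = FALSE
  )
  micro_p <- if (sum(tp + fp) == 0) 0 else sum(tp) / sum(tp + fp)
  micro_r <- if (sum(tp + fn) == 0) 0 else sum(tp) / sum(tp + fn)
  if (is.null(macro_labels)) {
    macro_labels <- pos[(tp + fn + fp)[pos] > 0]
    if (length(macro_labels) == 0L) macro_labels <- pos
  }
  sel <- per_class$label %in% macro_labels
  macro <- c(precision = mean(per_class$precision[sel]),
             recall = mean(per_class$recall[sel]),
             f1 = mean(per_class$f1[sel]))
  structure(
    list(per_class = per_class,
         micro = c(precision = micro_p, recall = micro_r,
                   f1 = f1_score(micro_p, micro_r)),
         macro = macro,
         macro_labels = macro_labels,
         confusion = table(gold = factor(gold, levels = labs),
                           pred = factor(pred, levels = labs))),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Relation classification evaluation (null label excluded)\n")
  cat(sprintf("  micro  P %.3f  R %.3f  F1 %.3f\n",
              x$micro["precision"], x$micro["recall"], x$micro["f1"]))
  cat(sprintf("  macro  P %.3f  R %.3f  F1 %.3f  (over %d classes)\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"],
              length(x$macro_labels)))
  invisible(x)
}

# rank-based (Mann-Whitney) AUC for one class; ties get midranks
binary_auc <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Macro one-vs-rest AUC
#'
#' Averages the one-vs-rest AUC over all classes (including the null label)
#' that have at least one positive and one negative gold instance; classes
#' lacking both are skipped with a message.
#'
#' @param probs n x 23 probability matrix (columns in [relation_labels()]
#'   order).
#' @param gold length-n gold labels (at least two distinct values).
#' @return Scalar macro AUC with attribute \code{per_class}.
#' @export
auc_ovr <- function(probs, gold) {
  probs <- as.matrix(probs)
  if (length(unique(gold)) < 2L) {
    stop("AUC undefined for single-class gold labels", call. = FALSE)
  }
  labs <- relation_labels()
  aucs <- stats::setNames(rep(NA_real_, length(labs)), labs)
  for (i in seq_along(labs)) {
    aucs[i] <- binary_auc(probs[, i], gold == labs[i])
  }
  skipped <- names(aucs)[is.na(aucs) & labs %in% unique(gold)]
  used <- aucs[!is.na(aucs)]
  out <- mean(used)
  attr(out, "per_class") <- aucs
  attr(out, "n_classes") <- length(used)
  out
}

#' McNemar's paired test for two classifiers
#'
#' Takes per-instance correctness of two systems over the same instances and
#' tests the discordant counts b (A correct, B wrong) and c (A wrong, B
#' correct). With b + c < 25 the exact two-sided binomial p-value is used
#' (no statistic); otherwise the chi-square statistic with continuity
#' correction \eqn{(|b-c|-1)^2/(b+c)} on 1 degree of freedom. With no
#' discordant pairs the p-value is 1 and the statistic is \code{NULL}.
#'
#' @param correct_a,correct_b aligned logical vectors.
#' @return List with \code{b}, \code{c}, \code{statistic} (or \code{NULL}),
#'   \code{p_value}, and \code{method}.
#' @export
mcnemar <- function(correct_a, correct_b) {
  if (length(correct_a) != length(correct_b)) {
    stop("correctness vectors must be aligned", call. = FALSE)
  }
  b <- sum(correct_a & !correct_b)
  c_ <- sum(!correct_a & correct_b)
  n <- b + c_
  if (n == 0L) {
    return(list(b = b, c = c_, statistic = NULL, p_value = 1,
                method = "degenerate"))
  }
  if (n < 25L) {
    p <- min(1, 2 * stats::pbinom(min(b, c_), n, 0.5))
    return(list(b = b, c = c_, statistic = NULL, p_value = p,
                method = "exact binomial"))
  }
  stat <- (abs(b - c_) - 1)^2 / n
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(b = b, c = c_, statistic = stat, p_value = p,
       method = "chi-square with continuity correction")
}

## ----------------------------------------------------------------- overlap --

# canonical matching key for a relation triple, folding the bidirectional
# and inverse-pair equivalences: bidirectional predicates sort their
# arguments; part_of is rewritten as location_of with swapped arguments.
relation_match_key <- function(doc_id, sentence_id, subject, predicate,
                               object) {
  inv <- inverse_label_map()
  n <- length(predicate)
  subj <- as.character(subject); obj <- as.character(object)
  pred <- as.character(predicate)
  for (i in seq_len(n)) {
    if (pred[i] %in% bidirectional_labels()) {
      pair <- sort(c(subj[i], obj[i]))
      subj[i] <- pair[1]; obj[i] <- pair[2]
    } else if (pred[i] == "part_of") {
      pred[i] <- inv[["part_of"]]
      tmp <- subj[i]; subj[i] <- obj[i]; obj[i] <- tmp
    }
  }
  paste(doc_id, sentence_id, subj, pred, obj, sep = "|")
}

as_relation_df <- function(x) {
  need <- c("doc_id", "sentence_id", "subject", "predicate", "object")
  if (!all(need %in% names(x))) {
    stop("relation set needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Two-system overlap decomposition of gold relations
#'
#' Partitions each gold relation into found-by-both, found by system A only,
#' found by system B only, or found by neither, per relation category.
#' Matching folds the bidirectional equivalences (argument swap for
#' bidirectional predicates) and the location_of/part_of inverse pair.
#'
#' @param gold,preds_a,preds_b data.frames with columns \code{doc_id},
#'   \code{sentence_id}, \code{subject}, \code{predicate}, \code{object}.
#' @return An object of class \code{overlap_report}: data.frame with one row
#'   per category and columns \code{both}, \code{a_only}, \code{b_only},
#'   \code{neither}, \code{support}.
#' @export
overlap <- function(gold, preds_a, preds_b) {
  gold <- as_relation_df(gold)
  a_keys <- if (nrow(preds_a <- as_relation_df(preds_a)) == 0L) character()
    else relation_match_key(preds_a$doc_id, preds_a$sentence_id,
                            preds_a$subject, preds_a$predicate,
                            preds_a$object)
  b_keys <- if (nrow(preds_b <- as_relation_df(preds_b)) == 0L) character()
    else relation_match_key(preds_b$doc_id, preds_b$sentence_id,
                            preds_b$subject, preds_b$predicate,
                            preds_b$object)
  if (nrow(gold) == 0L) {
    return(structure(data.frame(category = character(), both = integer(),
                                a_only = integer(), b_only = integer(),
                                neither = integer(), support = integer()),
                     class = c("overlap_report", "data.frame")))
  }
  g_keys <- relation_match_key(gold$doc_id, gold$sentence_id, gold$subject,
                               gold$predicate, gold$object)
  in_a <- g_keys %in% a_keys
  in_b <- g_keys %in% b_keys
  cat_of <- gold$predicate
  cats <- sort(unique(cat_of))
  rows <- lapply(cats, function(cc) {
    sel <- cat_of == cc
    data.frame(category = cc,
               both = sum(sel & in_a & in_b),
               a_only = sum(sel & in_a & !in_b),
               b_only = sum(sel & !in_a & in_b),
               neither = sum(sel & !in_a & !in_b),
               support = sum(sel), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("overlap_report", "data.frame"))
}
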