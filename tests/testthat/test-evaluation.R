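# brute-force confusion-matrix oracle
oracle_prf <- function(gold, pred) {
  pos <- positive_labels()
  tp <- fp <- fn <- 0
  per <- list()
  for (c in pos) {
    tpc <- sum(gold == c & pred == c)
    fpc <- sum(pred == c & gold != c)
    fnc <- sum(gold == c & pred != c)
    tp <- tp + tpc; fp <- fp + fpc; fn <- fn + fnc
    p <- if (tpc + fpc == 0) 0 else tpc / (tpc + fpc)
    r <- if (tpc + fnc == 0) 0 else tpc / (tpc + fnc)
    per[[c]] <- c(p = p, r = r,
                  f1 = if (p + r == 0) 0 else 2 * p * r / (p + r))
  }
  micro_p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  micro_r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  list(per = per, micro_p = micro_p, micro_r = micro_r)
}

test_that("printed-scale precision/recall pairs give the printed F1", {
  expect_identical(round(f1_score(0.62, 0.81), 2), 0.70)
  expect_identical(round(f1_score(0.57, 0.84), 2), 0.68)
  expect_identical(round(f1_score(0.61, 0.37), 2), 0.46)
})

test_that("prf handles perfect predictions and a hand-counted confusion", {
  gold <- c("causes", "causes", "treats", "no_rel")
  rep1 <- prf(gold, gold)
  expect_equal(unname(rep1$micro), c(1, 1, 1))
  expect_equal(unname(rep1$macro["f1"]), 1)

  # class A: TP=2, FP=1, FN=1 -> P=R=F1=2/3
  gold2 <- c("causes", "causes", "causes", "treats", "no_rel")
  pred2 <- c("causes", "causes", "treats", "causes", "no_rel")
  r <- prf(gold2, pred2)
  row <- r$per_class[r$per_class$label == "causes", ]
  expect_equal(row$precision, 2 / 3)
  expect_equal(row$recall, 2 / 3)
  expect_equal(row$f1, 2 / 3)
  expect_error(prf(gold2, pred2[1:3]), "length")
})

test_that("the null label contributes errors but no class of its own", {
  gold <- c("no_rel", "no_rel", "causes")
  pred <- c("causes", "no_rel", "no_rel")
  r <- prf(gold, pred)
  row <- r$per_class[r$per_class$label == "causes", ]
  expect_equal(row$fp, 1)     # null-gold predicted causes
  expect_equal(row$fn, 1)     # causes-gold predicted null
  expect_false("no_rel" %in% r$per_class$label)
  expect_equal(unname(r$micro["precision"]), 0)
})

test_that("prf agrees with the confusion-matrix oracle on 200 random runs", {
  labs <- c("causes", "treats", "inhibits", "isa", "no_rel")
  withr::with_seed(41, {
    for (rep in 1:200) {
      n <- sample(5:50, 1)
      gold <- sample(labs, n, replace = TRUE)
      pred <- sample(labs, n, replace = TRUE)
      r <- prf(gold, pred)
      o <- oracle_prf(gold, pred)
      expect_equal(unname(r$micro["precision"]), o$micro_p)
      expect_equal(unname(r$micro["recall"]), o$micro_r)
      expect_equal(unname(r$micro["f1"]),
                   f1_score(o$micro_p, o$micro_r))
      for (c in r$macro_labels) {
        expect_equal(r$per_class$f1[r$per_class$label == c],
                     unname(o$per[[c]]["f1"]))
      }
      expect_equal(unname(r$macro["f1"]),
                   mean(vapply(r$macro_labels,
                               function(c) unname(o$per[[c]]["f1"]),
                               numeric(1))))
    }
  })
})

test_that("one-vs-rest AUC behaves at the extremes and on a hand case", {
  labs <- relation_labels()
  mk_probs <- function(scores_causes, n) {
    p <- matrix(0.01, n, 23, dimnames = list(NULL, labs))
    p[, "causes"] <- scores_causes
    p[, "no_rel"] <- 1 - scores_causes
    p
  }
  gold <- c("causes", "causes", "no_rel", "no_rel")
  expect_equal(as.numeric(auc_ovr(mk_probs(c(0.9, 0.8, 0.2, 0.1), 4),
                                  gold)), 1)
  # one inversion among 4: positives ranked {0.9, 0.3} vs negatives
  # {0.5, 0.1} -> 3 of 4 pairs correct -> AUC 0.75 for both classes
  expect_equal(as.numeric(auc_ovr(mk_probs(c(0.9, 0.3, 0.5, 0.1), 4),
                                  gold)), 0.75)
  expect_error(auc_ovr(mk_probs(c(0.9, 0.8, 0.2, 0.1), 4),
                       rep("causes", 4)), "single-class")
  # label-independent probabilities: AUC near 0.5 at large n
  withr::with_seed(13, {
    n <- 4000
    g <- sample(c("causes", "no_rel"), n, replace = TRUE)
    expect_equal(as.numeric(auc_ovr(mk_probs(runif(n), n), g)), 0.5,
                 tolerance = 0.05)
  })
})

test_that("rank-based AUC matches an established implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(19, {
    for (rep in 1:10) {
      n <- 30
      scores <- runif(n)
      pos <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.4, .6))
      if (!any(pos) || all(pos)) next
      ref <- as.numeric(pROC::auc(pROC::roc(pos, scores, quiet = TRUE,
                                            direction = "<")))
      expect_equal(relclass:::binary_auc(scores, pos), ref,
                   tolerance = 1e-10)
    }
  })
})

test_that("McNemar switches between exact and corrected chi-square forms", {
  # b = c = 5: exact and symmetric -> p = 1
  ca <- c(rep(TRUE, 5), rep(FALSE, 5))
  cb <- !ca
  res <- mcnemar(ca, cb)
  expect_identical(res$p_value, 1)
  expect_null(res$statistic)

  # b = 10, c = 2 -> exact two-sided binomial: 2 * (1 + 12 + 66) / 4096
  ca <- c(rep(TRUE, 10), rep(FALSE, 2))
  cb <- c(rep(FALSE, 10), rep(TRUE, 2))
  res <- mcnemar(ca, cb)
  enum <- 2 * sum(choose(12, 0:2)) / 2^12
  expect_equal(res$p_value, enum, tolerance = 1e-12)
  expect_equal(res$p_value, 158 / 4096, tolerance = 1e-12)

  # b = 100, c = 50 -> (|b-c|-1)^2/(b+c) = 49^2/150
  ca <- c(rep(TRUE, 100), rep(FALSE, 50))
  cb <- c(rep(FALSE, 100), rep(TRUE, 50))
  res <- mcnemar(ca, cb)
  expect_equal(res$statistic, 49^2 / 150, tolerance = 1e-9)
  expect_lt(res$p_value, 0.001)
  # matches the standard implementation
  ref <- stats::mcnemar.test(matrix(c(0, 100, 50, 0), 2), correct = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)

  # no discordant pairs
  res0 <- mcnemar(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_identical(res0$p_value, 1)
})

test_that("McNemar is symmetric in the two systems", {
  withr::with_seed(23, {
    for (rep in 1:20) {
      n <- sample(10:200, 1)
      a <- sample(c(TRUE, FALSE), n, replace = TRUE)
      b <- sample(c(TRUE, FALSE), n, replace = TRUE)
      expect_equal(mcnemar(a, b)$p_value, mcnemar(b, a)$p_value)
    }
  })
})

test_that("overlap decomposes gold relations across two systems", {
  rel <- function(s, p, o) data.frame(
    doc_id = "D1", sentence_id = "S1", subject = s, predicate = p,
    object = o, stringsAsFactors = FALSE)
  gold <- rel("A", "causes", "B")
  r <- overlap(gold, gold, gold[0, ])
  expect_identical(r$a_only, 1L)
  expect_identical(r$both + r$a_only + r$b_only + r$neither, r$support)

  # bidirectional predicates match under argument swap
  gold2 <- rel("A", "associated_with", "B")
  swapped <- rel("B", "associated_with", "A")
  r2 <- overlap(gold2, swapped, gold2[0, ])
  expect_identical(r2$a_only, 1L)
  expect_identical(r2$neither, 0L)

  # the inverse pair folds: B-part_of-A matches gold A-location_of-B
  gold3 <- rel("A", "location_of", "B")
  invd <- rel("B", "part_of", "A")
  r3 <- overlap(gold3, gold3[0, ], invd)
  expect_identical(r3$b_only, 1L)
})

test_that("overlap partitions sum to gold support on random sets", {
  labs <- c("causes", "treats", "associated_with", "location_of")
  withr::with_seed(29, {
    for (rep in 1:20) {
      mk <- function(n) data.frame(
        doc_id = "D1", sentence_id = as.character(sample(1:3, n, TRUE)),
        subject = sample(LETTERS[1:5], n, TRUE),
        predicate = sample(labs, n, TRUE),
        object = sample(LETTERS[1:5], n, TRUE),
        stringsAsFactors = FALSE)
      gold <- unique(mk(12))
      r <- overlap(gold, mk(8), mk(8))
      expect_identical(r$both + r$a_only + r$b_only + r$neither, r$support)
      expect_identical(sum(r$support), nrow(gold))
    }
  })
})
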