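two_type_sentence <- function() {
  # subject entity with 2 semantic types, object with 3
  e1 <- entity_mention("rabeprazole", 0L, 11L, "C1",
                       semtypes = c("Organic Chemical",
                                    "Pharmacologic Substance"),
                       semgroups = "Chemicals and Drugs")
  e2 <- entity_mention("ulcer", 19L, 24L, "C2",
                       semtypes = c("Disease or Syndrome",
                                    "Pathologic Function", "Finding"),
                       semgroups = "Disorders")
  sentence_record("D1", "S1", "rabeprazole treats ulcer", list(e1, e2))
}

all_pairs_table <- function(sent) {
  rows <- expand.grid(
    subject_semtype = sent$entities[[1]]$semtypes,
    object_semtype = sent$entities[[2]]$semtypes,
    stringsAsFactors = FALSE)
  rows$predicate <- "treats"
  constraint_table(rows)
}

test_that("candidate enumeration crosses semantic types under constraints", {
  sent <- two_type_sentence()
  tab <- all_pairs_table(sent)
  cands <- enumerate_candidates(sent, tab)
  fwd <- cands[cands$subj_idx == 1, ]
  expect_identical(nrow(fwd), 6L)         # 2 x 3 licensed combinations
  expect_identical(nrow(cands[cands$subj_idx == 2, ]), 0L)

  # no licensed pair -> no candidates
  tab0 <- constraint_table(data.frame(subject_semtype = "X",
                                      predicate = "causes",
                                      object_semtype = "Y",
                                      stringsAsFactors = FALSE))
  expect_identical(nrow(enumerate_candidates(sent, tab0)), 0L)
})

test_that("three single-type entities give six ordered pairs", {
  mk <- function(surface, start, cui) {
    entity_mention(surface, start, start + nchar(surface), cui,
                   semtypes = "T1", semgroups = "G1")
  }
  sent <- sentence_record("D1", "S1", "aaa bbb ccc",
                          list(mk("aaa", 0L, "C1"), mk("bbb", 4L, "C2"),
                               mk("ccc", 8L, "C3")))
  tab <- constraint_table(data.frame(subject_semtype = "T1",
                                     predicate = "causes",
                                     object_semtype = "T1",
                                     stringsAsFactors = FALSE))
  cands <- enumerate_candidates(sent, tab)
  expect_identical(nrow(cands), 6L)
  expect_identical(nrow(unique(cands[, c("subj_idx", "obj_idx")])), 6L)
})

test_that("candidate counts factor as licensed subject x object types", {
  withr::with_seed(37, {
    for (rep in 1:15) {
      s_types <- paste0("S", seq_len(sample(1:3, 1)))
      o_types <- paste0("O", seq_len(sample(1:3, 1)))
      lic_s <- sample(s_types, sample(seq_along(s_types), 1))
      lic_o <- sample(o_types, sample(seq_along(o_types), 1))
      rows <- expand.grid(subject_semtype = lic_s, predicate = "causes",
                          object_semtype = lic_o,
                          stringsAsFactors = FALSE)
      e1 <- entity_mention("aaa", 0L, 3L, "C1", semtypes = s_types,
                           semgroups = "G")
      e2 <- entity_mention("bbb", 4L, 7L, "C2", semtypes = o_types,
                           semgroups = "G")
      sent <- sentence_record("D", "S", "aaa bbb", list(e1, e2))
      cands <- enumerate_candidates(sent, constraint_table(rows))
      fwd <- cands[cands$subj_idx == 1, ]
      expect_identical(nrow(fwd), length(lic_s) * length(lic_o))
    }
  })
})

test_that("predict_pair scores all type combinations and keeps the best", {
  sent <- two_type_sentence()
  tab <- all_pairs_table(sent)
  cands <- enumerate_candidates(sent, tab)
  fwd <- cands[cands$subj_idx == 1, ]
  th <- structure(stats::setNames(rep(0.5, 23), relation_labels()),
                  class = "threshold_table")
  scorer <- trigger_oracle_scorer(list(treats = "treats",
                                       no_rel = "ignored_phrase"))
  rec <- predict_pair(sent, 1L, 2L, fwd, scorer, th)
  expect_identical(rec$predicate, "treats")
  expect_identical(rec$subject_cui, "C1")
  expect_gte(rec$probability, 0.5)

  # all candidates below threshold -> nothing
  weak <- trigger_oracle_scorer(list(treats = "treats"), confidence = 0.3)
  expect_null(predict_pair(sent, 1L, 2L, fwd, weak, th))

  # the higher-probability candidate wins
  biased <- function(instance) {
    p <- stats::setNames(rep(0.001, 23), relation_labels())
    p["treats"] <- if (grepl("Organic Chemical", instance$sentence$text,
                             fixed = TRUE)) 0.8 else 0.7
    p
  }
  rec2 <- predict_pair(sent, 1L, 2L, fwd, biased, th)
  expect_identical(rec2$subject_type, "Organic Chemical")
  expect_equal(rec2$probability, 0.8)
  expect_error(predict_pair(sent, 1L, 2L, fwd[0, ], biased, th), "candidate")
})

test_that("hierarchy oracle computes transitive descendant queries", {
  edges <- data.frame(parent = c("root", "mid"), child = c("mid", "leaf"),
                      stringsAsFactors = FALSE)
  h <- hierarchy_oracle(edges)
  expect_true(h$is_descendant("leaf", "mid"))
  expect_true(h$is_descendant("leaf", "root"))    # transitive closure
  expect_false(h$is_descendant("root", "leaf"))
  expect_false(h$is_descendant("leaf", "leaf"))   # irreflexive
  expect_false(h$is_descendant("unknown", "root"))
})

test_that("verify_isa drops only hierarchy-violating isa records", {
  edges <- data.frame(parent = "C_dis", child = "C_sub",
                      stringsAsFactors = FALSE)
  h <- hierarchy_oracle(edges)
  recs <- data.frame(
    doc_id = "D1", sentence_id = c("S1", "S2", "S3"),
    subject_cui = c("C_sub", "C_x", "C_a"), subject_name = "s",
    subject_type = "T", predicate = c("isa", "isa", "causes"),
    object_cui = c("C_dis", "C_dis", "C_b"), object_name = "o",
    object_type = "T", probability = 0.9, stringsAsFactors = FALSE)
  out <- verify_isa(recs, h)
  expect_identical(nrow(out), 2L)
  expect_true(all(out$sentence_id %in% c("S1", "S3")))
  expect_identical(sum(out$predicate != "isa"),
                   sum(recs$predicate != "isa"))  # non-isa untouched
  expect_warning(verify_isa(recs, NULL), "skipped")
})

test_that("diff_with_store partitions records and folds equivalences", {
  rec <- data.frame(
    doc_id = "D1", sentence_id = "S1", subject_cui = "A",
    subject_name = "a", subject_type = "T",
    predicate = "associated_with", object_cui = "B", object_name = "b",
    object_type = "T", probability = 0.9, stringsAsFactors = FALSE)
  empty_store <- data.frame(doc_id = character(),
                            sentence_id = character(),
                            subject_cui = character(),
                            predicate = character(),
                            object_cui = character(),
                            stringsAsFactors = FALSE)
  d <- diff_with_store(rec, empty_store)
  expect_identical(nrow(d$new), 1L)

  store_swapped <- data.frame(
    doc_id = "D1", sentence_id = "S1", subject_cui = "B",
    predicate = "associated_with", object_cui = "A",
    stringsAsFactors = FALSE)
  d2 <- diff_with_store(rec, store_swapped)
  expect_identical(nrow(d2$shared), 1L)
  expect_identical(nrow(d2$new), 0L)
  expect_identical(nrow(d2$store_only), 0L)

  # partitions are disjoint and exhaustive
  store2 <- data.frame(
    doc_id = "D1", sentence_id = "S1", subject_cui = c("B", "X"),
    predicate = c("associated_with", "causes"), object_cui = c("A", "Y"),
    stringsAsFactors = FALSE)
  d3 <- diff_with_store(rec, store2)
  expect_identical(nrow(d3$new) + nrow(d3$shared), nrow(rec))
  expect_identical(nrow(d3$shared) + nrow(d3$store_only), nrow(store2))
})

test_that("stratified sampling draws per category, deterministically", {
  withr::with_seed(43, {
    new <- data.frame(
      doc_id = sprintf("D%04d", 1:600), sentence_id = "S1",
      subject_cui = sprintf("A%04d", 1:600), subject_name = "s",
      subject_type = "T",
      predicate = rep(positive_labels(), length.out = 600),
      object_cui = sprintf("B%04d", 1:600), object_name = "o",
      object_type = "T", probability = 0.8, stringsAsFactors = FALSE)
  })
  s <- stratified_sample(new, per_category = 23, seed = 2)
  tab <- table(s$predicate)
  expect_true(all(tab <= 23))
  full <- names(table(new$predicate))[table(new$predicate) >= 23]
  expect_true(all(tab[full] == 23))
  # exhaustion: a category with fewer records is drawn whole
  small <- new[new$predicate == "administered_to", ][1:5, ]
  rest <- new[new$predicate != "administered_to", ]
  s2 <- stratified_sample(rbind(small, rest), per_category = 23, seed = 2)
  expect_identical(sum(s2$predicate == "administered_to"), 5L)
  # determinism, independent of row order
  s3 <- stratified_sample(new[sample(nrow(new)), ], per_category = 23,
                          seed = 2)
  expect_identical(s$subject_cui[order(s$subject_cui)],
                   s3$subject_cui[order(s3$subject_cui)])
})

test_that("expansion estimates scale new counts by review accuracy", {
  expect_identical(estimate_expansion(77541, 0.67), 51952L)
  expect_identical(estimate_expansion(1000, 0), 0L)
  expect_identical(estimate_expansion(100, 0.5), 50L)
  expect_error(estimate_expansion(10, 1.2), "0, 1")
})
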