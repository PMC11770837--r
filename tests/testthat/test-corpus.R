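make_gs_instances <- function(n_sent, per_sent = 1L) {
  out <- list()
  for (i in seq_len(n_sent)) {
    sent <- fix_sentence(doc = sprintf("D%03d", i))
    for (j in seq_len(per_sent)) out <- c(out, list(
      relation_instance(sent, sent$entities[[1]], sent$entities[[2]],
                        "inhibits", source = "gs")))
  }
  out
}

test_that("gold-standard sentences split 20/80 at the sentence level", {
  gs <- make_gs_instances(10, per_sent = 2L)
  out <- assign_splits(gs, seed = 3)
  split_by_sent <- tapply(
    vapply(out, function(x) x$split, character(1)),
    vapply(out, function(x) x$sentence$doc_id, character(1)),
    unique)
  expect_true(all(lengths(split_by_sent) == 1L))  # sentence-level
  expect_identical(sum(split_by_sent == "train"), 2L)
  expect_identical(sum(split_by_sent == "test"), 8L)
  expect_identical(assign_splits(list(), seed = 1), list())
})

test_that("accuracy-source instances split 90/10 with floor on validation", {
  acc <- make_gs_instances(20)
  acc <- lapply(acc, function(x) { x$source <- "acc"; x })
  out <- assign_splits(list(), acc_instances = acc, seed = 3)
  splits <- vapply(out, function(x) x$split, character(1))
  expect_identical(sum(splits == "train"), 18L)
  expect_identical(sum(splits == "val"), 2L)
})

test_that("split assignment is invariant to input order under one seed", {
  gs <- make_gs_instances(12)
  a <- assign_splits(gs, seed = 11)
  b <- assign_splits(rev(gs), seed = 11)
  key_split <- function(z) {
    s <- vapply(z, function(x) x$split, character(1))
    names(s) <- vapply(z, function(x) x$sentence$doc_id, character(1))
    s[order(names(s))]
  }
  expect_identical(key_split(a), key_split(b))
})

test_that("bidirectional expansion adds reversed instances per rule", {
  sent <- fix_sentence()
  aw <- relation_instance(sent, sent$entities[[1]], sent$entities[[2]],
                          "associated_with", source = "gs")
  out <- expand_bidirectional(list(aw), seed = 1)
  expect_length(out, 2L)
  expect_identical(out[[2]]$label, "associated_with")
  expect_identical(out[[2]]$subject$cui, aw$object$cui)
  expect_identical(out[[2]]$object$cui, aw$subject$cui)

  lo <- relation_instance(sent, sent$entities[[1]], sent$entities[[2]],
                          "location_of", source = "gs")
  out <- expand_bidirectional(list(lo), seed = 1)
  expect_identical(out[[2]]$label, "part_of")
  expect_identical(out[[2]]$subject$cui, lo$object$cui)

  po <- relation_instance(sent, sent$entities[[1]], sent$entities[[2]],
                          "part_of", source = "gs")
  expect_identical(expand_bidirectional(list(po), seed = 1)[[2]]$label,
                   "location_of")

  iw <- lapply(1:10, function(i) relation_instance(
    sent, sent$entities[[1]], sent$entities[[2]], "interacts_with",
    source = "gs"))
  out <- expand_bidirectional(iw, interacts_fraction = 0.10, seed = 1)
  expect_length(out, 11L)   # exactly 1 reversed duplicate
  expect_error(expand_bidirectional(iw, interacts_fraction = 1.5), "0, 1")
})

test_that("expansion count identity holds on mixed corpora", {
  sent <- fix_sentence()
  mk <- function(lab, k) lapply(seq_len(k), function(i) relation_instance(
    sent, sent$entities[[1]], sent$entities[[2]], lab, source = "gs"))
  insts <- c(mk("associated_with", 3), mk("location_of", 2),
             mk("part_of", 4), mk("interacts_with", 25), mk("causes", 5))
  out <- expand_bidirectional(insts, seed = 2)
  # interacts_with count rounds half-up: 0.10 * 25 -> 3
  expect_length(out, length(insts) + 3 + 2 + 4 + floor(0.10 * 25 + 0.5))
})

test_that("negative generation emits fp and conformant negatives once each", {
  tab <- fix_constraints(data.frame(
    subject_semtype = "Gene or Genome", predicate = "interacts_with",
    object_semtype = "Pharmacologic Substance", stringsAsFactors = FALSE))
  sent <- fix_sentence()
  # gold A->B; constraint licenses only (B, A): one conformant negative
  gold <- data.frame(doc_id = "D1", sentence_id = "S1",
                     subject_cui = "CUI:A", predicate = "inhibits",
                     object_cui = "CUI:B", stringsAsFactors = FALSE)
  out <- generate_negatives(list(sent), gold, NULL, tab)
  expect_length(out, 1L)
  expect_identical(out[[1]]$source, "neg_conformant")
  expect_identical(out[[1]]$subject$cui, "CUI:B")
  expect_identical(out[[1]]$label, "no_rel")

  # extractor false positive becomes a neg_fp instance
  fp <- data.frame(doc_id = "D1", sentence_id = "S1",
                   subject_cui = "CUI:A", predicate = "treats",
                   object_cui = "CUI:B", stringsAsFactors = FALSE)
  out <- generate_negatives(list(sent), NULL, fp, tab)
  srcs <- vapply(out, function(x) x$source, character(1))
  expect_identical(sum(srcs == "neg_fp"), 1L)
  fp_inst <- out[[which(srcs == "neg_fp")]]
  expect_identical(fp_inst$subject$cui, "CUI:A")

  # pair with no licensed predicate yields nothing
  tab0 <- fix_constraints(data.frame(
    subject_semtype = "X", predicate = "causes", object_semtype = "Y",
    stringsAsFactors = FALSE))
  expect_length(generate_negatives(list(sent), NULL, NULL, tab0), 0L)
})

test_that("neg_fp takes precedence over conformant duplicates; cap applies", {
  tab <- fix_constraints(data.frame(
    subject_semtype = c("Pharmacologic Substance", "Gene or Genome"),
    predicate = c("inhibits", "interacts_with"),
    object_semtype = c("Gene or Genome", "Pharmacologic Substance"),
    stringsAsFactors = FALSE))
  sent <- fix_sentence()
  fp <- data.frame(doc_id = "D1", sentence_id = "S1",
                   subject_cui = "CUI:A", predicate = "treats",
                   object_cui = "CUI:B", stringsAsFactors = FALSE)
  out <- generate_negatives(list(sent), NULL, fp, tab)
  keys <- vapply(out, function(x) paste(x$subject$cui, x$object$cui),
                 character(1))
  expect_identical(anyDuplicated(keys), 0L)
  srcs <- vapply(out, function(x) x$source, character(1))
  expect_identical(srcs[keys == "CUI:A CUI:B"], "neg_fp")
  capped <- generate_negatives(list(sent), NULL, fp, tab,
                               cap_per_sentence = 1L, seed = 4)
  expect_length(capped, 1L)
  expect_identical(capped[[1]]$source, "neg_fp")
})

test_that("semantic type and group substitution rewrite the worked sentence", {
  txt <- paste0("Western blotting analysis indicated that quercetin ",
                "induces the G0/G1 phase arrest via decreasing the levels ",
                "of CDK2 , cyclins E , and D proteins")
  q_start <- regexpr("quercetin", txt, fixed = TRUE) - 1L
  c_start <- regexpr("CDK2", txt, fixed = TRUE) - 1L
  subj <- entity_mention("quercetin", q_start, q_start + 9L, "C0034392",
                         semtypes = "Pharmacologic Substance",
                         semgroups = "Chemicals and Drugs")
  obj <- entity_mention("CDK2", c_start, c_start + 4L, "C1332733",
                        semtypes = "Gene or Genome",
                        semgroups = "Genes and Molecular Sequences")
  sent <- sentence_record("D1", "S1", txt, list(subj, obj))
  inst <- relation_instance(sent, subj, obj, "inhibits", source = "gs")

  st <- substitute_representation(inst, "semtype")
  expect_match(st$sentence$text,
               "that Pharmacologic Substance induces", fixed = TRUE)
  expect_match(st$sentence$text, "levels of Gene or Genome ,", fixed = TRUE)
  expect_identical(st$subject$surface, "Pharmacologic Substance")
  expect_identical(st$representation, "semtype")

  sg <- substitute_representation(inst, "semgroup")
  expect_match(sg$sentence$text, "that Chemicals and Drugs induces",
               fixed = TRUE)
  expect_match(sg$sentence$text, "of Genes and Molecular Sequences ,",
               fixed = TRUE)

  id <- substitute_representation(inst, "mention")
  expect_identical(id$sentence$text, txt)

  # spans recomputed: surfaces match the new text
  for (x in list(st, sg)) {
    expect_identical(
      substr(x$sentence$text, x$subject$start + 1, x$subject$end),
      x$subject$surface)
    expect_identical(
      substr(x$sentence$text, x$object$start + 1, x$object$end),
      x$object$surface)
  }
  # missing groups are an input error
  no_grp <- entity_mention("quercetin", q_start, q_start + 9L, "C0034392",
                           semtypes = "Pharmacologic Substance")
  sent2 <- sentence_record("D1", "S1", txt, list(no_grp, obj))
  inst2 <- relation_instance(sent2, no_grp, obj, "inhibits", source = "gs")
  expect_error(substitute_representation(inst2, "semgroup"), "semgroups")
})

test_that("marker insertion wraps arguments and strips back to the original", {
  inst <- fix_instance()
  ms <- insert_markers(inst)
  expect_identical(
    ms$text, "<s>aspirin</s> inhibits <o>cdk2</o> strongly today .")
  expect_identical(strip_markers(ms$text), inst$sentence$text)
  expect_identical(
    substr(ms$text, ms$subject_char_span[1] + 1, ms$subject_char_span[2]),
    "<s>aspirin</s>")
  expect_identical(
    substr(ms$text, ms$object_char_span[1] + 1, ms$object_char_span[2]),
    "<o>cdk2</o>")
})

test_that("marker insertion round-trips on random fixtures incl. nesting", {
  withr::with_seed(21, {
    n_nested <- 0L
    for (rep in 1:300) {
      inst <- rand_marked_instance()
      ms <- insert_markers(inst)
      expect_identical(strip_markers(ms$text), inst$sentence$text)
      s <- inst$subject; o <- inst$object
      if (s$start >= o$start && s$end <= o$end) n_nested <- n_nested + 1L
    }
    expect_gt(n_nested, 0L)   # nesting exercised
  })
})

test_that("identical argument spans are a structural error", {
  sent <- fix_sentence()
  expect_error(relation_instance(sent, sent$entities[[1]],
                                 sent$entities[[1]], "causes"),
               "distinct")
})
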