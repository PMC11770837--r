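# Shared fixtures, all built in code.

fix_entity <- function(surface, start, cui = "C1", types = "T1",
                       groups = "G1", name = surface) {
  entity_mention(surface, start, start + nchar(surface), cui, name, types,
                 groups)
}

# "drugA inhibits targetB" style sentence with two entities
fix_sentence <- function(doc = "D1", sid = "S1",
                         text = "aspirin inhibits cdk2 strongly today .",
                         e1 = fix_entity("aspirin", 0L, "CUI:A",
                                         "Pharmacologic Substance",
                                         "Chemicals and Drugs"),
                         e2 = fix_entity("cdk2", 17L, "CUI:B",
                                         "Gene or Genome",
                                         "Genes and Molecular Sequences")) {
  sentence_record(doc, sid, text, list(e1, e2))
}

fix_instance <- function(label = "inhibits", sent = fix_sentence(),
                         split = NA_character_, source = "gs") {
  relation_instance(sent, sent$entities[[1]], sent$entities[[2]], label,
                    source = source, split = split)
}

fix_constraints <- function(rows = NULL) {
  if (is.null(rows)) {
    rows <- data.frame(
      subject_semtype = c("Pharmacologic Substance",
                          "Gene or Genome"),
      predicate = c("inhibits", "interacts_with"),
      object_semtype = c("Gene or Genome", "Pharmacologic Substance"),
      stringsAsFactors = FALSE)
  }
  constraint_table(rows)
}

# random word for generated sentences
rand_word <- function(n = 1) {
  vapply(seq_len(n), function(i) {
    paste(sample(letters, sample(3:8, 1), replace = TRUE), collapse = "")
  }, character(1))
}

# random sentence with two non-overlapping (possibly nested) entity spans
rand_marked_instance <- function(allow_nested = TRUE) {
  words <- rand_word(sample(4:9, 1))
  text <- paste(words, collapse = " ")
  starts <- c(0L, cumsum(nchar(words) + 1L))[seq_along(words)]
  i <- sample(seq_along(words), 1)
  j <- sample(setdiff(seq_along(words), i), 1)
  e1 <- fix_entity(words[i], starts[i], "CUI:1")
  if (allow_nested && nchar(words[j]) >= 2 && stats::runif(1) < 0.3) {
    # nested: subject inside a multi-word object region
    k <- min(i, j); l <- max(i, j)
    span_text_ <- substr(text, starts[k] + 1,
                         starts[l] + nchar(words[l]))
    e2 <- fix_entity(span_text_, starts[k], "CUI:2")
    if (identical(e2$start, e1$start) && identical(e2$end, e1$end)) {
      e2 <- fix_entity(words[j], starts[j], "CUI:2")
    }
  } else {
    e2 <- fix_entity(words[j], starts[j], "CUI:2")
  }
  sent <- sentence_record("D1", "S1", text, list(e1, e2))
  relation_instance(sent, e1, e2, "causes", source = "gs")
}

# tiny trained-model helper used by several suites
fit_tiny_model <- function(n = 200, epochs = 3, seed = 5, noise = 0,
                           contrastive = FALSE) {
  cfg <- synth_config(n_sentences = n, label_noise = noise, seed = seed)
  corp <- make_corpus(cfg)
  texts <- vapply(corp$instances, function(i) insert_markers(i)$text,
                  character(1))
  backend <- tiny_backbone(make_tokenizer(texts), hidden_size = 32L,
                           seed = seed)
  model <- train_relation_model(
    corp$instances, backend,
    train_config(epochs = epochs, learning_rate = default_backbone_lr(),
                 seed = seed),
    pretrain = contrastive,
    aug_config = augmentation_config(synonym_lexicon = corp$lexicon,
                                     seed = seed))
  list(model = model, corpus = corp)
}
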