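## Seeded synthetic corpora and SemMedDB-style tables with the statistical
## structure the system assumes: trigger-word signal per relation label,
## semantic-type constraints, class imbalance, and hard negatives that
## satisfy the constraints but express no relation. Everything is generated
## in code so every pipeline stage is testable without downloads.

default_entity_inventory <- function() {
  df <- function(names, type, group, prefix) {
    data.frame(cui = sprintf("%s%03d", prefix, seq_along(names)),
               name = names, semtypes = type, semgroups = group,
               stringsAsFactors = FALSE)
  }
  rbind(
    df(c("quercetin", "aspirin", "metformin", "rapamycin", "curcumin",
         "resveratrol", "doxorubicin", "ibuprofen"),
       "Pharmacologic Substance", "Chemicals and Drugs", "CD"),
    df(c("pneumonia", "asthma", "sepsis", "fibrosis", "colitis",
         "nephritis", "dermatitis", "hepatitis"),
       "Disease or Syndrome", "Disorders", "DS"),
    df(c("cdk2", "tp53", "egfr", "mtor", "brca1", "vegfa"),
       "Gene or Genome", "Genes and Molecular Sequences", "GG"),
    df(c("liver", "lung", "kidney", "pancreas", "spleen"),
       "Body Part, Organ, or Organ Component", "Anatomy", "BP"),
    df(c("apoptosis", "angiogenesis", "autophagy", "glycolysis"),
       "Cell Function", "Physiology", "CF")
  )
}

default_trigger_lexicon <- function() {
  list(
    causes = c("induces", "causes", "drives"),
    treats = c("treats", "alleviates"),
    inhibits = c("inhibits", "suppresses"),
    stimulates = c("stimulates", "promotes"),
    prevents = c("prevents"),
    predisposes = c("predisposes to"),
    location_of = c("is the site of"),
    interacts_with = c("interacts with", "binds"),
    part_of = c("is a component of"),
    isa = c("is a type of"),
    associated_with = c("is linked with"),
    no_rel = c("was measured alongside", "was examined together with",
               "was recorded in the same assay as")
  )
}

default_constraint_rows <- function() {
  r <- function(s, p, o) data.frame(subject_semtype = s, predicate = p,
                                    object_semtype = o,
                                    stringsAsFactors = FALSE)
  rbind(
    r("Pharmacologic Substance", "causes", "Disease or Syndrome"),
    r("Gene or Genome", "causes", "Disease or Syndrome"),
    r("Pharmacologic Substance", "treats", "Disease or Syndrome"),
    r("Pharmacologic Substance", "inhibits", "Cell Function"),
    r("Pharmacologic Substance", "inhibits", "Gene or Genome"),
    r("Pharmacologic Substance", "stimulates", "Cell Function"),
    r("Pharmacologic Substance", "prevents", "Disease or Syndrome"),
    r("Gene or Genome", "predisposes", "Disease or Syndrome"),
    r("Body Part, Organ, or Organ Component", "location_of",
      "Disease or Syndrome"),
    r("Disease or Syndrome", "part_of", "Body Part, Organ, or Organ Component"),
    r("Pharmacologic Substance", "interacts_with", "Gene or Genome"),
    r("Gene or Genome", "interacts_with", "Pharmacologic Substance"),
    r("Disease or Syndrome", "isa", "Disease or Syndrome"),
    r("Gene or Genome", "associated_with", "Disease or Syndrome"),
    r("Disease or Syndrome", "associated_with", "Gene or Genome")
  )
}

context_families <- function() {
  list(
    c("notably", "markedly", "strikingly", "clearly"),
    c("recent", "previous", "earlier", "prior"),
    c("study", "analysis", "report", "experiment"),
    c("patients", "subjects", "participants"),
    c("observed", "noted", "documented"),
    c("significantly", "substantially", "considerably")
  )
}

#' Synthetic corpus configuration
#'
#' @param n_sentences number of sentences (one instance per sentence).
#' @param relation_labels subset of [positive_labels()] to plant.
#' @param trigger_lexicon named list label -> trigger phrases (must also
#'   contain a \code{no_rel} entry with neutral phrases).
#' @param entity_inventory data.frame with columns \code{cui}, \code{name},
#'   \code{semtypes} (pipe-separated), \code{semgroups}.
#' @param constraint_rows data.frame of licensed triples; every planted
#'   (subject type, label, object type) must appear here.
#' @param negative_fraction fraction of instances that are hard negatives
#'   (constraint-conformant pairs with a neutral phrase, labeled
#'   \code{no_rel}).
#' @param label_noise probability that a planted label is corrupted to a
#'   different label (applied last).
#' @param class_skew geometric imbalance ratio across the relation labels
#'   (1 = uniform; label i gets weight \code{class_skew^(i-1)}).
#' @param split_fracs named numeric vector of train/val/test fractions.
#' @param seed integer seed.
#' @return An object of class \code{synth_config}.
#' @export
synth_config <- function(n_sentences = 1000L,
                         relation_labels = c("causes", "treats", "inhibits",
                                             "stimulates", "prevents",
                                             "predisposes", "location_of",
                                             "interacts_with"),
                         trigger_lexicon = default_trigger_lexicon(),
                         entity_inventory = default_entity_inventory(),
                         constraint_rows = default_constraint_rows(),
                         negative_fraction = 0.3, label_noise = 0,
                         class_skew = 1,
                         split_fracs = c(train = 0.7, val = 0.1,
                                         test = 0.2),
                         seed = 42L) {
  for (p in c(negative_fraction, label_noise)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]",
                             call. = FALSE)
  }
  for (lab in relation_labels) {
    check_label(lab, allow_null = FALSE)
    if (is.null(trigger_lexicon[[lab]]) ||
        length(trigger_lexicon[[lab]]) == 0L) {
      stop("no trigger phrases for requested label ", lab, call. = FALSE)
    }
    if (!any(constraint_rows$predicate == lab)) {
      stop("no constraint rows license label ", lab, call. = FALSE)
    }
  }
  if (is.null(trigger_lexicon$no_rel)) {
    stop("trigger lexicon needs neutral no_rel phrases", call. = FALSE)
  }
  if (abs(sum(split_fracs) - 1) > 1e-9) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  structure(
    list(n_sentences = as.integer(n_sentences),
         relation_labels = relation_labels,
         trigger_lexicon = trigger_lexicon,
         entity_inventory = entity_inventory,
         constraint_rows = constraint_rows,
         negative_fraction = negative_fraction,
         label_noise = label_noise, class_skew = class_skew,
         split_fracs = split_fracs, seed = as.integer(seed)),
    class = "synth_config"
  )
}

inventory_by_type <- function(inventory, type) {
  hit <- vapply(strsplit(inventory$semtypes, "|", fixed = TRUE),
                function(ts) type %in% ts, logical(1))
  inventory[hit, , drop = FALSE]
}

mention_from_row <- function(row, start, surface = row$name) {
  entity_mention(surface, start, start + nchar(surface), row$cui, row$name,
                 strsplit(row$semtypes, "|", fixed = TRUE)[[1]],
                 strsplit(row$semgroups, "|", fixed = TRUE)[[1]])
}

#' Generate a synthetic relation corpus
#'
#' Builds sentences from templates of the form \emph{context, SUBJECT
#' trigger OBJECT context}, where the trigger phrase determines the planted
#' label; hard negatives use constraint-conformant entity pairs with a
#' neutral phrase and carry the null label. Class frequencies follow the
#' configured geometric skew, label noise (if any) is applied last, and
#' everything is seeded: the same configuration yields an identical corpus.
#'
#' @param config a [synth_config()].
#' @return List with \code{instances} (list of [relation_instance()] with
#'   splits assigned), \code{gold} (data.frame of planted positive
#'   predications, pre-noise), \code{constraints} (a [constraint_table()]),
#'   \code{lexicon} (synonym lexicon for augmentation), and \code{config}.
#' @export
make_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  tablev <- constraint_table(config$constraint_rows)
  fams <- context_families()
  lexicon <- list()
  for (fam in fams) {
    for (w in fam) lexicon[[w]] <- setdiff(fam, w)
  }
  if (config$n_sentences == 0L) {
    return(list(instances = list(),
                gold = data.frame(doc_id = character(),
                                  sentence_id = character(),
                                  subject_cui = character(),
                                  predicate = character(),
                                  object_cui = character(),
                                  stringsAsFactors = FALSE),
                constraints = tablev, lexicon = lexicon, config = config))
  }
  labs <- config$relation_labels
  w <- config$class_skew^(seq_along(labs) - 1)
  w <- w / sum(w)
  all_labs <- c(labs, null_label())
  probs <- c((1 - config$negative_fraction) * w, config$negative_fraction)

  instances <- vector("list", config$n_sentences)
  gold <- list()
  withr_seed(config$seed, {
    for (i in seq_len(config$n_sentences)) {
      lab <- sample(all_labs, 1L, prob = probs)
      if (lab == null_label()) {
        # any licensed type pair, neutral phrase
        row <- config$constraint_rows[
          sample.int(nrow(config$constraint_rows), 1L), ]
        trig <- sample(config$trigger_lexicon$no_rel, 1L)
      } else {
        cand <- config$constraint_rows[
          config$constraint_rows$predicate == lab, , drop = FALSE]
        row <- cand[sample.int(nrow(cand), 1L), ]
        trig <- sample(config$trigger_lexicon[[lab]], 1L)
      }
      subj_pool <- inventory_by_type(config$entity_inventory,
                                     row$subject_semtype)
      obj_pool <- inventory_by_type(config$entity_inventory,
                                    row$object_semtype)
      if (nrow(subj_pool) == 0L || nrow(obj_pool) == 0L) {
        stop("entity inventory does not cover semantic type ",
             row$subject_semtype, " or ", row$object_semtype, call. = FALSE)
      }
      repeat {
        subj_row <- subj_pool[sample.int(nrow(subj_pool), 1L), ]
        obj_row <- obj_pool[sample.int(nrow(obj_pool), 1L), ]
        if (subj_row$cui != obj_row$cui) break
      }
      ctx <- vapply(fams[1:3], function(f) sample(f, 1L), character(1))
      adv <- sample(fams[[6L]], 1L)
      prefix <- sprintf("In a %s %s , ", ctx[2L], ctx[3L])
      s_start <- nchar(prefix)
      mid <- sprintf("%s %s ", subj_row$name, trig)
      o_start <- s_start + nchar(mid)
      text <- sprintf("%s%s%s %s %s .", prefix, mid, obj_row$name, adv,
                      ctx[1L])
      subj <- mention_from_row(subj_row, s_start)
      obj <- mention_from_row(obj_row, o_start)
      sent <- sentence_record(sprintf("D%05d", i), "S1", text,
                              list(subj, obj))
      planted <- lab
      if (lab != null_label()) {
        gold <- c(gold, list(data.frame(
          doc_id = sent$doc_id, sentence_id = sent$sentence_id,
          subject_cui = subj$cui, predicate = lab, object_cui = obj$cui,
          stringsAsFactors = FALSE)))
      }
      if (config$label_noise > 0 &&
          stats::runif(1) < config$label_noise) {
        lab <- sample(setdiff(all_labs, lab), 1L)
      }
      split <- sample(names(config$split_fracs), 1L,
                      prob = config$split_fracs)
      instances[[i]] <- relation_instance(
        sent, subj, obj, lab,
        source = if (planted == null_label() && lab == null_label())
          "neg_conformant" else "synthetic",
        split = split)
    }
  })
  gold <- if (length(gold) == 0L) {
    data.frame(doc_id = character(), sentence_id = character(),
               subject_cui = character(), predicate = character(),
               object_cui = character(), stringsAsFactors = FALSE)
  } else do.call(rbind, gold)
  list(instances = instances, gold = gold, constraints = tablev,
       lexicon = lexicon, config = config)
}

#' Rule-oracle scorer from the trigger lexicon
#'
#' Maps an instance to a near-one-hot probability vector by looking up the
#' trigger phrase present in the sentence. On a noise-free synthetic corpus
#' this oracle is a perfect classifier (the separability guarantee behind
#' the learnability tests); in the expansion pipeline it stands in for a
#' trained model where pipeline mechanics, not learning, are under test.
#'
#' @param trigger_lexicon named list label -> phrases.
#' @param confidence probability assigned to the matched label.
#' @return Scorer function instance -> named numeric(23).
#' @export
trigger_oracle_scorer <- function(trigger_lexicon = default_trigger_lexicon(),
                                  confidence = 0.99) {
  labs <- relation_labels()
  flat <- list()
  for (lab in names(trigger_lexicon)) {
    for (ph in trigger_lexicon[[lab]]) flat[[ph]] <- lab
  }
  phrases <- names(flat)[order(-nchar(names(flat)))]  # longest match first
  function(instance) {
    text <- paste0(" ", instance$sentence$text, " ")
    hit <- null_label()
    for (ph in phrases) {
      if (grepl(paste0(" ", ph, " "), text, fixed = TRUE)) {
        hit <- flat[[ph]]
        break
      }
    }
    p <- stats::setNames(rep((1 - confidence) / (length(labs) - 1),
                             length(labs)), labs)
    p[hit] <- confidence
    p
  }
}

#' Emit SemMedDB-style tables from a synthetic corpus
#'
#' Produces the sentence, entity, predication-store and hierarchy tables
#' the expansion pipeline consumes. The store contains all planted gold
#' predications except a seeded hold-out subset (\code{planted_new}), which
#' the pipeline should rediscover; the toy hierarchy contains a child ->
#' parent edge for every planted isa predication so that planted isa
#' records survive hierarchy verification.
#'
#' @param corpus a [make_corpus()] result.
#' @param hold_out_fraction proportion of gold predications withheld from
#'   the store (count rounded half-up).
#' @param seed integer seed for the hold-out draw.
#' @return List with data.frames \code{sentences} (doc_id, sentence_id,
#'   text), \code{entities} (doc_id, sentence_id, start, end, cui, name,
#'   semtypes, semgroups), \code{store}, \code{hierarchy} (parent, child),
#'   and \code{planted_new}.
#' @export
make_semmeddb_tables <- function(corpus, hold_out_fraction = 0.3,
                                 seed = 42L) {
  if (length(corpus$instances) == 0L) stop("empty corpus", call. = FALSE)
  sent_rows <- list(); ent_rows <- list()
  for (inst in corpus$instances) {
    s <- inst$sentence
    sent_rows[[paste(s$doc_id, s$sentence_id)]] <-
      data.frame(doc_id = s$doc_id, sentence_id = s$sentence_id,
                 text = s$text, stringsAsFactors = FALSE)
    for (e in s$entities) {
      key <- paste(s$doc_id, s$sentence_id, e$start, e$end)
      ent_rows[[key]] <- data.frame(
        doc_id = s$doc_id, sentence_id = s$sentence_id, start = e$start,
        end = e$end, cui = e$cui, name = e$name,
        semtypes = paste(e$semtypes, collapse = "|"),
        semgroups = paste(e$semgroups, collapse = "|"),
        stringsAsFactors = FALSE)
    }
  }
  sentences <- do.call(rbind, unname(sent_rows))
  entities <- do.call(rbind, unname(ent_rows))
  gold <- corpus$gold
  n_hold <- round_half_up(hold_out_fraction * nrow(gold))
  hold_idx <- integer(0)
  if (n_hold > 0L) {
    hold_idx <- withr_seed(seed, sample.int(nrow(gold), n_hold))
  }
  planted_new <- gold[hold_idx, , drop = FALSE]
  store <- gold[setdiff(seq_len(nrow(gold)), hold_idx), , drop = FALSE]
  isa_gold <- gold[gold$predicate == "isa", , drop = FALSE]
  hierarchy <- if (nrow(isa_gold) > 0L) {
    unique(data.frame(parent = isa_gold$object_cui,
                      child = isa_gold$subject_cui,
                      stringsAsFactors = FALSE))
  } else {
    data.frame(parent = character(), child = character(),
               stringsAsFactors = FALSE)
  }
  rownames(planted_new) <- rownames(store) <- NULL
  list(sentences = sentences, entities = entities, store = store,
       hierarchy = hierarchy, planted_new = planted_new)
}

#' Rebuild sentence records from SemMedDB-style tables
#'
#' @param sentences data.frame (doc_id, sentence_id, text).
#' @param entities data.frame (doc_id, sentence_id, start, end, cui, name,
#'   semtypes pipe-separated, optional semgroups).
#' @return List of [sentence_record()].
#' @export
sentences_from_tables <- function(sentences, entities) {
  out <- vector("list", nrow(sentences))
  for (i in seq_len(nrow(sentences))) {
    sel <- entities$doc_id == sentences$doc_id[i] &
      entities$sentence_id == sentences$sentence_id[i]
    ents <- lapply(which(sel), function(r) {
      entity_mention(
        span_text(sentences$text[i], entities$start[r], entities$end[r]),
        entities$start[r], entities$end[r], entities$cui[r],
        entities$name[r],
        strsplit(entities$semtypes[r], "|", fixed = TRUE)[[1]],
        if ("semgroups" %in% names(entities) &&
            !is.na(entities$semgroups[r])) {
          strsplit(entities$semgroups[r], "|", fixed = TRUE)[[1]]
        } else character()
      )
    })
    out[[i]] <- sentence_record(sentences$doc_id[i],
                                sentences$sentence_id[i],
                                sentences$text[i], ents)
  }
  out
}
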