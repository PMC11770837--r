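## Corpus construction: split assignment, bidirectional expansion, negative
## generation, entity-representation substitution, and entity-marker
## insertion.

#' Reserved entity-marker tokens
#'
#' Four ASCII-safe reserved strings wrap the subject and object spans so the
#' encoder can locate the arguments. They are registered as atomic vocabulary
#' items by the tokenizer and must never occur in raw sentence text.
#'
#' @return Named character vector with elements \code{s_open}, \code{s_close},
#'   \code{o_open}, \code{o_close}.
#' @export
marker_tokens <- function() {
  c(s_open = "<s>", s_close = "</s>", o_open = "<o>", o_close = "</o>")
}

# half-up rounding; R's round() is round-half-even, which would make seeded
# sample sizes depend on parity conventions.
round_half_up <- function(x) floor(x + 0.5)

## ------------------------------------------------------------------ splits --

split_key <- function(inst) {
  paste(inst$sentence$doc_id, inst$sentence$sentence_id, sep = "|")
}

#' Assign train/val/test splits
#'
#' The fully annotated gold-standard source is split at the sentence level,
#' with 20\% of sentences (floor) for training and the remaining 80\% set
#' aside for testing; all instances of one sentence share its split. The two
#' accuracy-annotated sources are split at the instance level into 90\%
#' training and 10\% validation (floor on the validation side), each source
#' independently. Assignment is deterministic under \code{seed} and invariant
#' to the input order (inputs are canonically sorted before the seeded
#' shuffle).
#'
#' @param gs_instances list of [relation_instance()] with source \code{gs}
#'   (or negatives generated from gold-standard sentences).
#' @param acc_instances,acc_plus_instances lists of [relation_instance()].
#' @param seed integer seed.
#' @return A single list of instances with the \code{split} field set.
#' @export
assign_splits <- function(gs_instances, acc_instances = list(),
                          acc_plus_instances = list(), seed = 42L) {
  out <- list()
  withr_seed(seed, {
    if (length(gs_instances) > 0L) {
      keys <- vapply(gs_instances, split_key, character(1))
      sent <- sort(unique(keys))
      sent <- sent[sample.int(length(sent))]
      n_train <- floor(0.20 * length(sent))
      train_sent <- sent[seq_len(n_train)]
      gs <- lapply(gs_instances, function(inst) {
        inst$split <- if (split_key(inst) %in% train_sent) "train" else "test"
        inst
      })
      out <- c(out, gs)
    }
    for (src in list(acc_instances, acc_plus_instances)) {
      if (length(src) == 0L) next
      keys <- vapply(src, instance_key, character(1))
      src <- src[order(keys)]
      idx <- sample.int(length(src))
      n_val <- floor(0.10 * length(src))
      val_idx <- idx[seq_len(n_val)]
      src <- lapply(seq_along(src), function(i) {
        inst <- src[[i]]
        inst$split <- if (i %in% val_idx) "val" else "train"
        inst
      })
      out <- c(out, src)
    }
  })
  out
}

# run code under a local RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

## ---------------------------------------------------- bidirectional expand --

reverse_instance <- function(inst, new_label = inst$label) {
  relation_instance(inst$sentence, subject = inst$object,
                    object = inst$subject, label = new_label,
                    source = inst$source, split = inst$split,
                    representation = inst$representation)
}

#' Expand bidirectional and inverse relations
#'
#' Every \code{associated_with} instance gains a reversed duplicate with the
#' same label; every \code{location_of} instance gains a reversed instance
#' labeled \code{part_of} and vice versa (the inverse pair). Because
#' \code{interacts_with} is typically over-represented, only a seeded random
#' fraction (default 10\%, count rounded half-up) of its instances gain
#' reversed duplicates. Originals are always retained.
#'
#' @param instances list of [relation_instance()].
#' @param interacts_fraction proportion of \code{interacts_with} instances to
#'   reverse, in \[0, 1\].
#' @param seed integer seed for the interacts_with subsample.
#' @return The input list followed by the added reversed instances.
#' @export
expand_bidirectional <- function(instances, interacts_fraction = 0.10,
                                 seed = 42L) {
  if (interacts_fraction < 0 || interacts_fraction > 1) {
    stop("interacts_fraction must be in [0, 1]", call. = FALSE)
  }
  inv <- inverse_label_map()
  added <- list()
  labels <- vapply(instances, function(x) x$label, character(1))
  for (i in seq_along(instances)) {
    lab <- labels[i]
    if (lab == "associated_with") {
      added <- c(added, list(reverse_instance(instances[[i]])))
    } else if (lab %in% names(inv)) {
      added <- c(added, list(reverse_instance(instances[[i]], inv[[lab]])))
    }
  }
  iw <- which(labels == "interacts_with")
  if (length(iw) > 0L) {
    k <- round_half_up(interacts_fraction * length(iw))
    if (k > 0L) {
      pick <- withr_seed(seed, iw[sample.int(length(iw), k)])
      for (i in pick) added <- c(added, list(reverse_instance(instances[[i]])))
    }
  }
  c(instances, added)
}

## -------------------------------------------------------------- negatives --

triple_pair_key <- function(doc, sent, scui, ocui) {
  paste(doc, sent, scui, ocui, sep = "|")
}

triple_full_key <- function(doc, sent, scui, pred, ocui) {
  paste(doc, sent, scui, pred, ocui, sep = "|")
}

first_mention_by_cui <- function(sentence, cui) {
  for (e in sentence$entities) if (identical(e$cui, cui)) return(e)
  NULL
}

#' Generate negative (null-label) training instances
#'
#' Emits \code{no_rel} instances of two kinds: (a) source \code{neg_fp} for
#' extractor-proposed triples absent from the gold annotation (extractor
#' false positives; challenging negatives because they already satisfy the
#' extractor's semantic and syntactic constraints); and (b) source
#' \code{neg_conformant} for ordered entity pairs that have at least one
#' constraint-licensed predicate but appear in neither the gold set nor the
#' false-positive set. Pairs that carry any gold relation are never emitted
#' as negatives. Duplicates (same sentence, subject, object) are emitted once
#' with \code{neg_fp} taking precedence; an optional per-sentence cap is
#' applied after a seeded shuffle.
#'
#' @param sentences list of [sentence_record()].
#' @param gold data.frame of gold triples with columns \code{doc_id},
#'   \code{sentence_id}, \code{subject_cui}, \code{predicate},
#'   \code{object_cui}.
#' @param extractor_fp data.frame of extractor triples, same columns.
#' @param table a [constraint_table()] used to license candidate pairs.
#' @param cap_per_sentence optional integer cap on negatives per sentence.
#' @param seed integer seed (used only when capping).
#' @return List of \code{no_rel} [relation_instance()] objects.
#' @export
generate_negatives <- function(sentences, gold, extractor_fp, table,
                               cap_per_sentence = NULL, seed = 42L) {
  empty <- data.frame(doc_id = character(), sentence_id = character(),
                      subject_cui = character(), predicate = character(),
                      object_cui = character(), stringsAsFactors = FALSE)
  if (is.null(gold) || nrow(gold) == 0L) gold <- empty
  if (is.null(extractor_fp) || nrow(extractor_fp) == 0L) extractor_fp <- empty

  gold_pairs <- triple_pair_key(gold$doc_id, gold$sentence_id,
                                gold$subject_cui, gold$object_cui)
  gold_triples <- triple_full_key(gold$doc_id, gold$sentence_id,
                                  gold$subject_cui, gold$predicate,
                                  gold$object_cui)
  fp_pairs <- triple_pair_key(extractor_fp$doc_id, extractor_fp$sentence_id,
                              extractor_fp$subject_cui,
                              extractor_fp$object_cui)

  out <- list()
  for (sent in sentences) {
    seen <- character()   # pair keys already emitted for this sentence
    sent_out <- list()
    # (a) extractor false positives
    sel <- extractor_fp$doc_id == sent$doc_id &
      extractor_fp$sentence_id == sent$sentence_id
    for (r in which(sel)) {
      scui <- extractor_fp$subject_cui[r]
      ocui <- extractor_fp$object_cui[r]
      full <- triple_full_key(sent$doc_id, sent$sentence_id, scui,
                              extractor_fp$predicate[r], ocui)
      pair <- triple_pair_key(sent$doc_id, sent$sentence_id, scui, ocui)
      if (full %in% gold_triples) next       # not a false positive
      if (pair %in% gold_pairs) next         # pair has a gold relation
      if (pair %in% seen) next
      subj <- first_mention_by_cui(sent, scui)
      obj <- first_mention_by_cui(sent, ocui)
      if (is.null(subj) || is.null(obj)) next
      if (identical(subj$start, obj$start) && identical(subj$end, obj$end)) next
      seen <- c(seen, pair)
      sent_out <- c(sent_out, list(relation_instance(
        sent, subj, obj, null_label(), source = "neg_fp")))
    }
    # (b) constraint-conformant unannotated pairs
    ents <- sent$entities
    if (length(ents) >= 2L) {
      for (i in seq_along(ents)) {
        for (j in seq_along(ents)) {
          if (i == j) next
          subj <- ents[[i]]; obj <- ents[[j]]
          if (identical(subj$start, obj$start) &&
              identical(subj$end, obj$end)) next
          pair <- triple_pair_key(sent$doc_id, sent$sentence_id,
                                  subj$cui, obj$cui)
          if (pair %in% gold_pairs || pair %in% fp_pairs) next
          if (pair %in% seen) next
          if (length(licensed_predicates(subj$semtypes, obj$semtypes,
                                         table)) == 0L) next
          seen <- c(seen, pair)
          sent_out <- c(sent_out, list(relation_instance(
            sent, subj, obj, null_label(), source = "neg_conformant")))
        }
      }
    }
    if (!is.null(cap_per_sentence) && length(sent_out) > cap_per_sentence) {
      keep <- withr_seed(seed, sample.int(length(sent_out)))
      # neg_fp instances take precedence over conformant ones under the cap
      src <- vapply(sent_out, function(x) x$source, character(1))[keep]
      keep <- keep[order(src != "neg_fp")]
      sent_out <- sent_out[keep[seq_len(cap_per_sentence)]]
    }
    out <- c(out, sent_out)
  }
  out
}

## ----------------------------------------------------------- substitution --

#' Substitute the argument mentions with semantic types or groups
#'
#' In \code{semtype} (resp. \code{semgroup}) mode, the surface text of the
#' two argument mentions is replaced in the sentence by the mention's primary
#' (first-listed) semantic type (resp. group) name, and all spans are
#' recomputed. Non-argument entities are left verbatim (their spans are
#' shifted; any non-argument entity overlapping a replaced region is
#' dropped from the substituted record). \code{mention} mode returns the
#' instance unchanged apart from the representation tag.
#'
#' @param instance a [relation_instance()].
#' @param mode one of \code{mention}, \code{semtype}, \code{semgroup}.
#' @return A [relation_instance()] with the \code{representation} field set.
#' @export
substitute_representation <- function(instance,
                                      mode = c("mention", "semtype",
                                               "semgroup")) {
  mode <- match.arg(mode)
  if (mode == "mention") {
    instance$representation <- "mention"
    return(instance)
  }
  field <- if (mode == "semtype") "semtypes" else "semgroups"
  for (role in c("subject", "object")) {
    if (length(instance[[role]][[field]]) == 0L) {
      stop("instance ", role, " has no ", field,
           "; cannot substitute representation", call. = FALSE)
    }
  }
  subj <- instance$subject; obj <- instance$object
  if (!(subj$end <= obj$start || obj$end <= subj$start)) {
    stop("argument spans overlap; representation substitution requires ",
         "disjoint subject and object spans", call. = FALSE)
  }
  sent <- instance$sentence
  reps <- list(
    list(start = subj$start, end = subj$end, new = subj[[field]][1L]),
    list(start = obj$start, end = obj$end, new = obj[[field]][1L])
  )
  reps <- reps[order(vapply(reps, `[[`, integer(1), "start"))]

  text <- sent$text
  # apply right-to-left so earlier offsets stay valid
  for (r in rev(reps)) {
    text <- paste0(substr(text, 1L, r$start),
                   r$new,
                   substr(text, r$end + 1L, nchar(text)))
  }
  shift_point <- function(pos) {
    d <- 0L
    for (r in reps) {
      if (pos >= r$end) d <- d + nchar(r$new) - (r$end - r$start)
    }
    pos + d
  }
  remap_span <- function(start, end) {
    for (r in reps) {
      if (start == r$start && end == r$end) {
        ns <- shift_point(r$start)
        return(c(ns, ns + nchar(r$new)))
      }
    }
    # entity not itself replaced: keep iff disjoint from every replaced span
    for (r in reps) {
      if (!(end <= r$start || start >= r$end)) return(NULL)
    }
    c(shift_point(start), shift_point(end))
  }
  sub_entity <- function(e, is_arg) {
    sp <- remap_span(e$start, e$end)
    if (is.null(sp)) return(NULL)
    surf <- span_text(text, sp[1L], sp[2L])
    entity_mention(surf, sp[1L], sp[2L], e$cui, e$name, e$semtypes,
                   e$semgroups)
  }
  new_entities <- list()
  new_subj <- new_obj <- NULL
  for (e in sent$entities) {
    is_subj <- e$start == subj$start && e$end == subj$end
    is_obj <- e$start == obj$start && e$end == obj$end
    ne <- sub_entity(e, is_subj || is_obj)
    if (is.null(ne)) next
    new_entities <- c(new_entities, list(ne))
    if (is_subj && is.null(new_subj)) new_subj <- ne
    if (is_obj && is.null(new_obj)) new_obj <- ne
  }
  if (is.null(new_subj)) new_subj <- sub_entity(subj, TRUE)
  if (is.null(new_obj)) new_obj <- sub_entity(obj, TRUE)
  new_sent <- sentence_record(sent$doc_id, sent$sentence_id, text,
                              new_entities)
  relation_instance(new_sent, new_subj, new_obj, instance$label,
                    source = instance$source, split = instance$split,
                    representation = mode)
}

## ----------------------------------------------------------------- markers --

#' Construct a marked sequence
#'
#' A sentence with the subject and object spans wrapped in the four reserved
#' marker tokens. Invariants: each marker occurs exactly once, the two pairs
#' are properly nested or disjoint, and removing the markers reconstructs the
#' unmarked sentence text exactly.
#'
#' @param text marked sentence text.
#' @param subject_char_span,object_char_span 0-based half-open spans of the
#'   marker-enclosed regions (markers included) within \code{text}.
#' @param label relation label.
#' @param instance_id provenance key.
#' @param subject,object the argument [entity_mention()]s (as they appear in
#'   the unmarked text).
#' @param meta optional list of extra provenance fields.
#' @return An object of class \code{marked_sequence}.
#' @export
marked_sequence <- function(text, subject_char_span, object_char_span, label,
                            instance_id, subject = NULL, object = NULL,
                            meta = list()) {
  mk <- marker_tokens()
  for (m in mk) {
    n_occ <- lengths(regmatches(text, gregexpr(m, text, fixed = TRUE)))
    if (n_occ != 1L) {
      stop("marked text must contain the marker ", m, " exactly once",
           call. = FALSE)
    }
  }
  structure(
    list(text = text, subject_char_span = as.integer(subject_char_span),
         object_char_span = as.integer(object_char_span), label = label,
         instance_id = instance_id, subject = subject, object = object,
         meta = meta),
    class = "marked_sequence"
  )
}

#' Remove the four marker tokens from marked text
#' @param text marked sentence text.
#' @return The unmarked text.
#' @export
strip_markers <- function(text) {
  for (m in marker_tokens()) text <- sub(m, "", text, fixed = TRUE)
  text
}

#' Insert entity markers around the argument spans
#'
#' Wraps the subject region in the subject open/close markers and the object
#' region in the object open/close markers. Nested argument spans produce
#' correspondingly nested markers; partially overlapping or identical spans
#' are a structural error.
#'
#' @param instance a [relation_instance()].
#' @return A [marked_sequence()].
#' @export
insert_markers <- function(instance) {
  subj <- instance$subject; obj <- instance$object
  if (!spans_compatible(subj$start, subj$end, obj$start, obj$end) ||
      (subj$start == obj$start && subj$end == obj$end)) {
    stop("argument spans partially overlap or coincide", call. = FALSE)
  }
  text <- instance$sentence$text
  mk <- marker_tokens()
  for (m in mk) {
    if (grepl(m, text, fixed = TRUE)) {
      stop("sentence already contains reserved marker token ", m,
           call. = FALSE)
    }
  }
  ins <- data.frame(
    pos = c(subj$start, subj$end, obj$start, obj$end),
    str = c(mk[["s_open"]], mk[["s_close"]], mk[["o_open"]], mk[["o_close"]]),
    kind = c(1L, 0L, 1L, 0L),                     # 0 = close, 1 = open
    anchor = c(subj$end, subj$start, obj$end, obj$start),
    stringsAsFactors = FALSE
  )
  # at equal positions: closes before opens; inner close (larger start)
  # first; outer open (larger end) first
  ins <- ins[order(ins$pos, ins$kind,
                   ifelse(ins$kind == 0L, -ins$anchor, -ins$anchor)), ]
  out <- ""
  prev <- 0L
  offset <- integer(4)  # marked-text start offset of each insertion, in order
  for (k in seq_len(nrow(ins))) {
    out <- paste0(out, substr(text, prev + 1L, ins$pos[k]))
    offset[k] <- nchar(out)
    out <- paste0(out, ins$str[k])
    prev <- ins$pos[k]
  }
  out <- paste0(out, substr(text, prev + 1L, nchar(text)))
  marked_pos <- function(m) {
    i <- which(ins$str == m)
    c(offset[i], offset[i] + nchar(m))
  }
  s_span <- c(marked_pos(mk[["s_open"]])[1L], marked_pos(mk[["s_close"]])[2L])
  o_span <- c(marked_pos(mk[["o_open"]])[1L], marked_pos(mk[["o_close"]])[2L])
  marked_sequence(
    out, s_span, o_span, instance$label, instance_key(instance),
    subject = subj, object = obj,
    meta = list(doc_id = instance$sentence$doc_id,
                sentence_id = instance$sentence$sentence_id,
                source = instance$source, split = instance$split,
                representation = instance$representation)
  )
}
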