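#' Relation label schema
#'
#' The classifier predicts one of 23 labels: 22 in-scope relation types
#' produced by rule-based biomedical triple extraction, plus the null label
#' \code{no_rel} meaning that no in-scope relation holds between the entity
#' pair. Label order is fixed (alphabetical, \code{no_rel} last) so that
#' argmax tie-breaking and serialized label indices are reproducible.
#'
#' @return Character vector of length 23; \code{no_rel} is the final element.
#' @export
relation_labels <- function() {
  c(
    "administered_to", "affects", "associated_with", "augments", "causes",
    "coexists_with", "compared_with", "diagnoses", "disrupts", "inhibits",
    "interacts_with", "isa", "location_of", "part_of", "precedes",
    "predisposes", "prevents", "process_of", "produces", "stimulates",
    "treats", "uses", "no_rel"
  )
}

#' Non-null relation labels
#' @return Character vector of the 22 relation types (no null label).
#' @export
positive_labels <- function() {
  labs <- relation_labels()
  labs[labs != "no_rel"]
}

#' The null label
#' @return The string \code{"no_rel"}.
#' @export
null_label <- function() "no_rel"

#' Bidirectional relation types
#'
#' For these predicates, swapping subject and object does not change the
#' meaning (A-associated_with-B is equivalent to B-associated_with-A).
#'
#' @return Character vector of bidirectional predicate names.
#' @export
bidirectional_labels <- function() c("associated_with", "interacts_with")

#' Inverse predicate map
#'
#' \code{location_of} and \code{part_of} are inverses of each other:
#' A-location_of-B is equivalent to B-part_of-A. The map is symmetric.
#'
#' @return Named character vector mapping each predicate to its inverse.
#' @export
inverse_label_map <- function() {
  c(location_of = "part_of", part_of = "location_of")
}

#' Validate a relation label
#' @param label character scalar.
#' @param allow_null whether the null label is acceptable.
#' @return The label, invisibly, if valid; otherwise an error.
#' @keywords internal
check_label <- function(label, allow_null = TRUE) {
  ok <- relation_labels()
  if (!allow_null) ok <- positive_labels()
  if (length(label) != 1L || !label %in% ok) {
    stop("unknown relation label: ", paste(label, collapse = ","), call. = FALSE)
  }
  invisible(label)
}

## ---------------------------------------------------------------- entities --

#' Construct an entity mention
#'
#' A mention of an ontology concept inside one sentence. Character spans are
#' 0-based and half-open (the mention surface is
#' \code{substr(text, start + 1, end)}). \code{semgroups} may be derived from
#' \code{semtypes} through a type-to-group map (see [group_of()]); when
#' omitted it must be supplied before group-level substitution is possible.
#'
#' @param surface mention text as it appears in the sentence.
#' @param start,end 0-based half-open character span within the sentence.
#' @param cui opaque concept identifier string.
#' @param name preferred concept name (defaults to the surface form).
#' @param semtypes non-empty character vector of semantic-type names, ordered
#'   by preference; the first entry is the primary type.
#' @param semgroups character vector of semantic-group names, parallel in
#'   role to \code{semtypes}.
#' @return An object of class \code{entity_mention}.
#' @export
entity_mention <- function(surface, start, end, cui, name = surface,
                           semtypes, semgroups = character()) {
  if (!is.character(semtypes) || length(semtypes) == 0L) {
    stop("semtypes must be a non-empty character vector", call. = FALSE)
  }
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start >= end || start < 0L) {
    stop("invalid span [", start, ", ", end, ")", call. = FALSE)
  }
  structure(
    list(surface = surface, start = start, end = end, cui = cui, name = name,
         semtypes = semtypes, semgroups = as.character(semgroups)),
    class = "entity_mention"
  )
}

#' @export
format.entity_mention <- function(x, ...) {
  sprintf("%s:%s (%s) [%d,%d)", x$cui, x$name, x$semtypes[1], x$start, x$end)
}

#' @export
print.entity_mention <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

span_text <- function(text, start, end) substr(text, start + 1L, end)

# TRUE iff the two 0-based half-open spans are identical, disjoint or nested.
spans_compatible <- function(s1, e1, s2, e2) {
  if (s1 == s2 && e1 == e2) return(TRUE)
  if (e1 <= s2 || e2 <= s1) return(TRUE)              # disjoint
  if (s1 <= s2 && e2 <= e1) return(TRUE)              # 2 nested in 1
  if (s2 <= s1 && e1 <= e2) return(TRUE)              # 1 nested in 2
  FALSE
}

#' Construct a sentence record
#'
#' One sentence with its recognized entity mentions. Mention spans must lie
#' within the text and may not partially overlap one another (identical,
#' disjoint, or nested spans are all permitted).
#'
#' @param doc_id document identifier (PMID-like string).
#' @param sentence_id identifier unique within the document.
#' @param text the sentence string.
#' @param entities list of [entity_mention()] objects.
#' @return An object of class \code{sentence_record}.
#' @export
sentence_record <- function(doc_id, sentence_id, text, entities = list()) {
  n <- nchar(text)
  for (e in entities) {
    if (!inherits(e, "entity_mention")) {
      stop("entities must be entity_mention objects", call. = FALSE)
    }
    if (e$end > n) stop("entity span exceeds sentence length", call. = FALSE)
    if (!identical(span_text(text, e$start, e$end), e$surface)) {
      stop("entity surface does not match sentence span: ", e$surface,
           call. = FALSE)
    }
  }
  if (length(entities) > 1L) {
    for (i in seq_len(length(entities) - 1L)) {
      for (j in (i + 1L):length(entities)) {
        a <- entities[[i]]; b <- entities[[j]]
        if (!spans_compatible(a$start, a$end, b$start, b$end)) {
          stop("partially overlapping entity spans: ", a$surface, " / ",
               b$surface, call. = FALSE)
        }
      }
    }
  }
  structure(
    list(doc_id = as.character(doc_id),
         sentence_id = as.character(sentence_id),
         text = text, entities = entities),
    class = "sentence_record"
  )
}

#' Construct a relation instance
#'
#' One (sentence, subject, object, label) unit for training or evaluation.
#' Subject and object must be distinct mentions of the same sentence.
#' Negative instances (sources \code{neg_fp}, \code{neg_conformant}) must
#' carry the null label.
#'
#' @param sentence a [sentence_record()].
#' @param subject,object [entity_mention()] objects belonging to the sentence.
#' @param label a relation label (see [relation_labels()]).
#' @param source provenance: one of \code{gs}, \code{acc}, \code{acc_plus},
#'   \code{neg_fp}, \code{neg_conformant}, \code{synthetic}.
#' @param split one of \code{train}, \code{val}, \code{test}, or \code{NA}
#'   if not yet assigned.
#' @param representation one of \code{mention}, \code{semtype},
#'   \code{semgroup}.
#' @return An object of class \code{relation_instance}.
#' @export
relation_instance <- function(sentence, subject, object, label,
                              source = "synthetic", split = NA_character_,
                              representation = "mention") {
  check_label(label)
  sources <- c("gs", "acc", "acc_plus", "neg_fp", "neg_conformant", "synthetic")
  if (!source %in% sources) stop("unknown source: ", source, call. = FALSE)
  if (!is.na(split) && !split %in% c("train", "val", "test")) {
    stop("unknown split: ", split, call. = FALSE)
  }
  if (!representation %in% c("mention", "semtype", "semgroup")) {
    stop("unknown representation: ", representation, call. = FALSE)
  }
  if (identical(subject$start, object$start) &&
      identical(subject$end, object$end)) {
    stop("subject and object must be distinct mentions", call. = FALSE)
  }
  if (source %in% c("neg_fp", "neg_conformant") && label != null_label()) {
    stop("negative-source instances must be labeled ", null_label(),
         call. = FALSE)
  }
  structure(
    list(sentence = sentence, subject = subject, object = object,
         label = label, source = source, split = split,
         representation = representation),
    class = "relation_instance"
  )
}

# Stable provenance key for an instance (used for deterministic ordering).
instance_key <- function(inst) {
  paste(inst$sentence$doc_id, inst$sentence$sentence_id,
        inst$subject$start, inst$subject$end,
        inst$object$start, inst$object$end, inst$label, sep = "|")
}

## ----------------------------------------------------- constraints & groups --

#' Construct an ontological constraint table
#'
#' The set of licensed (subject semantic type, predicate, object semantic
#' type) triples. Lookup is exact on all three fields; no inference or
#' closure is performed over the table.
#'
#' @param rows data.frame with columns \code{subject_semtype},
#'   \code{predicate}, \code{object_semtype}.
#' @return An object of class \code{constraint_table}.
#' @export
constraint_table <- function(rows) {
  need <- c("subject_semtype", "predicate", "object_semtype")
  if (!all(need %in% names(rows))) {
    stop("constraint table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  rows <- unique(rows[, need, drop = FALSE])
  for (p in rows$predicate) check_label(p, allow_null = FALSE)
  rownames(rows) <- NULL
  structure(list(rows = rows), class = "constraint_table")
}

#' Read a constraint table from TSV
#'
#' Three-column tab-separated file with a header row
#' (\code{subject_semtype}, \code{predicate}, \code{object_semtype}).
#'
#' @param path file path.
#' @return A [constraint_table()].
#' @export
read_constraint_table <- function(path) {
  rows <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  constraint_table(rows)
}

#' Write a constraint table to TSV
#' @param table a [constraint_table()].
#' @param path file path.
#' @export
write_constraint_table <- function(table, path) {
  utils::write.table(table$rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Predicates licensed for a pair of semantic-type lists
#'
#' Returns the union, over every (subject type, object type) pair, of the
#' predicates the constraint table licenses for that type pair. An empty
#' result means no relation is ontologically possible for the pair.
#'
#' @param subject_types,object_types non-empty character vectors.
#' @param table a [constraint_table()].
#' @return Character vector of licensed predicates (possibly empty), in
#'   schema label order.
#' @export
licensed_predicates <- function(subject_types, object_types, table) {
  if (length(subject_types) == 0L || length(object_types) == 0L) {
    stop("semantic-type lists must be non-empty", call. = FALSE)
  }
  rows <- table$rows
  hit <- rows$subject_semtype %in% subject_types &
    rows$object_semtype %in% object_types
  preds <- unique(rows$predicate[hit])
  labs <- relation_labels()
  preds[order(match(preds, labs))]
}

#' Map a semantic type to its semantic group
#'
#' Semantic types are aggregated into coarse-grained semantic groups (for
#' example, Disease or Syndrome belongs to the Disorders group). The map is
#' supplied as data; every semantic type maps to exactly one group.
#'
#' @param semantic_type a semantic-type name.
#' @param type_group_map named character vector (names = types,
#'   values = groups), e.g. from [read_type_group_map()].
#' @return The group name (character scalar).
#' @export
group_of <- function(semantic_type, type_group_map) {
  if (!semantic_type %in% names(type_group_map)) {
    stop("semantic type not in type-group map: ", semantic_type,
         call. = FALSE)
  }
  unname(type_group_map[[semantic_type]])
}

#' Read a type-to-group map from TSV
#'
#' Two-column tab-separated file with a header row
#' (\code{semantic_type}, \code{semantic_group}).
#'
#' @param path file path.
#' @return Named character vector: names are types, values groups.
#' @export
read_type_group_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("type-group map needs two columns", call. = FALSE)
  stats::setNames(df[[2L]], df[[1L]])
}
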