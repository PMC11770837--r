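## File-format dialects and the end-to-end pipeline orchestration. All
## JSONL/TSV dialects used by the package live here: instance JSONL,
## predictions TSV, threshold TSV (thresholds.R), constraint and type-group
## TSV (schema.R), synonym lexicon TSV (augment.R), and the SemMedDB-style
## sentence/entity/store/hierarchy TSVs (synthetic.R / expansion.R).
## Everything is UTF-8.

entity_to_json <- function(e) {
  list(span = c(e$start, e$end), cui = e$cui, name = e$name,
       semtypes = as.list(e$semtypes), semgroups = as.list(e$semgroups))
}

entity_from_json <- function(x, text, line) {
  span <- unlist(x$span)
  if (length(span) != 2L) {
    stop("line ", line, ": entity span must have two elements",
         call. = FALSE)
  }
  surf <- span_text(text, span[1L], span[2L])
  entity_mention(surf, span[1L], span[2L], x$cui, x$name,
                 unlist(x$semtypes), unlist(x$semgroups))
}

#' Write relation instances to JSONL
#'
#' One JSON object per line with fields \code{doc_id}, \code{sentence_id},
#' \code{text}, \code{subject} and \code{object} (each with \code{span},
#' \code{cui}, \code{name}, \code{semtypes}, \code{semgroups}),
#' \code{label}, \code{source}, \code{split}, \code{representation}.
#'
#' @param instances list of [relation_instance()].
#' @param path output file path.
#' @export
write_instances <- function(instances, path) {
  lines <- vapply(instances, function(inst) {
    jsonlite::toJSON(list(
      doc_id = inst$sentence$doc_id,
      sentence_id = inst$sentence$sentence_id,
      text = inst$sentence$text,
      subject = entity_to_json(inst$subject),
      object = entity_to_json(inst$object),
      label = inst$label, source = inst$source,
      split = if (is.na(inst$split)) NULL else inst$split,
      representation = inst$representation
    ), auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read relation instances from JSONL
#'
#' Inverse of [write_instances()]; a malformed line, unknown label or bad
#' span raises an error naming the line.
#'
#' @param path input file path.
#' @return List of [relation_instance()].
#' @export
read_instances <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                  error = function(e) {
                    stop("line ", i, ": malformed JSON: ",
                         conditionMessage(e), call. = FALSE)
                  })
    out[[i]] <- tryCatch({
      subj <- entity_from_json(x$subject, x$text, i)
      obj <- entity_from_json(x$object, x$text, i)
      sent <- sentence_record(x$doc_id, x$sentence_id, x$text,
                              list(subj, obj))
      relation_instance(sent, subj, obj, x$label, source = x$source,
                        split = if (is.null(x$split)) NA_character_ else
                          x$split,
                        representation = x$representation)
    }, error = function(e) {
      stop("line ", i, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  out
}

#' Write a predictions table
#'
#' TSV with instance id, gold and predicted labels, and the 23 class
#' probabilities.
#'
#' @param ids,gold,pred character vectors.
#' @param probs n x 23 matrix.
#' @param path output path.
#' @export
write_predictions <- function(ids, gold, pred, probs, path) {
  df <- data.frame(instance_id = ids, gold = gold, predicted = pred,
                   stringsAsFactors = FALSE)
  pm <- as.data.frame(as.matrix(probs))
  names(pm) <- paste0("p_", relation_labels())
  utils::write.table(cbind(df, pm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a predictions table written by [write_predictions()]
#' @param path input path.
#' @return List with \code{ids}, \code{gold}, \code{pred}, \code{probs}.
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  pcols <- paste0("p_", relation_labels())
  probs <- as.matrix(df[, pcols])
  colnames(probs) <- relation_labels()
  list(ids = df$instance_id, gold = df$gold, pred = df$predicted,
       probs = probs)
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the end-to-end pipeline on a synthetic corpus
#'
#' Orchestrates the full flow: corpus generation (or reuse), backbone and
#' model training with optional contrastive pre-training, per-class
#' threshold calibration on the validation split, and evaluation on the
#' test split. Every artifact directory is stamped with the configuration
#' hash and seed; with \code{resume = TRUE} a previously written corpus is
#' reused. A stage failure halts with an error naming the stage.
#'
#' @param synth a [synth_config()] describing the corpus.
#' @param out_dir output directory (created if missing).
#' @param representation entity representation mode.
#' @param contrastive run contrastive pre-training before fine-tuning.
#' @param config a [train_config()].
#' @param aug_config an [augmentation_config()]; defaults to one built from
#'   the corpus synonym lexicon.
#' @param hidden_size,n_layers backbone dimensions.
#' @param resume reuse \code{instances.jsonl} in \code{out_dir} if present.
#' @return List with the trained \code{model}, \code{thresholds},
#'   \code{report} (an \code{eval_report}), \code{auc}, and artifact paths.
#' @export
run_pipeline <- function(synth, out_dir,
                         representation = c("mention", "semtype",
                                            "semgroup"),
                         contrastive = FALSE,
                         config = train_config(
                           learning_rate = default_backbone_lr()),
                         aug_config = NULL,
                         hidden_size = 64L, n_layers = 2L,
                         resume = FALSE) {
  representation <- match.arg(representation)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  inst_path <- file.path(out_dir, "instances.jsonl")
  corpus <- NULL
  instances <- stage("build", {
    if (resume && file.exists(inst_path)) {
      read_instances(inst_path)
    } else {
      corpus <- make_corpus(synth)
      write_instances(corpus$instances, inst_path)
      corpus$instances
    }
  })
  if (is.null(corpus)) corpus <- list(lexicon = list())
  if (is.null(aug_config)) {
    aug_config <- augmentation_config(synonym_lexicon = corpus$lexicon,
                                      seed = config$seed)
  }
  splits <- vapply(instances, function(x) x$split, character(1))

  model <- stage("train", {
    train_texts <- vapply(instances[splits == "train"], function(i) {
      insert_markers(substitute_representation(i, representation))$text
    }, character(1))
    tokenizer <- make_tokenizer(train_texts)
    backend <- tiny_backbone(tokenizer, hidden_size = hidden_size,
                             n_layers = n_layers,
                             max_length = config$max_length,
                             seed = config$seed)
    train_relation_model(instances, backend, config,
                         pretrain = contrastive, aug_config = aug_config,
                         representation = representation)
  })

  thresholds <- stage("calibrate", {
    val <- instances[splits == "val"]
    if (length(val) == 0L) stop("no validation split", call. = FALSE)
    vp <- predict_probs(model, val, representation = representation)
    # classes absent from validation default to 0.5; log once, quietly
    defaulted <- character()
    th <- withCallingHandlers(
      fit_thresholds(vp, vapply(val, function(x) x$label, character(1))),
      warning = function(w) {
        if (grepl("no positive validation instances", conditionMessage(w))) {
          defaulted <<- c(defaulted, conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      })
    if (length(defaulted) > 0L) {
      message(length(defaulted),
              " class(es) had no positive validation instances; ",
              "thresholds default to 0.5")
    }
    write_threshold_table(th, file.path(out_dir, "thresholds.tsv"))
    th
  })

  result <- stage("evaluate", {
    test <- instances[splits == "test"]
    if (length(test) == 0L) stop("no test split", call. = FALSE)
    tp <- predict_probs(model, test, representation = representation)
    gold <- vapply(test, function(x) x$label, character(1))
    pred <- apply_thresholds_matrix(tp, thresholds)
    write_predictions(rownames(tp), gold, pred, tp,
                      file.path(out_dir, "predictions.tsv"))
    auc <- if (length(unique(gold)) > 1L && !anyNA(tp[, 1L])) {
      as.numeric(auc_ovr(tp, gold))
    } else NA_real_
    list(report = prf(gold, pred), auc = auc)
  })

  run_meta <- list(seed = config$seed, representation = representation,
                   contrastive = contrastive,
                   epochs = config$epochs, batch_size = config$batch_size,
                   learning_rate = config$learning_rate,
                   hidden_size = hidden_size, n_layers = n_layers,
                   synth_seed = synth$seed,
                   n_sentences = synth$n_sentences)
  run_meta$config_hash <- config_hash(run_meta)
  report_json <- list(
    meta = run_meta,
    micro = as.list(result$report$micro),
    macro = as.list(result$report$macro),
    auc = result$auc,
    skipped = model$skipped
  )
  jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(model = model, thresholds = thresholds, report = result$report,
       auc = result$auc, out_dir = out_dir, meta = run_meta,
       paths = list(instances = inst_path,
                    thresholds = file.path(out_dir, "thresholds.tsv"),
                    predictions = file.path(out_dir, "predictions.tsv"),
                    report = file.path(out_dir, "report.json")))
}
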