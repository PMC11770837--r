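## EDA-style augmentation for contrastive pre-training: synonym replacement,
## random swap/deletion/insertion over context tokens only. The marker tokens
## and everything inside the marker-enclosed argument regions are immutable,
## because perturbing the arguments would corrupt the relation semantics the
## positive pair must preserve.

#' Augmentation configuration
#'
#' @param synonym_lexicon named list (or named character vector) mapping a
#'   lowercased token to a character vector of synonyms. May be derived from
#'   a concept synonym table; see [read_synonym_lexicon()].
#' @param p_synonym,p_swap,p_delete,p_insert per-token perturbation
#'   probabilities in \[0, 1\].
#' @param n_variants number of variants generated per sample (two variants
#'   form the positive pair for contrastive pre-training).
#' @param seed integer seed; per-sample streams are derived from it and the
#'   sample's instance id, so augmentation is reproducible and independent of
#'   processing order.
#' @return An object of class \code{augmentation_config}.
#' @export
augmentation_config <- function(synonym_lexicon = list(), p_synonym = 0.1,
                                p_swap = 0.1, p_delete = 0.1, p_insert = 0.1,
                                n_variants = 2L, seed = 42L) {
  for (p in c(p_synonym, p_swap, p_delete, p_insert)) {
    if (is.na(p) || p < 0 || p > 1) {
      stop("augmentation probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  if (n_variants < 1L) stop("n_variants must be >= 1", call. = FALSE)
  structure(
    list(synonym_lexicon = as.list(synonym_lexicon),
         p_synonym = p_synonym, p_swap = p_swap, p_delete = p_delete,
         p_insert = p_insert, n_variants = as.integer(n_variants),
         seed = as.integer(seed)),
    class = "augmentation_config"
  )
}

#' Read a synonym lexicon from TSV
#'
#' Two-column tab-separated file with a header row (\code{term},
#' \code{synonyms}); synonyms are pipe-separated.
#'
#' @param path file path.
#' @return Named list mapping term to character vector of synonyms.
#' @export
read_synonym_lexicon <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("synonym lexicon needs two columns", call. = FALSE)
  stats::setNames(strsplit(df[[2L]], "|", fixed = TRUE), df[[1L]])
}

#' Write a synonym lexicon to TSV
#' @param lexicon named list of synonym vectors.
#' @param path file path.
#' @export
write_synonym_lexicon <- function(lexicon, path) {
  df <- data.frame(term = names(lexicon),
                   synonyms = vapply(lexicon, paste, character(1),
                                     collapse = "|"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# deterministic small integer derived from a string (for per-sample seeds)
string_seed <- function(s, base) {
  codes <- utf8ToInt(s)
  h <- base %% 2147483647
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# Decompose marked text into an ordered list of segments. Protected segments
# (the marker-enclosed argument regions, merged when nested) are immutable;
# context segments are whitespace-tokenized.
segment_marked <- function(sample) {
  s <- sample$subject_char_span; o <- sample$object_char_span
  if (s[1] >= o[1] && s[2] <= o[2]) {
    prot <- list(o)
  } else if (o[1] >= s[1] && o[2] <= s[2]) {
    prot <- list(s)
  } else if (s[1] < o[1]) {
    prot <- list(s, o)
  } else {
    prot <- list(o, s)
  }
  segs <- list()
  pos <- 0L
  text <- sample$text
  for (p in prot) {
    if (p[1] > pos) {
      segs <- c(segs, list(list(kind = "context",
                                text = substr(text, pos + 1L, p[1]))))
    }
    segs <- c(segs, list(list(kind = "protected",
                              text = substr(text, p[1] + 1L, p[2]))))
    pos <- p[2]
  }
  if (pos < nchar(text)) {
    segs <- c(segs, list(list(kind = "context",
                              text = substr(text, pos + 1L, nchar(text)))))
  }
  segs
}

ws_tokens <- function(x) {
  t <- strsplit(trimws(x), "\\s+")[[1]]
  t[nzchar(t)]
}

#' Generate augmentation variants of a marked sequence
#'
#' Applies EDA-style perturbations (synonym replacement, random swap,
#' deletion, insertion) to context tokens only; the marker tokens and the
#' tokens inside the argument regions are never touched, so every variant is
#' a valid marked sequence with unchanged label and argument concepts.
#' Deterministic under the configuration seed. A sample with no perturbable
#' context is returned verbatim.
#'
#' @param sample a [marked_sequence()].
#' @param config an [augmentation_config()].
#' @return List of \code{n_variants} [marked_sequence()] objects; each
#'   carries \code{meta$origin} identifying the source sample.
#' @export
augment <- function(sample, config) {
  segs <- segment_marked(sample)
  out <- vector("list", config$n_variants)
  for (v in seq_len(config$n_variants)) {
    seed_v <- string_seed(paste0(sample$instance_id, "#", v), config$seed)
    out[[v]] <- withr_seed(seed_v, augment_once(sample, segs, config))
    out[[v]]$meta$origin <- sample$instance_id
    out[[v]]$meta$variant <- v
  }
  out
}

augment_once <- function(x, segs, config) {
  # flatten context tokens with segment membership
  tok <- list()   # each: list(seg, text)
  for (i in seq_along(segs)) {
    if (segs[[i]]$kind != "context") next
    for (w in ws_tokens(segs[[i]]$text)) {
      tok <- c(tok, list(list(seg = i, text = w, alive = TRUE)))
    }
  }
  changed <- FALSE
  n <- length(tok)
  lex <- config$synonym_lexicon
  if (n > 0L) {
    # synonym replacement
    for (i in seq_len(n)) {
      key <- tolower(tok[[i]]$text)
      if (!is.null(lex[[key]]) && length(lex[[key]]) > 0L &&
          stats::runif(1) < config$p_synonym) {
        tok[[i]]$text <- sample(lex[[key]], 1L)
        changed <- TRUE
      }
    }
    # random swap (within the context tokens, across segments)
    if (n >= 2L) {
      for (i in seq_len(n)) {
        if (stats::runif(1) < config$p_swap) {
          j <- sample(setdiff(seq_len(n), i), 1L)
          tmp <- tok[[i]]$text; tok[[i]]$text <- tok[[j]]$text
          tok[[j]]$text <- tmp
          changed <- TRUE
        }
      }
    }
    # random deletion
    for (i in seq_len(n)) {
      if (stats::runif(1) < config$p_delete) {
        tok[[i]]$alive <- FALSE
        changed <- TRUE
      }
    }
    # random insertion: a synonym of a random context token, after position i
    inserts <- list()
    if (length(lex) > 0L) {
      for (i in seq_len(n)) {
        if (stats::runif(1) < config$p_insert) {
          src <- tok[[sample(n, 1L)]]$text
          syn <- lex[[tolower(src)]]
          if (is.null(syn) || length(syn) == 0L) next
          inserts <- c(inserts, list(list(after = i,
                                          seg = tok[[i]]$seg,
                                          text = sample(syn, 1L))))
          changed <- TRUE
        }
      }
    }
    if (length(inserts) > 0L) {
      for (ins in rev(inserts)) {
        tok <- append(tok, list(list(seg = ins$seg, text = ins$text,
                                     alive = TRUE)),
                      after = ins$after)
      }
    }
  }
  if (!changed) {
    res <- x
    return(res)
  }
  # reassemble: single spaces between pieces, protected segments verbatim
  pieces <- character()
  kinds <- character()
  for (i in seq_along(segs)) {
    if (segs[[i]]$kind == "protected") {
      pieces <- c(pieces, segs[[i]]$text)
      kinds <- c(kinds, "protected")
    } else {
      words <- vapply(Filter(function(t) t$seg == i && t$alive, tok),
                      `[[`, character(1), "text")
      if (length(words) > 0L) {
        pieces <- c(pieces, paste(words, collapse = " "))
        kinds <- c(kinds, "context")
      }
    }
  }
  text <- paste(pieces, collapse = " ")
  # locate protected regions in the rebuilt text
  prot_idx <- which(kinds == "protected")
  starts <- integer(length(pieces))
  pos <- 0L
  for (i in seq_along(pieces)) {
    starts[i] <- pos
    pos <- pos + nchar(pieces[i]) + 1L   # + joining space
  }
  prot_spans <- lapply(prot_idx, function(i) {
    c(starts[i], starts[i] + nchar(pieces[i]))
  })
  # map protected spans back to subject/object spans
  s <- x$subject_char_span; o <- x$object_char_span
  if (length(prot_spans) == 1L) {
    outer <- prot_spans[[1L]]
    if (s[1] >= o[1] && s[2] <= o[2]) {   # subject nested in object
      d <- outer[1] - o[1]
      o_span <- outer
      s_span <- s + d
    } else {
      d <- outer[1] - s[1]
      s_span <- outer
      o_span <- o + d
    }
  } else {
    if (s[1] < o[1]) {
      s_span <- prot_spans[[1L]]; o_span <- prot_spans[[2L]]
    } else {
      o_span <- prot_spans[[1L]]; s_span <- prot_spans[[2L]]
    }
  }
  marked_sequence(text, s_span, o_span, x$label, x$instance_id,
                  subject = x$subject, object = x$object,
                  meta = x$meta)
}

#' Build contrastive pre-training batches
#'
#' For each batch of \code{batch_size} source samples, generates the first
#' two augmentation variants of every source; the two variants of one source
#' form the positive pair and all sequences from other sources in the batch
#' act as negatives. The final ragged batch is kept if it has at least two
#' sources (a single source has no negatives) and dropped otherwise.
#'
#' @param samples list of [marked_sequence()].
#' @param batch_size number of source samples per batch (>= 2).
#' @param config an [augmentation_config()] (\code{n_variants} >= 2).
#' @param shuffle whether to shuffle the sources (seeded by
#'   \code{config$seed}) before batching.
#' @return List of batches; each batch is a list with \code{sequences}
#'   (2N marked sequences) and \code{origins} (length-2N character vector).
#' @export
build_contrastive_batches <- function(samples, batch_size = 16L, config,
                                      shuffle = TRUE) {
  if (batch_size < 2L) stop("batch_size must be >= 2", call. = FALSE)
  if (config$n_variants < 2L) {
    stop("contrastive batches need n_variants >= 2", call. = FALSE)
  }
  if (length(samples) < 2L) return(list())
  idx <- seq_along(samples)
  if (shuffle) idx <- withr_seed(config$seed, sample(idx))
  batches <- split(idx, ceiling(seq_along(idx) / batch_size))
  out <- list()
  for (b in batches) {
    if (length(b) < 2L) next
    seqs <- list(); origins <- character()
    for (i in b) {
      vs <- augment(samples[[i]], config)
      seqs <- c(seqs, vs[1:2])
      origins <- c(origins,
                   rep(samples[[i]]$instance_id, 2L))
    }
    out <- c(out, list(list(sequences = seqs, origins = origins)))
  }
  out
}
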