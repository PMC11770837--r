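## Encoder backend: tokenizer with atomic marker tokens, and a small
## trainable sequence encoder written in plain matrix code (token + position
## embeddings followed by stacked context-mixing tanh layers with manual
## backpropagation). The backend satisfies the encoder contract used by the
## training loop: tokenize text with the four marker tokens atomic, reject
## sequences longer than max_length, and return per-token vectors from the
## last layer plus a sentence-summary vector. A large pretrained biomedical
## transformer can implement the same contract; the built-in backbone is a
## small randomly initialized network so the whole package runs end-to-end
## with no downloads.

#' Tokenize text with atomic marker tokens
#'
#' Splits out the four reserved marker tokens as atomic items, lowercases
#' the remaining text, separates common punctuation, and splits on
#' whitespace.
#'
#' @param text character scalar.
#' @return Character vector of tokens.
#' @export
tokenize_text <- function(text) {
  mk <- unname(marker_tokens())
  segs <- list(list(text = text, marker = FALSE))
  for (m in mk) {
    new <- list()
    for (s in segs) {
      if (s$marker) { new <- c(new, list(s)); next }
      parts <- strsplit(s$text, m, fixed = TRUE)[[1]]
      if (length(parts) == 0L) parts <- ""
      ends_with <- endsWith(s$text, m)
      for (i in seq_along(parts)) {
        new <- c(new, list(list(text = parts[i], marker = FALSE)))
        if (i < length(parts) || ends_with) {
          new <- c(new, list(list(text = m, marker = TRUE)))
        }
      }
    }
    segs <- new
  }
  out <- character()
  for (s in segs) {
    if (s$marker) {
      out <- c(out, s$text)
    } else {
      t <- tolower(s$text)
      t <- gsub("[.,;:!?\"()\\[\\]]", " ", t, perl = TRUE)
      out <- c(out, ws_tokens(t))
    }
  }
  out
}

#' Build a whitespace tokenizer with a fixed vocabulary
#'
#' The vocabulary is collected from the supplied texts; the four marker
#' tokens are always registered as atomic vocabulary items, and unknown
#' tokens at encoding time map to a reserved \code{<unk>} item.
#'
#' @param texts character vector of (marked or unmarked) training texts.
#' @return An object of class \code{marker_tokenizer}.
#' @export
make_tokenizer <- function(texts) {
  toks <- unique(unlist(lapply(texts, tokenize_text)))
  vocab <- unique(c("<unk>", unname(marker_tokens()), toks))
  structure(
    list(vocab = vocab, index = stats::setNames(seq_along(vocab), vocab)),
    class = "marker_tokenizer"
  )
}

#' Encode text to token ids
#' @param tokenizer a [make_tokenizer()] object.
#' @param text character scalar.
#' @return List with \code{tokens} (character) and \code{ids} (integer;
#'   unknown tokens map to the \code{<unk>} id).
#' @export
encode_tokens <- function(tokenizer, text) {
  tokens <- tokenize_text(text)
  ids <- unname(tokenizer$index[tokens])
  ids[is.na(ids)] <- tokenizer$index[["<unk>"]]
  list(tokens = tokens, ids = as.integer(ids))
}

## ----------------------------------------------------------- test backbone --

glorot <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

#' Construct the small trainable encoder backbone
#'
#' A deliberately small sequence encoder satisfying the encoder contract:
#' token and position embeddings followed by \code{n_layers} context-mixing
#' layers, each computing \code{tanh(H W1 + mean(H) W2 + b)} so every token
#' vector sees both its own content and the sentence context. The last
#' layer's token vectors are the sequence output; their mean is the
#' sentence-summary vector. All parameters are seeded; evaluation-mode
#' outputs are deterministic.
#'
#' @param tokenizer a [make_tokenizer()] object (fixes the vocabulary).
#' @param hidden_size embedding and hidden dimension (default 64).
#' @param n_layers number of mixing layers (default 2).
#' @param max_length maximum tokenized sequence length; longer sequences are
#'   rejected before encoding (default 384).
#' @param seed integer seed for parameter initialization.
#' @return An object of class \code{encoder_backend} holding the tokenizer,
#'   dimensions and initial parameters.
#' @export
tiny_backbone <- function(tokenizer, hidden_size = 64L, n_layers = 2L,
                          max_length = 384L, seed = 1L) {
  d <- as.integer(hidden_size)
  V <- length(tokenizer$vocab)
  params <- withr_seed(seed, {
    layers <- lapply(seq_len(n_layers), function(l) {
      list(W1 = glorot(d, d), W2 = glorot(d, d), b = numeric(d))
    })
    list(emb = matrix(stats::rnorm(V * d, sd = 0.1), V, d),
         pos = matrix(stats::rnorm(max_length * d, sd = 0.02), max_length, d),
         layers = layers)
  })
  structure(
    list(tokenizer = tokenizer, hidden_size = d, n_layers = n_layers,
         max_length = as.integer(max_length), seed = as.integer(seed),
         params = params),
    class = "encoder_backend"
  )
}

# forward pass through the backbone; returns token vectors, summary, and a
# cache for backpropagation
backbone_forward <- function(params, ids, max_length) {
  T_ <- length(ids)
  H <- params$emb[ids, , drop = FALSE] + params$pos[seq_len(T_), , drop = FALSE]
  cache <- list(ids = ids, H = list(H))
  for (l in seq_along(params$layers)) {
    ly <- params$layers[[l]]
    M <- colMeans(H)
    A <- H %*% ly$W1 +
      matrix(M %*% ly$W2, T_, ncol(H), byrow = TRUE) +
      matrix(ly$b, T_, ncol(H), byrow = TRUE)
    H <- tanh(A)
    cache$H[[l + 1L]] <- H
  }
  list(tokens = H, summary = colMeans(H), cache = cache)
}

# backward pass; dH is the gradient w.r.t. the final token matrix and
# dsummary w.r.t. the summary vector. Returns gradients in the same shape as
# params.
backbone_backward <- function(params, cache, dH, dsummary) {
  T_ <- length(cache$ids)
  d <- ncol(dH)
  if (!is.null(dsummary)) {
    dH <- dH + matrix(dsummary / T_, T_, d, byrow = TRUE)
  }
  g_layers <- vector("list", length(params$layers))
  for (l in rev(seq_along(params$layers))) {
    ly <- params$layers[[l]]
    H_out <- cache$H[[l + 1L]]
    H_in <- cache$H[[l]]
    dZ <- dH * (1 - H_out^2)
    csum <- colSums(dZ)
    M_in <- colMeans(H_in)
    # every row of the pre-activation receives M_in %*% W2, so
    # dW2 = M_in^T (colSums dZ)
    g_layers[[l]] <- list(W1 = crossprod(H_in, dZ),
                          W2 = outer(M_in, csum),
                          b = csum)
    dM <- as.numeric(csum %*% t(ly$W2))
    dH <- dZ %*% t(ly$W1) + matrix(dM / T_, T_, d, byrow = TRUE)
  }
  # dH is now the gradient w.r.t. emb[ids,] + pos[1:T,]
  demb <- matrix(0, nrow(params$emb), d)
  agg <- rowsum(dH, group = cache$ids)
  demb[as.integer(rownames(agg)), ] <- agg
  dpos <- matrix(0, nrow(params$pos), d)
  dpos[seq_len(T_), ] <- dH
  list(emb = demb, pos = dpos, layers = g_layers)
}

#' Tokenize and locate the argument regions of a marked sequence
#'
#' Tokenizes a marked sequence with the backend's tokenizer and locates the
#' marker-enclosed subject and object token spans (marker tokens included,
#' so each span has length at least 3). Sequences whose tokenization exceeds
#' the backend's maximum length are rejected with a classed condition
#' (\code{relclass_seq_too_long}); callers exclude, count and report such
#' samples.
#'
#' @param sample a [marked_sequence()].
#' @param backend an \code{encoder_backend}.
#' @return List with \code{tokens}, \code{ids}, \code{subject_span} and
#'   \code{object_span} (inclusive token index ranges).
#' @export
tokenize_sample <- function(sample, backend) {
  enc <- encode_tokens(backend$tokenizer, sample$text)
  if (length(enc$ids) > backend$max_length) {
    stop(structure(
      class = c("relclass_seq_too_long", "error", "condition"),
      list(message = sprintf(
        "tokenized length %d exceeds max_length %d (instance %s)",
        length(enc$ids), backend$max_length, sample$instance_id),
        call = NULL)
    ))
  }
  mk <- marker_tokens()
  pos1 <- function(tok) {
    w <- which(enc$tokens == tok)
    if (length(w) != 1L) {
      stop("marker token ", tok, " must appear exactly once after ",
           "tokenization (markers must be atomic)", call. = FALSE)
    }
    w
  }
  s_span <- c(pos1(mk[["s_open"]]), pos1(mk[["s_close"]]))
  o_span <- c(pos1(mk[["o_open"]]), pos1(mk[["o_close"]]))
  if (s_span[2] - s_span[1] < 2L || o_span[2] - o_span[1] < 2L) {
    stop("argument region must contain at least one token between markers",
         call. = FALSE)
  }
  list(tokens = enc$tokens, ids = enc$ids,
       subject_span = s_span, object_span = o_span)
}

#' Encode a marked sequence with a backend
#'
#' Runs the backend over the tokenized sample and returns the last-layer
#' token vectors, the sentence-summary vector, and the subject/object token
#' spans (marker tokens included).
#'
#' @param sample a [marked_sequence()].
#' @param backend an \code{encoder_backend}.
#' @param params optional parameter list overriding \code{backend$params}
#'   (used during training).
#' @return List with \code{tokens} (T x d matrix), \code{summary} (length-d
#'   vector), \code{subject_span}, \code{object_span}, and \code{cache}.
#' @export
encode_sample <- function(sample, backend, params = backend$params) {
  tk <- tokenize_sample(sample, backend)
  fw <- backbone_forward(params, tk$ids, backend$max_length)
  list(tokens = fw$tokens, summary = fw$summary,
       subject_span = tk$subject_span, object_span = tk$object_span,
       cache = fw$cache)
}

#' Mean-pool token vectors over a span
#'
#' Arithmetic mean of the token vectors across an inclusive token index
#' range; the entity position markers are part of the span and are included
#' in the mean.
#'
#' @param token_vectors T x d matrix of token vectors.
#' @param span inclusive integer range \code{c(first, last)}.
#' @return Length-d vector.
#' @export
pool_entity <- function(token_vectors, span) {
  if (length(span) != 2L || span[1] > span[2]) {
    stop("span must be a non-empty inclusive range", call. = FALSE)
  }
  colMeans(token_vectors[span[1]:span[2], , drop = FALSE])
}
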