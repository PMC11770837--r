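## Relation classification model: projection head for contrastive
## pre-training, classification head over (sentence summary, mean-pooled
## subject, mean-pooled object), temperature-scaled cosine contrastive loss,
## batch class weighting, and the Adam training loop. All gradients are
## written out analytically; no automatic differentiation is used.

#' Training configuration
#'
#' Defaults follow the reference experimental settings: 10 epochs for both
#' pre-training and fine-tuning, batch size 16, maximum sequence length 384,
#' Adam with learning rate 5e-5 and epsilon 1e-8, contrastive temperature
#' 0.1. The 5e-5 rate is the convention for fine-tuning a large pretrained
#' encoder; when training the small built-in backbone from random
#' initialization a larger rate (1e-3) is the appropriate choice and is used
#' by [default_backbone_lr()].
#'
#' @param epochs number of passes over the training data.
#' @param batch_size supervised (and contrastive source) batch size.
#' @param max_length maximum tokenized sequence length.
#' @param learning_rate Adam step size.
#' @param adam_epsilon Adam denominator stabilizer.
#' @param temperature contrastive softmax temperature (> 0).
#' @param dropout dropout rate for all head layers.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(epochs = 10L, batch_size = 16L, max_length = 384L,
                         learning_rate = 5e-5, adam_epsilon = 1e-8,
                         temperature = 0.1, dropout = 0.1, seed = 42L) {
  stopifnot(epochs >= 0, batch_size >= 1, max_length >= 1,
            learning_rate > 0, adam_epsilon > 0, temperature > 0,
            dropout >= 0, dropout < 1)
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         max_length = as.integer(max_length),
         learning_rate = learning_rate, adam_epsilon = adam_epsilon,
         temperature = temperature, dropout = dropout,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Learning rate recommended for the built-in small backbone
#' @return Numeric scalar (1e-3).
#' @export
default_backbone_lr <- function() 1e-3

## ------------------------------------------------------- contrastive loss --

#' Temperature-scaled cosine contrastive loss
#'
#' For a batch of 2N projected vectors in which each vector has exactly one
#' positive partner (the other augmentation variant of the same source), the
#' per-anchor loss is
#' \deqn{-\log \frac{\exp(\mathrm{sim}(z', z'')/\tau)}
#'                  {\sum_{k \ne \mathrm{anchor}} \exp(\mathrm{sim}(z', z_k)/\tau)}}
#' with cosine similarity and temperature \eqn{\tau}; the batch loss is the
#' mean over all 2N anchors. The denominator excludes the anchor by index
#' (identity, not value, comparison), so duplicate vectors are handled
#' correctly. With a single pair (N = 1) the numerator equals the
#' denominator and the loss is exactly 0.
#'
#' @param embeddings 2N x k matrix of projected vectors.
#' @param origins length-2N vector; vectors sharing an origin are the
#'   positive pair (each origin must appear exactly twice).
#' @param temperature positive scalar.
#' @param grad if \code{TRUE}, also return the gradient w.r.t.
#'   \code{embeddings}.
#' @return The scalar loss, or (with \code{grad}) a list with \code{loss}
#'   and \code{grad}.
#' @export
contrastive_loss <- function(embeddings, origins, temperature = 0.1,
                             grad = FALSE) {
  Z <- as.matrix(embeddings)
  n <- nrow(Z)
  if (n %% 2L != 0L || n < 2L) {
    stop("contrastive batch must contain an even number (>= 2) of vectors",
         call. = FALSE)
  }
  tab <- table(origins)
  if (any(tab != 2L)) {
    stop("every origin must appear exactly twice", call. = FALSE)
  }
  partner <- integer(n)
  for (i in seq_len(n)) {
    partner[i] <- setdiff(which(origins == origins[i]), i)
  }
  norms <- sqrt(rowSums(Z^2))
  if (any(norms == 0)) stop("zero-norm embedding vector", call. = FALSE)
  S <- (Z %*% t(Z)) / outer(norms, norms)
  S <- pmin(pmax(S, -1), 1)
  E <- exp(S / temperature)
  loss_i <- numeric(n)
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) {
    denom <- sum(E[i, -i])
    loss_i[i] <- -S[i, partner[i]] / temperature + log(denom)
    Q[i, -i] <- E[i, -i] / denom
  }
  loss <- mean(loss_i)
  if (!grad) return(loss)
  # dL/dS[i,j] (j != i) = (Q[i,j] - 1[j == partner(i)]) / (n * temperature)
  dS <- Q
  for (i in seq_len(n)) dS[i, partner[i]] <- dS[i, partner[i]] - 1
  dS <- dS / (n * temperature)
  dZ <- matrix(0, n, ncol(Z))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || dS[i, j] == 0) next
      g <- dS[i, j]
      dZ[i, ] <- dZ[i, ] + g * (Z[j, ] / (norms[i] * norms[j]) -
                                  S[i, j] * Z[i, ] / norms[i]^2)
      dZ[j, ] <- dZ[j, ] + g * (Z[i, ] / (norms[i] * norms[j]) -
                                  S[i, j] * Z[j, ] / norms[j]^2)
    }
  }
  list(loss = loss, grad = dZ)
}

## ------------------------------------------------------------ class weights --

#' Balanced per-batch class weights
#'
#' For each class present in the batch, \eqn{w_c = B / (C \cdot n_c)} where
#' \eqn{B} is the batch size, \eqn{C} the number of distinct classes present
#' and \eqn{n_c} the count of class \eqn{c}; classes absent from the batch
#' get weight 0. Rarer classes receive strictly larger weights, mitigating
#' class imbalance in the weighted cross-entropy loss.
#'
#' @param labels character vector of labels in the batch (non-empty).
#' @return Named numeric vector over [relation_labels()].
#' @export
batch_class_weights <- function(labels) {
  if (length(labels) == 0L) stop("empty batch", call. = FALSE)
  labs <- relation_labels()
  w <- stats::setNames(numeric(length(labs)), labs)
  tab <- table(labels)
  B <- length(labels)
  C <- length(tab)
  w[names(tab)] <- B / (C * as.numeric(tab))
  w
}

## ------------------------------------------------------------------- heads --

init_heads <- function(d, k, n_labels, seed) {
  withr_seed(seed, {
    branch <- function() {
      list(W = glorot(d, k), b = numeric(k),
           g = rep(1, k), be = numeric(k))
    }
    list(
      proj = list(W = glorot(d, k), b = numeric(k)),
      cls = branch(), subj = branch(), obj = branch(),
      out = list(W = glorot(3L * k, n_labels), b = numeric(n_labels))
    )
  })
}

LN_EPS <- 1e-5

layer_norm_forward <- function(a, g, be) {
  mu <- mean(a)
  v <- mean((a - mu)^2)
  xhat <- (a - mu) / sqrt(v + LN_EPS)
  list(y = g * xhat + be, xhat = xhat, inv = 1 / sqrt(v + LN_EPS))
}

layer_norm_backward <- function(dy, g, cache) {
  k <- length(dy)
  dxhat <- dy * g
  dx <- cache$inv * (dxhat - mean(dxhat) - cache$xhat * mean(dxhat * cache$xhat))
  list(dx = dx, dg = dy * cache$xhat, dbe = dy)
}

# one classifier branch: dropout -> linear -> tanh -> layer norm
branch_forward <- function(x, p, dropout_mask = NULL) {
  xd <- if (is.null(dropout_mask)) x else x * dropout_mask
  a <- as.numeric(xd %*% p$W) + p$b
  h <- tanh(a)
  ln <- layer_norm_forward(h, p$g, p$be)
  list(y = ln$y, x = x, xd = xd, h = h, ln = ln, mask = dropout_mask)
}

branch_backward <- function(dy, p, cache) {
  lb <- layer_norm_backward(dy, p$g, cache$ln)
  da <- lb$dx * (1 - cache$h^2)
  dW <- outer(as.numeric(cache$xd), da)
  dxd <- as.numeric(p$W %*% da)
  dx <- if (is.null(cache$mask)) dxd else dxd * cache$mask
  list(dx = dx, grads = list(W = dW, b = da, g = lb$dg, dbe = lb$dbe))
}

#' Classify one encoded sample
#'
#' Passes the sentence-summary vector and the mean-pooled subject and object
#' vectors through three independent transforms (linear, dropout, tanh,
#' layer normalization), concatenates the three results, and maps the
#' concatenation to 23 label scores, normalized by softmax.
#'
#' @param sentence_vec,subject_vec,object_vec length-d input vectors.
#' @param head parameter list as produced inside [new_relation_model()].
#' @return Named probability vector over [relation_labels()] (sums to 1).
#' @export
classify <- function(sentence_vec, subject_vec, object_vec, head) {
  d <- nrow(head$cls$W)
  if (length(sentence_vec) != d || length(subject_vec) != d ||
      length(object_vec) != d) {
    stop("input vector dimension does not match the classifier head",
         call. = FALSE)
  }
  fw <- classifier_forward(sentence_vec, subject_vec, object_vec, head,
                           dropout = 0, train = FALSE)
  fw$probs
}

classifier_forward <- function(cls_vec, subj_vec, obj_vec, head,
                               dropout = 0, train = FALSE) {
  mk_mask <- function(d) {
    if (!train || dropout <= 0) return(NULL)
    (stats::runif(d) >= dropout) / (1 - dropout)
  }
  d <- length(cls_vec)
  b_cls <- branch_forward(cls_vec, head$cls, mk_mask(d))
  b_subj <- branch_forward(subj_vec, head$subj, mk_mask(d))
  b_obj <- branch_forward(obj_vec, head$obj, mk_mask(d))
  u <- c(b_cls$y, b_subj$y, b_obj$y)
  logits <- as.numeric(u %*% head$out$W) + head$out$b
  z <- logits - max(logits)
  p <- exp(z) / sum(exp(z))
  names(p) <- relation_labels()[seq_along(p)]
  list(probs = p, logits = logits, u = u,
       b_cls = b_cls, b_subj = b_subj, b_obj = b_obj)
}

classifier_backward <- function(dlogits, head, cache) {
  k <- length(cache$b_cls$y)
  dW_out <- outer(cache$u, dlogits)
  du <- as.numeric(head$out$W %*% dlogits)
  g_cls <- branch_backward(du[seq_len(k)], head$cls, cache$b_cls)
  g_subj <- branch_backward(du[k + seq_len(k)], head$subj, cache$b_subj)
  g_obj <- branch_backward(du[2L * k + seq_len(k)], head$obj, cache$b_obj)
  reshape <- function(g) list(W = g$grads$W, b = g$grads$b,
                              g = g$grads$g, be = g$grads$dbe)
  list(
    grads = list(cls = reshape(g_cls), subj = reshape(g_subj),
                 obj = reshape(g_obj),
                 out = list(W = dW_out, b = dlogits)),
    d_cls = g_cls$dx, d_subj = g_subj$dx, d_obj = g_obj$dx
  )
}

projection_forward <- function(x, proj, dropout = 0, train = FALSE) {
  mask <- if (train && dropout > 0) {
    (stats::runif(length(x)) >= dropout) / (1 - dropout)
  } else NULL
  xd <- if (is.null(mask)) x else x * mask
  a <- as.numeric(xd %*% proj$W) + proj$b
  z <- tanh(a)
  list(z = z, a = a, xd = xd, x = x, mask = mask)
}

projection_backward <- function(dz, proj, cache) {
  da <- dz * (1 - tanh(cache$a)^2)
  dW <- outer(as.numeric(cache$xd), da)
  dxd <- as.numeric(proj$W %*% da)
  dx <- if (is.null(cache$mask)) dxd else dxd * cache$mask
  list(dx = dx, grads = list(W = dW, b = da))
}

## -------------------------------------------------------------------- adam --

tree_map <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) {
      out[[i]] <- tree_map(f, a[[i]], if (is.null(b)) NULL else b[[i]])
    }
    out
  } else {
    if (is.null(b)) f(a) else f(a, b)
  }
}

zeros_like <- function(p) tree_map(function(x) x * 0, p)

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, eps, beta1 = 0.9,
                      beta2 = 0.999) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                  state$m, state$v)
  params <- tree_map(`-`, params, upd)
  list(params = params, state = state)
}

add_trees <- function(a, b) tree_map(`+`, a, b)

## ------------------------------------------------------------------- model --

#' Initialize a relation classification model
#'
#' Couples an encoder backend with a projection head (used only during
#' contrastive pre-training and discarded afterwards) and the three-branch
#' classifier head mapping to the 23 labels.
#'
#' @param backend an \code{encoder_backend} (see [tiny_backbone()]).
#' @param head_dim width of the head branches (default: the backbone hidden
#'   size).
#' @param seed integer seed for head initialization.
#' @return An object of class \code{relation_model}.
#' @export
new_relation_model <- function(backend, head_dim = backend$hidden_size,
                               seed = 1L) {
  heads <- init_heads(backend$hidden_size, head_dim,
                      length(relation_labels()), seed)
  structure(
    list(backend = backend,
         params = c(list(backbone = backend$params), heads),
         label_order = relation_labels(),
         skipped = 0L),
    class = "relation_model"
  )
}

# forward + loss + gradients for one supervised sample
supervised_sample_pass <- function(params, backend, tk, label_idx, weight,
                                   dropout, train = TRUE, grad = TRUE) {
  fw <- backbone_forward(params$backbone, tk$ids, backend$max_length)
  subj_vec <- pool_entity(fw$tokens, tk$subject_span)
  obj_vec <- pool_entity(fw$tokens, tk$object_span)
  cf <- classifier_forward(fw$summary, subj_vec, obj_vec, params,
                           dropout = dropout, train = train)
  p <- cf$probs
  loss <- -weight * log(max(p[label_idx], 1e-12))
  if (!grad) return(list(loss = loss, probs = p))
  dlogits <- weight * p
  dlogits[label_idx] <- dlogits[label_idx] - weight
  cb <- classifier_backward(dlogits, params, cf)
  # distribute pooled-entity gradients back over token rows
  T_ <- length(tk$ids)
  dH <- matrix(0, T_, backend$hidden_size)
  s_idx <- tk$subject_span[1]:tk$subject_span[2]
  o_idx <- tk$object_span[1]:tk$object_span[2]
  dH[s_idx, ] <- dH[s_idx, ] +
    matrix(cb$d_subj / length(s_idx), length(s_idx),
           backend$hidden_size, byrow = TRUE)
  dH[o_idx, ] <- dH[o_idx, ] +
    matrix(cb$d_obj / length(o_idx), length(o_idx),
           backend$hidden_size, byrow = TRUE)
  g_backbone <- backbone_backward(params$backbone, fw$cache, dH, cb$d_cls)
  grads <- list(backbone = g_backbone, proj = zeros_like(params$proj),
                cls = cb$grads$cls, subj = cb$grads$subj,
                obj = cb$grads$obj, out = cb$grads$out)
  list(loss = loss, probs = p, grads = grads)
}

#' Train a relation classification model
#'
#' Optionally runs contrastive pre-training on augmentation-generated
#' positive pairs from the training split (the projection head is used only
#' here and discarded afterwards), then fine-tunes with class-weighted
#' cross-entropy over the 23 labels. Both stages use Adam and are fully
#' seeded; per-epoch mean losses are recorded. Samples whose tokenization
#' exceeds the maximum length are excluded, counted and reported. The
#' fine-tuning stage consumes identical supervised batches whether or not
#' pre-training ran (pre-training draws on an independent RNG stream).
#'
#' @param instances list of [relation_instance()] with \code{train} (and,
#'   for downstream calibration, \code{val}) splits assigned.
#' @param backend an \code{encoder_backend}.
#' @param config a [train_config()].
#' @param pretrain logical: run contrastive pre-training first.
#' @param aug_config an [augmentation_config()] (required when
#'   \code{pretrain} is \code{TRUE}).
#' @param representation entity representation mode applied before marker
#'   insertion: \code{mention}, \code{semtype} or \code{semgroup}.
#' @return A \code{relation_model} with trained parameters and fields
#'   \code{history} (per-epoch supervised loss), \code{pretrain_history},
#'   and \code{skipped} (count of overlong samples).
#' @export
train_relation_model <- function(instances, backend, config = train_config(),
                                 pretrain = FALSE, aug_config = NULL,
                                 representation = "mention") {
  splits <- vapply(instances, function(x) x$split, character(1))
  if (!any(splits == "train")) {
    stop("training requires instances with split == 'train'", call. = FALSE)
  }
  train_inst <- instances[splits == "train"]
  train_inst <- lapply(train_inst, substitute_representation,
                       mode = representation)
  model <- new_relation_model(backend, seed = config$seed)
  params <- model$params
  skipped <- 0L
  marked <- list()
  for (inst in train_inst) {
    ms <- insert_markers(inst)
    tk <- tryCatch(tokenize_sample(ms, backend),
                   relclass_seq_too_long = function(e) NULL)
    if (is.null(tk)) { skipped <- skipped + 1L; next }
    marked <- c(marked, list(list(ms = ms, tk = tk, label = inst$label)))
  }
  if (skipped > 0L) {
    message(skipped, " training sample(s) exceeded max_length and were ",
            "excluded")
  }
  labs <- relation_labels()
  pre_history <- numeric(0)

  if (pretrain) {
    if (is.null(aug_config)) {
      stop("pretrain = TRUE requires an augmentation_config", call. = FALSE)
    }
    state <- adam_init(params)
    pre_seed <- config$seed + 104729L   # independent stream for pre-training
    for (ep in seq_len(config$epochs)) {
      ep_cfg <- aug_config
      ep_cfg$seed <- string_seed(paste0("pretrain-epoch-", ep), pre_seed)
      batches <- build_contrastive_batches(
        lapply(marked, `[[`, "ms"), batch_size = config$batch_size,
        config = ep_cfg, shuffle = TRUE)
      ep_loss <- numeric(0)
      for (batch in batches) {
        res <- withr_seed(
          string_seed(paste0("drop-", ep, "-", length(ep_loss)), pre_seed),
          contrastive_batch_pass(params, backend, batch, config))
        if (is.null(res)) next
        ep_loss <- c(ep_loss, res$loss)
        st <- adam_step(params, res$grads, state, config$learning_rate,
                        config$adam_epsilon)
        params <- st$params; state <- st$state
      }
      pre_history <- c(pre_history, mean(ep_loss))
    }
  }

  # supervised fine-tuning (RNG stream independent of pre-training)
  history <- numeric(0)
  if (config$epochs > 0L && length(marked) > 0L) {
    state <- adam_init(params)
    n <- length(marked)
    for (ep in seq_len(config$epochs)) {
      ord <- withr_seed(config$seed + ep, sample.int(n))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0; ep_n <- 0L
      for (bi in seq_along(batches)) {
        b <- batches[[bi]]
        blabels <- vapply(marked[b], `[[`, character(1), "label")
        w <- batch_class_weights(blabels)
        wsum <- sum(w[blabels])
        grads <- NULL
        bloss <- 0
        drop_seed <- string_seed(paste0("ft-", ep, "-", bi), config$seed)
        withr_seed(drop_seed, {
          for (s in seq_along(b)) {
            sm <- marked[[b[s]]]
            res <- supervised_sample_pass(
              params, backend, sm$tk, match(sm$label, labs),
              weight = w[[sm$label]] / wsum, dropout = config$dropout,
              train = TRUE, grad = TRUE)
            bloss <- bloss + res$loss
            grads <- if (is.null(grads)) res$grads else
              add_trees(grads, res$grads)
          }
        })
        st <- adam_step(params, grads, state, config$learning_rate,
                        config$adam_epsilon)
        params <- st$params; state <- st$state
        ep_loss <- ep_loss + bloss * length(b)
        ep_n <- ep_n + length(b)
      }
      history <- c(history, ep_loss / ep_n)
    }
  }
  model$params <- params
  model$history <- history
  model$pretrain_history <- pre_history
  model$skipped <- skipped
  model$config <- config
  model
}

# encode + project a contrastive batch, compute loss and full gradients
contrastive_batch_pass <- function(params, backend, batch, config) {
  n <- length(batch$sequences)
  fws <- vector("list", n)
  pjs <- vector("list", n)
  Z <- matrix(0, n, length(params$proj$b))
  for (i in seq_len(n)) {
    tk <- tryCatch(tokenize_sample(batch$sequences[[i]], backend),
                   relclass_seq_too_long = function(e) NULL)
    if (is.null(tk)) return(NULL)
    fw <- backbone_forward(params$backbone, tk$ids, backend$max_length)
    pj <- projection_forward(fw$summary, params$proj,
                             dropout = config$dropout, train = TRUE)
    fws[[i]] <- fw; pjs[[i]] <- pj
    Z[i, ] <- pj$z
  }
  cl <- contrastive_loss(Z, batch$origins, config$temperature, grad = TRUE)
  grads <- NULL
  for (i in seq_len(n)) {
    pb <- projection_backward(cl$grad[i, ], params$proj, pjs[[i]])
    T_ <- nrow(fws[[i]]$tokens)
    gb <- backbone_backward(params$backbone, fws[[i]]$cache,
                            matrix(0, T_, backend$hidden_size), pb$dx)
    g <- list(backbone = gb, proj = pb$grads,
              cls = zeros_like(params$cls), subj = zeros_like(params$subj),
              obj = zeros_like(params$obj), out = zeros_like(params$out))
    grads <- if (is.null(grads)) g else add_trees(grads, g)
  }
  list(loss = cl$loss, grads = grads)
}

#' Predict label probabilities for instances
#'
#' Applies the trained model in evaluation mode (no dropout; deterministic).
#' Overlong samples are excluded, counted in the \code{skipped} attribute,
#' and receive a row of \code{NA}.
#'
#' @param model a trained \code{relation_model}.
#' @param instances list of [relation_instance()].
#' @param representation entity representation mode (should match training).
#' @return n x 23 matrix of probabilities (rows named by instance key,
#'   columns by label), with attribute \code{skipped}.
#' @export
predict_probs <- function(model, instances, representation = "mention") {
  backend <- model$backend
  labs <- relation_labels()
  out <- matrix(NA_real_, length(instances), length(labs),
                dimnames = list(NULL, labs))
  skipped <- 0L
  for (i in seq_along(instances)) {
    inst <- substitute_representation(instances[[i]], mode = representation)
    ms <- insert_markers(inst)
    tk <- tryCatch(tokenize_sample(ms, backend),
                   relclass_seq_too_long = function(e) NULL)
    if (is.null(tk)) { skipped <- skipped + 1L; next }
    res <- supervised_sample_pass(model$params, backend, tk, 1L, 1,
                                  dropout = 0, train = FALSE, grad = FALSE)
    out[i, ] <- res$probs
  }
  rownames(out) <- vapply(instances, instance_key, character(1))
  attr(out, "skipped") <- skipped
  out
}
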