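# The convolution-transformer association model: configuration objects,
# the fitting function, and the classed model object with its methods.

#' Convolution-transformer encoder configuration
#'
#' Geometry and regularisation of the per-channel encoder. The transformer
#' defaults (dropout 0.1, 16 heads, feed-forward width 128, 3 TR blocks)
#' are the published optimum for this architecture; the convolution
#' geometry (kernel 16, stride 8, token width 128) is this package's
#' choice, sized so that level-4 feature rows (~3.5k columns on a
#' full-scale corpus) reduce to a transformer-friendly token count.
#'
#' @param conv_kernel 1D convolution kernel width (columns per patch).
#' @param conv_stride convolution stride; tokens
#'   `L = floor((n + m - kernel)/stride) + 1`.
#' @param model_width token embedding dimension `D`; must be divisible by
#'   `n_heads` (per-head key width `d_k = D / n_heads`).
#' @param n_heads number of parallel attention heads `h`.
#' @param ffn_hidden hidden width of the two-layer feed-forward network.
#' @param n_blocks number of TR (transformer encoder) blocks.
#' @param dropout dropout rate in `[0, 1)`, applied after each sublayer.
#' @param share_encoders use one weight set for all channels instead of
#'   one encoder per channel (ablation switch).
#' @param positional_encoding `"sinusoidal"`, `"learned"`, or `"none"`.
#' @param seed seed for weight initialisation.
#' @return an object of class `"ct_config"`.
#' @export
ct_config <- function(conv_kernel = 16L, conv_stride = 8L, model_width = 128L,
                      n_heads = 16L, ffn_hidden = 128L, n_blocks = 3L,
                      dropout = 0.1, share_encoders = FALSE,
                      positional_encoding = c("sinusoidal", "learned", "none"),
                      seed = 1L) {
  positional_encoding <- match.arg(positional_encoding)
  assert_scalar_int(conv_kernel, "conv_kernel", min = 1L)
  assert_scalar_int(conv_stride, "conv_stride", min = 1L)
  assert_scalar_int(model_width, "model_width", min = 1L)
  assert_scalar_int(n_heads, "n_heads", min = 1L)
  assert_scalar_int(ffn_hidden, "ffn_hidden", min = 1L)
  assert_scalar_int(n_blocks, "n_blocks", min = 1L)
  if (model_width %% n_heads != 0L)
    stop_validation("model_width (%d) must be divisible by n_heads (%d)",
                    model_width, n_heads)
  if (!is.numeric(dropout) || dropout < 0 || dropout >= 1)
    stop_validation("dropout must lie in [0, 1)")
  structure(list(conv_kernel = as.integer(conv_kernel),
                 conv_stride = as.integer(conv_stride),
                 model_width = as.integer(model_width),
                 n_heads = as.integer(n_heads),
                 ffn_hidden = as.integer(ffn_hidden),
                 n_blocks = as.integer(n_blocks),
                 dropout = dropout,
                 share_encoders = isTRUE(share_encoders),
                 positional_encoding = positional_encoding,
                 seed = as.integer(seed)),
            class = "ct_config")
}

#' Training configuration
#'
#' Binary cross-entropy loss with the Adam optimiser throughout. The
#' full-scale defaults (50 epochs, batch 32, learning rate 1e-4) suit
#' corpora of thousands of pairs; small synthetic corpora trained for few
#' epochs warrant a larger step (see the methods vignette).
#'
#' @param epochs passes over the training pairs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed seed controlling shuffling and dropout.
#' @return an object of class `"ct_train_config"`.
#' @export
train_config <- function(epochs = 50L, batch_size = 32L, learning_rate = 1e-4,
                         seed = 1L) {
  assert_scalar_int(epochs, "epochs", min = 1L)
  assert_scalar_int(batch_size, "batch_size", min = 1L)
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop_validation("learning_rate must be positive")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "ct_train_config")
}

.check_channels <- function(drug_sims) {
  if (!is.list(drug_sims) || length(drug_sims) == 0L ||
      is.null(names(drug_sims)) || !all(names(drug_sims) %in% DRUG_CHANNELS))
    stop_validation("`drug_sims` must be a non-empty named list with names among: %s",
                    paste(DRUG_CHANNELS, collapse = ", "))
  names(drug_sims)
}

# forward through all channel encoders + head; returns probabilities and
# (optionally) the caches for backprop
.model_forward <- function(params, cfg, feats, idx, training = FALSE) {
  channels <- names(feats)
  embs <- list(); caches <- list()
  for (ch in channels) {
    ep <- if (cfg$share_encoders) params$encoders$shared else params$encoders[[ch]]
    fw <- .encoder_forward(ep, feats[[ch]][idx], cfg, training = training)
    embs[[ch]] <- fw$emb
    caches[[ch]] <- fw$cache
  }
  E <- do.call(cbind, embs)
  z <- drop(E %*% params$head$W) + params$head$b
  list(p = 1 / (1 + exp(-z)), z = z, E = E, caches = caches)
}

#' Fit the convolution-transformer drug-ATC association model
#'
#' Trains one encoder per similarity channel (three parallel branches by
#' default) plus the shared prediction head, with binary cross-entropy on
#' balanced labeled pairs and Adam. Features are assembled once, under the
#' two-stage masking protocol: the cells of `test_pairs` (the current
#' fold's held-out pairs) are zeroed for every sample, and each sample's
#' own target cell is zeroed in its feature matrix, so no label the model
#' is asked about is ever visible to it.
#'
#' @param pairs labeled training pairs (columns `drug`, `code`, `label`).
#' @param table the unmasked [association_table()].
#' @param drug_sims named list of drug-similarity matrices (names among
#'   `"cs"`, `"ddi"`, `"se"`); determines the channels used.
#' @param atc_sim `m x m` ATC-code similarity matrix
#'   (see [atc_similarity_matrix()]).
#' @param test_pairs pairs whose association cells are masked during
#'   feature construction (pass the fold's test set during
#'   cross-validation); `NULL` for none.
#' @param config a [ct_config()].
#' @param train a [train_config()].
#' @param verbose print per-epoch loss.
#' @param log_file optional path; per-epoch training metrics are appended
#'   as JSON lines (`{"epoch": ..., "loss": ...}`).
#' @return an object of class `"ct_model"`.
#' @export
ct_fit <- function(pairs, table, drug_sims, atc_sim, test_pairs = NULL,
                   config = ct_config(), train = train_config(),
                   verbose = FALSE, log_file = NULL) {
  stopifnot(inherits(table, "assoc_table"), inherits(config, "ct_config"),
            inherits(train, "ct_train_config"))
  channels <- .check_channels(drug_sims)
  pairs <- as.data.frame(pairs)
  if (!all(c("drug", "code", "label") %in% names(pairs)))
    stop_validation("`pairs` needs columns drug, code, label")
  n <- nrow(table$matrix); m <- ncol(table$matrix)
  feats <- lapply(drug_sims, function(sim)
    batch_features(pairs, sim, atc_sim, table, test_pairs))
  N <- nrow(pairs)
  y <- as.numeric(pairs$label)
  S <- n + m
  L <- (S - config$conv_kernel) %/% config$conv_stride + 1L
  if (L < 1L)
    stop_validation("n + m = %d is shorter than conv_kernel = %d", S, config$conv_kernel)

  set.seed(split_seed(config$seed, 10L))
  params <- list(encoders = list(), head = NULL)
  if (config$share_encoders) {
    params$encoders$shared <- .encoder_init(config, L)
  } else {
    for (ch in channels) params$encoders[[ch]] <- .encoder_init(config, L)
  }
  D <- config$model_width
  params$head <- list(W = .glorot(length(channels) * D, 1L), b = 0)

  state <- list(m = .zeros_like(params), v = .zeros_like(params), t = 0L)
  losses <- numeric(train$epochs)
  set.seed(split_seed(train$seed, 20L))
  for (ep in seq_len(train$epochs)) {
    ord <- sample.int(N)
    batch_losses <- c()
    for (start in seq(1L, N, by = train$batch_size)) {
      idx <- ord[start:min(start + train$batch_size - 1L, N)]
      B <- length(idx)
      fw <- .model_forward(params, config, feats, idx, training = TRUE)
      p <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
      loss <- -mean(y[idx] * log(p) + (1 - y[idx]) * log(1 - p))
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", ep,
             "; reduce the learning rate", call. = FALSE)
      batch_losses <- c(batch_losses, loss)
      dz <- matrix((fw$p - y[idx]) / B, ncol = 1L)
      grads <- list(encoders = list(),
                    head = list(W = crossprod(fw$E, dz), b = sum(dz)))
      dE <- dz %*% t(params$head$W)   # B x (C*D)
      for (ci in seq_along(channels)) {
        ch <- channels[ci]
        cols <- ((ci - 1L) * D + 1L):(ci * D)
        ep_par <- if (config$share_encoders) params$encoders$shared
                  else params$encoders[[ch]]
        g <- .encoder_backward(ep_par, config, fw$caches[[ch]],
                               dE[, cols, drop = FALSE])
        if (config$share_encoders) {
          grads$encoders$shared <- if (is.null(grads$encoders$shared)) g
            else .sum_grads(grads$encoders$shared, g)
        } else grads$encoders[[ch]] <- g
      }
      st <- .adam_step(params, grads, state, train$learning_rate)
      params <- st$params; state <- st$state
    }
    losses[ep] <- mean(batch_losses)
    if (!is.null(log_file))
      cat(jsonlite::toJSON(list(epoch = ep, loss = losses[ep]),
                           auto_unbox = TRUE, digits = NA),
          "\n", sep = "", file = log_file, append = TRUE)
    if (verbose) message(sprintf("epoch %3d  loss %.5f", ep, losses[ep]))
  }

  structure(list(params = params, config = config, train = train,
                 channels = channels, n_drugs = n, n_codes = m,
                 loss_history = losses,
                 context = list(table = table, drug_sims = drug_sims,
                                atc_sim = atc_sim, test_pairs = test_pairs)),
            class = "ct_model")
}

.sum_grads <- function(a, b) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- .sum_grads(a[[nm]], b[[nm]])
    a
  } else a + b
}

#' Predict association probabilities for drug-code pairs
#'
#' Features are assembled under the same masking protocol as in fitting
#' (test-fold cells from the fit, plus per-target masking), using the data
#' context stored in the model unless overridden.
#'
#' @param object a fitted [ct_fit()] model.
#' @param pairs data frame with columns `drug`, `code`.
#' @param drug_sims,atc_sim,table,test_pairs optional overrides of the
#'   stored data context.
#' @param batch_size evaluation batch size.
#' @param ... unused.
#' @return numeric vector of probabilities in `(0, 1)`, one per pair.
#' @export
predict.ct_model <- function(object, pairs, drug_sims = NULL, atc_sim = NULL,
                             table = NULL, test_pairs = NULL,
                             batch_size = 64L, ...) {
  ctx <- object$context
  drug_sims <- drug_sims %||% ctx$drug_sims
  atc_sim <- atc_sim %||% ctx$atc_sim
  table <- table %||% ctx$table
  test_pairs <- test_pairs %||% ctx$test_pairs
  if (!setequal(names(drug_sims), object$channels))
    stop_validation("channels of `drug_sims` (%s) differ from the fitted model (%s)",
                    paste(names(drug_sims), collapse = ","),
                    paste(object$channels, collapse = ","))
  pairs <- as.data.frame(pairs)
  feats <- lapply(drug_sims[object$channels], function(sim)
    batch_features(pairs, sim, atc_sim, table, test_pairs))
  out <- numeric(nrow(pairs))
  for (start in seq(1L, nrow(pairs), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, nrow(pairs))
    out[idx] <- .model_forward(object$params, object$config, feats, idx,
                               training = FALSE)$p
  }
  out
}

#' Score one (drug, code) pair from its pre-built channel features
#'
#' The low-level prediction head: encodes each channel's `2 x (m + n)`
#' feature matrix, concatenates the embeddings, and applies the fully
#' connected layer and sigmoid.
#'
#' @param model a fitted `ct_model`.
#' @param features named list of feature matrices, one per model channel.
#' @return a single probability strictly inside `(0, 1)`.
#' @export
predict_pair <- function(model, features) {
  stopifnot(inherits(model, "ct_model"))
  if (!setequal(names(features), model$channels))
    stop_validation("features must be supplied for exactly the channels: %s",
                    paste(model$channels, collapse = ", "))
  feats <- lapply(model$channels, function(ch) list(features[[ch]]))
  names(feats) <- model$channels
  .model_forward(model$params, model$config, feats, 1L, training = FALSE)$p
}

#' Encode one feature matrix into its channel embedding
#'
#' Runs the convolution-transformer encoder (convolution tokeniser,
#' positional encoding, TR blocks, average pooling) in evaluation mode.
#'
#' @param model a fitted `ct_model`.
#' @param feature a `2 x (m + n)` feature matrix.
#' @param channel which channel's encoder weights to use.
#' @return embedding vector of length `model_width`.
#' @export
ct_encode <- function(model, feature, channel = model$channels[[1L]]) {
  stopifnot(inherits(model, "ct_model"))
  if (!channel %in% model$channels)
    stop_validation("unknown channel '%s'", channel)
  ep <- if (model$config$share_encoders) model$params$encoders$shared
        else model$params$encoders[[channel]]
  drop(.encoder_forward(ep, list(feature), model$config, training = FALSE)$emb)
}

.n_params <- function(p) sum(rapply(p, length, how = "unlist"))

#' @export
print.ct_model <- function(x, ...) {
  cat(sprintf(paste0("<ct_model> channels: %s | %d drugs x %d codes\n",
                     "  encoder: width %d, %d heads, %d TR blocks, kernel %d/stride %d%s\n",
                     "  %s parameters | final training loss %.4f\n"),
              paste(x$channels, collapse = "+"), x$n_drugs, x$n_codes,
              x$config$model_width, x$config$n_heads, x$config$n_blocks,
              x$config$conv_kernel, x$config$conv_stride,
              if (x$config$share_encoders) " (shared weights)" else "",
              format(.n_params(x$params), big.mark = ","),
              utils::tail(x$loss_history, 1L)))
  invisible(x)
}

#' @export
summary.ct_model <- function(object, ...) {
  print(object)
  cat(sprintf("  trained %d epochs, batch %d, lr %g, dropout %g, pos-enc %s\n",
              object$train$epochs, object$train$batch_size,
              object$train$learning_rate, object$config$dropout,
              object$config$positional_encoding))
  cat(sprintf("  loss: first %.4f -> last %.4f\n",
              object$loss_history[1L], utils::tail(object$loss_history, 1L)))
  invisible(object)
}

#' @export
plot.ct_model <- function(x, ...) {
  plot(seq_along(x$loss_history), x$loss_history, type = "l",
       xlab = "epoch", ylab = "mean binary cross-entropy",
       main = "Training loss", ...)
  invisible(x)
}
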