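# Permutation-invariant deep one-class model.
#
# A pair is treated as a SET of two molecule sub-vectors: a shared
# per-molecule MLP embeds each sub-vector, mean pooling merges the two
# embeddings (making the representation exactly order-invariant by
# construction), and a bias-free linear read-out produces the latent
# code. Phase 1 pretrains this encoder as an autoencoder with an
# orderless (assignment-minimal) reconstruction loss; the hypersphere
# center is then frozen as the mean training latent, and phase 2
# fine-tunes the encoder to pull training latents toward that center
# (Deep SVDD objective). Collapse guards: bias-free read-out, weight
# decay, non-trainable center. Backprop is hand-written (no deep-learning
# runtime exists in the target environment) and is verified against
# numerical gradients in the test suite.

#' Configuration of the deep one-class model
#'
#' @param d Per-molecule feature count (the pair input has length `2 * d`).
#' @param latent Latent dimension of the encoder read-out.
#' @param hidden Width of the shared per-molecule MLP.
#' @param attention_blocks,attention_heads Retained for forward
#'   compatibility with attention-based set encoders; the shipped
#'   implementation uses shared-MLP mean pooling and records (but does
#'   not consume) these fields.
#' @param pretrain_epochs Autoencoder pretraining epochs.
#' @param epochs Hypersphere fine-tuning epochs.
#' @param batch_size Minibatch size (`Inf` = full batch).
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty on weight matrices (not biases).
#' @param seed Integer seed for initialization and batching.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(d, latent = 32L, hidden = 64L,
                           attention_blocks = 2L, attention_heads = 4L,
                           pretrain_epochs = 150L, epochs = 80L,
                           batch_size = 64L, lr = 3e-3,
                           weight_decay = 1e-5, seed = 1L) {
  check_scalar(d, 1); check_scalar(latent, 1); check_scalar(hidden, 1)
  structure(list(d = as.integer(d), latent = as.integer(latent),
                 hidden = as.integer(hidden),
                 attention_blocks = as.integer(attention_blocks),
                 attention_heads = as.integer(attention_heads),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 epochs = as.integer(epochs), batch_size = batch_size,
                 lr = lr, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "encoder_config")
}

deep_init_params <- function(cfg) {
  rmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 1 / sqrt(nr)),
                                  nr, nc)
  with_seed(cfg$seed, list(
    # first layer is the equivariant set layer: each element sees its own
    # features and its deviation from the set mean, so cross-co-former
    # contrasts are available before any mixing
    W1 = rmat(2L * cfg$d, cfg$hidden), b1 = numeric(cfg$hidden),
    W2 = rmat(cfg$hidden, cfg$hidden), b2 = numeric(cfg$hidden),
    # read-out MLP over the invariant pooled statistics (mean and
    # absolute difference of the two molecule embeddings — the 2-element
    # analogue of pairwise set-attention interactions); final read-out
    # layer bias-free (collapse guard)
    Wr = rmat(2L * cfg$hidden, cfg$hidden), br = numeric(cfg$hidden),
    W3 = rmat(cfg$hidden, cfg$latent),
    W4 = rmat(cfg$latent, cfg$hidden), b4 = numeric(cfg$hidden),
    W5 = rmat(cfg$hidden, 2L * cfg$d), b5 = numeric(2L * cfg$d)))
}

affine <- function(X, W, b) sweep(X %*% W, 2, b, "+")

deep_encode_forward <- function(par, X, d) {
  A <- X[, seq_len(d), drop = FALSE]
  B <- X[, d + seq_len(d), drop = FALSE]
  Ain <- cbind(A, (A - B) / 2)   # equivariant layer input: (x_i, x_i - mean)
  Bin <- cbind(B, (B - A) / 2)
  h1a <- tanh(affine(Ain, par$W1, par$b1)); h2a <- tanh(affine(h1a, par$W2, par$b2))
  h1b <- tanh(affine(Bin, par$W1, par$b1)); h2b <- tanh(affine(h1b, par$W2, par$b2))
  diff <- h2a - h2b
  p <- cbind((h2a + h2b) / 2, abs(diff) / 2)   # invariant pooled statistics
  q <- tanh(affine(p, par$Wr, par$br))
  list(A = A, B = B, Ain = Ain, Bin = Bin,
       h1a = h1a, h2a = h2a, h1b = h1b, h2b = h2b,
       sgn = sign(diff), p = p, q = q, z = q %*% par$W3)
}

# gradient of the encoder given dL/dz; returns gradients for W1..W3
deep_encode_backward <- function(par, cache, dz) {
  g <- list(W3 = crossprod(cache$q, dz))
  dpre_r <- (dz %*% t(par$W3)) * (1 - cache$q^2)
  g$Wr <- crossprod(cache$p, dpre_r)
  g$br <- colSums(dpre_r)
  dp <- dpre_r %*% t(par$Wr)
  h <- ncol(cache$h2a)
  dmean <- dp[, seq_len(h), drop = FALSE]
  ddiff <- dp[, h + seq_len(h), drop = FALSE] * cache$sgn
  acc <- list(W1 = 0, b1 = 0, W2 = 0, b2 = 0)
  for (branch in c("a", "b")) {
    h1 <- cache[[paste0("h1", branch)]]
    h2 <- cache[[paste0("h2", branch)]]
    inp <- if (branch == "a") cache$Ain else cache$Bin
    de <- (dmean + if (branch == "a") ddiff else -ddiff) / 2
    dpre2 <- de * (1 - h2^2)
    acc$W2 <- acc$W2 + crossprod(h1, dpre2)
    acc$b2 <- acc$b2 + colSums(dpre2)
    dpre1 <- (dpre2 %*% t(par$W2)) * (1 - h1^2)
    acc$W1 <- acc$W1 + crossprod(inp, dpre1)
    acc$b1 <- acc$b1 + colSums(dpre1)
  }
  c(g, acc)
}

deep_decode_forward <- function(par, z) {
  hd <- tanh(affine(z, par$W4, par$b4))
  list(hd = hd, out = affine(hd, par$W5, par$b5))
}

# Orderless reconstruction: the decoder reconstructs the pair's
# order-invariant canonical form [(a + b) / 2, |a - b| / 2], which is
# equivalent to the molecule set up to orientation. Reconstructing the
# difference block forces the latent to encode how strongly the two
# co-former profiles diverge — the axis along which non-complementary
# pairs are novel — rather than only the pair average.
deep_ae_grad <- function(par, X, d, weight_decay) {
  enc <- deep_encode_forward(par, X, d)
  dec <- deep_decode_forward(par, enc$z)
  n <- nrow(X)
  target <- cbind((enc$A + enc$B) / 2, abs(enc$A - enc$B) / 2)
  denom <- n * 2 * d
  loss <- sum((dec$out - target)^2) / denom
  dout <- 2 * (dec$out - target) / denom
  g <- list(W5 = crossprod(dec$hd, dout), b5 = colSums(dout))
  dhd <- (dout %*% t(par$W5)) * (1 - dec$hd^2)
  g$W4 <- crossprod(enc$z, dhd); g$b4 <- colSums(dhd)
  dz <- dhd %*% t(par$W4)
  g <- c(g, deep_encode_backward(par, enc, dz))
  for (w in c("W1", "W2", "Wr", "W3", "W4", "W5")) {
    g[[w]] <- g[[w]] + weight_decay * par[[w]]
    loss <- loss + weight_decay * sum(par[[w]]^2) / 2
  }
  list(loss = loss, grad = g)
}

# hypersphere loss (mean squared distance to the fixed center)
deep_svdd_grad <- function(par, X, d, center, weight_decay) {
  enc <- deep_encode_forward(par, X, d)
  n <- nrow(X)
  diff <- sweep(enc$z, 2, center)
  loss <- sum(diff^2) / n
  dz <- 2 * diff / n
  g <- deep_encode_backward(par, enc, dz)
  for (w in c("W1", "W2", "Wr", "W3")) {
    g[[w]] <- g[[w]] + weight_decay * par[[w]]
    loss <- loss + weight_decay * sum(par[[w]]^2) / 2
  }
  list(loss = loss, grad = g)
}

adam_new <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (w in names(grad)) {
    st$m[[w]] <- beta1 * st$m[[w]] + (1 - beta1) * grad[[w]]
    st$v[[w]] <- beta2 * st$v[[w]] + (1 - beta2) * grad[[w]]^2
    mh <- st$m[[w]] / (1 - beta1^st$t)
    vh <- st$v[[w]] / (1 - beta2^st$t)
    par[[w]] <- par[[w]] - lr * mh / (sqrt(vh) + eps)
  }
  list(par = par, st = st)
}

deep_train_loop <- function(par, X, cfg, grad_fun, epochs, which_params) {
  st <- adam_new(par[which_params])
  losses <- numeric(epochs)
  n <- nrow(X)
  bs <- if (is.finite(cfg$batch_size)) min(cfg$batch_size, n) else n
  for (e in seq_len(epochs)) {
    idx <- if (bs < n) with_seed(derive_seed(cfg$seed, 77000L + e),
                                 sample(n)) else seq_len(n)
    tot <- 0
    for (start in seq(1L, n, by = bs)) {
      rows <- idx[start:min(start + bs - 1L, n)]
      gr <- grad_fun(par, X[rows, , drop = FALSE])
      if (!is.finite(gr$loss))
        oc_stop(sprintf(
          "non-finite loss at epoch %d (lr = %g, batch = %d); lower the learning rate",
          e, cfg$lr, bs), "oc_training_error")
      upd <- adam_step(par[which_params], gr$grad[which_params], st, cfg$lr)
      par[which_params] <- upd$par
      st <- upd$st
      tot <- tot + gr$loss * length(rows)
    }
    losses[e] <- tot / n
  }
  list(par = par, losses = losses)
}

#' Pretrain the set autoencoder
#'
#' Phase 1 of the deep one-class workflow: the permutation-invariant
#' encoder plus a decoder are trained to reconstruct the two molecule
#' sub-vectors under an orderless (best-assignment) mean-squared error.
#' With `pretrain_epochs = 0` the initialized state is returned and the
#' untrained loss reported.
#'
#' @param config An [encoder_config()].
#' @param X Pair-vector matrix (`2 * d` columns, scaled features).
#' @return An object of class `deep_encoder`: `params`, `config`,
#'   `losses` (per-epoch reconstruction loss; element 0 reported as
#'   `initial_loss`).
#' @export
pretrain_autoencoder <- function(config, X) {
  stopifnot(inherits(config, "encoder_config"))
  X <- as.matrix(X)
  if (ncol(X) != 2L * config$d)
    oc_stop(sprintf("expected %d columns, got %d", 2L * config$d, ncol(X)),
            "oc_input_error")
  par <- deep_init_params(config)
  gf <- function(p, Xb) deep_ae_grad(p, Xb, config$d, config$weight_decay)
  initial_loss <- gf(par, X)$loss
  if (config$pretrain_epochs > 0L) {
    run <- deep_train_loop(par, X, config, gf, config$pretrain_epochs,
                           names(par))
    par <- run$par; losses <- run$losses
  } else losses <- numeric(0)
  structure(list(params = par, config = config, losses = losses,
                 initial_loss = initial_loss), class = "deep_encoder")
}

#' Latent representations of pair vectors
#' @param encoder A `deep_encoder` or `hypersphere_model`.
#' @param X Pair-vector matrix.
#' @return Numeric matrix (rows x latent).
#' @export
encode_pairs <- function(encoder, X) {
  cfg <- encoder$config
  X <- as.matrix(X)
  if (ncol(X) != 2L * cfg$d)
    oc_stop(sprintf("expected %d columns, got %d", 2L * cfg$d, ncol(X)),
            "oc_input_error")
  deep_encode_forward(encoder$params, X, cfg$d)$z
}

#' Hypersphere center: mean latent representation of the training pairs
#'
#' @param encoder A pretrained `deep_encoder`.
#' @param X Training pair-vector matrix.
#' @return Numeric vector of length `latent`.
#' @export
compute_center <- function(encoder, X) {
  if (nrow(as.matrix(X)) == 0L) oc_stop("empty training set",
                                        "oc_input_error")
  colMeans(encode_pairs(encoder, X))
}

#' Fine-tune the encoder against the fixed hypersphere center
#'
#' Phase 2: minimizes the mean squared Euclidean distance of the training
#' latents to the frozen center (plus weight decay). The decoder is
#' discarded. Warns when a representation collapse is detected (training
#' distances numerically zero).
#'
#' @param encoder A pretrained `deep_encoder`.
#' @param center The [compute_center()] vector (frozen).
#' @param X Training pair-vector matrix.
#' @param config Optional override of the encoder's config (epochs, lr).
#' @return An object of class `hypersphere_model`: `params`, `center`,
#'   `config`, `losses`.
#' @export
train_one_class <- function(encoder, center, X, config = encoder$config) {
  stopifnot(inherits(encoder, "deep_encoder"))
  X <- as.matrix(X)
  if (length(center) != config$latent)
    oc_stop("center length must equal the latent dimension", "oc_input_error")
  enc_params <- c("W1", "b1", "W2", "b2", "Wr", "br", "W3")
  gf <- function(p, Xb) deep_svdd_grad(p, Xb, config$d, center,
                                       config$weight_decay)
  par <- encoder$params
  losses <- numeric(0)
  if (config$epochs > 0L) {
    run <- deep_train_loop(par, X, config, gf, config$epochs, enc_params)
    par <- run$par; losses <- run$losses
  }
  model <- structure(list(params = par, center = center, config = config,
                          losses = losses), class = "hypersphere_model")
  dists <- deep_distance(model, X)
  if (mean(dists) < 1e-8)
    warning(paste("possible representation collapse: training distances are",
                  "numerically zero; check weight decay and the bias-free",
                  "read-out, and validate against planted outliers"))
  model
}

#' Euclidean latent distance to the hypersphere center
#' @param model A `hypersphere_model`.
#' @param X Pair-vector matrix.
#' @return Numeric vector of distances (>= 0).
#' @export
deep_distance <- function(model, X) {
  stopifnot(inherits(model, "hypersphere_model"))
  z <- encode_pairs(model, X)
  sqrt(rowSums(sweep(z, 2, model$center)^2))
}

#' Normalized deep scores
#'
#' `-distance` min-max normalized over the declared reference set: the
#' reference pair closest to the center scores 1, the farthest 0. The
#' score is symmetric under orientation swap by architecture.
#'
#' @param model A `hypersphere_model`.
#' @param X Pair-vector matrix to score.
#' @param reference Pair-vector matrix defining the normalization range
#'   (default `X`; in the workflow, the union of labelled and candidate
#'   pairs).
#' @return Numeric scores in \[0, 1\] relative to the reference.
#' @export
score_deep <- function(model, X, reference = X) {
  raw <- -deep_distance(model, X)
  ref <- -deep_distance(model, reference)
  normalize_scores(raw, ref)
}
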