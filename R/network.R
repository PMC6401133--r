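# The 2D fully convolutional residual contact network and its 1D
# secondary-structure sibling.
#
# Architecture (2D): entry 3x3 conv + ReLU, then `blocks` identical
# residual blocks (conv, ReLU, conv, add skip, ReLU), then the per-channel
# transpose average (O + t(O))/2, a final 3x3 conv to 3 output channels
# (non-contact / contact / ignored), a second transpose average on the
# logits (which makes the output exactly symmetric), and a per-pair
# softmax. No batch normalization and no dropout: inputs have variable
# side length L and the output needs pixel-level resolution.

#' Configuration of the contact network
#'
#' Defaults give the full-size network: 51 input channels, 64 filters per
#' convolution, 3 x 3 kernels, 19 residual blocks and a 3-channel output,
#' i.e. 40 convolutional layers and ~1.4 million trainable parameters.
#' Smaller settings are useful for desk-scale training.
#'
#' @param in_channels Input feature channels (default 51).
#' @param filters Filters per convolutional layer (default 64).
#' @param blocks Number of residual blocks (default 19).
#' @param out_channels Output classes (default 3).
#' @param kernel Kernel side (only 3 is supported).
#' @return An object of class `contact_net_config`.
#' @export
contact_net_config <- function(in_channels = 51L, filters = 64L,
                               blocks = 19L, out_channels = 3L,
                               kernel = 3L) {
  cfg <- list(in_channels = as.integer(in_channels),
              filters = as.integer(filters), blocks = as.integer(blocks),
              out_channels = as.integer(out_channels),
              kernel = as.integer(kernel), dims = 2L)
  if (any(unlist(cfg[1:4]) < 1L)) stop("all configuration counts must be >= 1")
  if (cfg$kernel != 3L) stop("only 3 x 3 kernels are supported")
  class(cfg) <- "contact_net_config"
  cfg
}

#' Configuration of the 1D secondary-structure network
#'
#' The 1D analogue of the residual contact network: entry conv + ReLU,
#' `blocks` residual blocks, final conv to a 3-state (helix, strand, coil)
#' output, softmax per residue. The default of 4 blocks yields 10
#' convolutional layers. Input channels default to 41: a 20-column profile
#' plus a 21-letter one-hot sequence encoding (20 amino acids + X).
#'
#' @param in_channels Input channels per residue (default 41).
#' @param filters Filters per layer (default 64).
#' @param blocks Residual blocks (default 4).
#' @param out_channels Output states (default 3).
#' @return An object of class `ss_net_config`.
#' @export
ss_net_config <- function(in_channels = 41L, filters = 64L, blocks = 4L,
                          out_channels = 3L) {
  cfg <- list(in_channels = as.integer(in_channels),
              filters = as.integer(filters), blocks = as.integer(blocks),
              out_channels = as.integer(out_channels), kernel = 3L,
              dims = 1L)
  if (any(unlist(cfg[1:4]) < 1L)) stop("all configuration counts must be >= 1")
  class(cfg) <- "ss_net_config"
  cfg
}

#' Number of convolutional layers of a configuration
#'
#' Entry conv + 2 per residual block + final conv.
#'
#' @param config A [contact_net_config()] or [ss_net_config()].
#' @return Integer layer count (40 for the default 2D configuration, 10
#'   for the default 1D configuration).
#' @export
n_conv_layers <- function(config) {
  2L + 2L * config$blocks
}

#' Number of trainable parameters of a configuration
#'
#' Closed form: with kernel size k (k^2 weights per input/output channel
#' pair in 2D, k in 1D), f filters, c_in input and c_out output channels
#' and B blocks: (k c_in f + f) + B * 2 * (k f f + f) + (k f c_out + c_out)
#' where k is the kernel footprint (9 in 2D, 3 in 1D).
#'
#' @param config A [contact_net_config()] or [ss_net_config()].
#' @return Integer parameter count (1,434,499 for the default 2D
#'   configuration, which rounds to 1.4 million).
#' @export
n_parameters <- function(config) {
  k <- if (config$dims == 2L) config$kernel^2 else config$kernel
  f <- config$filters
  (k * config$in_channels * f + f) +
    config$blocks * 2L * (k * f * f + f) +
    (k * f * config$out_channels + config$out_channels)
}

# He-initialized parameter list; layer 1 = entry, layers 2..(2B+1) = block
# convs, last layer = final conv. Uses the R RNG (seed it for determinism).
init_conv_params <- function(config, zero_final = FALSE) {
  k <- if (config$dims == 2L) config$kernel^2 else config$kernel
  mk <- function(cin, cout) {
    fan_in <- k * cin
    list(W = matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout),
         b = numeric(cout))
  }
  layers <- vector("list", n_conv_layers(config))
  layers[[1L]] <- mk(config$in_channels, config$filters)
  for (l in 2L:(1L + 2L * config$blocks)) layers[[l]] <- mk(config$filters, config$filters)
  nl <- length(layers)
  layers[[nl]] <- mk(config$filters, config$out_channels)
  if (zero_final) {
    layers[[nl]]$W[] <- 0
    layers[[nl]]$b[] <- 0
  }
  layers
}

#' Build an (untrained) contact network
#'
#' @param config A [contact_net_config()].
#' @param seed Optional integer seed for the weight initialization.
#' @param zero_final Zero the final layer's weights (useful to verify the
#'   uniform-softmax baseline).
#' @return An object of class `contact_net` holding `config` and the
#'   parameter list.
#' @export
build_contact_network <- function(config = contact_net_config(),
                                  seed = NULL, zero_final = FALSE) {
  stopifnot(inherits(config, "contact_net_config"))
  if (!is.null(seed)) set.seed(seed)
  structure(list(config = config,
                 params = init_conv_params(config, zero_final = zero_final)),
            class = "contact_net")
}

#' Build an (untrained) secondary-structure network
#'
#' @param config An [ss_net_config()].
#' @param seed Optional integer seed.
#' @return An object of class `ss_net`.
#' @export
build_ss_network <- function(config = ss_net_config(), seed = NULL) {
  stopifnot(inherits(config, "ss_net_config"))
  if (!is.null(seed)) set.seed(seed)
  structure(list(config = config, params = init_conv_params(config)),
            class = "ss_net")
}

#' @export
print.contact_net <- function(x, ...) {
  cat(sprintf(
    "<contact_net> %d conv layers (%d residual blocks, %d filters), %s parameters\n",
    n_conv_layers(x$config), x$config$blocks, x$config$filters,
    format(n_parameters(x$config), big.mark = ",")))
  invisible(x)
}

# transpose of the spatial dims of an L x L x C array
sym_transpose <- function(A) aperm(A, c(2L, 1L, 3L))

# Forward pass. Returns list(probs, pmap, logits, cache).
contact_forward <- function(params, config, X, want_cache = FALSE) {
  if (dim(X)[3L] != config$in_channels)
    stop("feature tensor has ", dim(X)[3L], " channels, configuration expects ",
         config$in_channels)
  B <- config$blocks
  nl <- length(params)
  cache <- if (want_cache) list(blocks = vector("list", B)) else NULL
  Z0 <- conv2d_fw(X, params[[1L]]$W, params[[1L]]$b)
  A <- Z0 * (Z0 > 0)
  if (want_cache) { cache$X <- X; cache$A0 <- A }
  for (b in seq_len(B)) {
    l1 <- 2L * b; l2 <- 2L * b + 1L
    A_in <- A
    Z1 <- conv2d_fw(A_in, params[[l1]]$W, params[[l1]]$b)
    R1 <- Z1 * (Z1 > 0)
    Z2 <- conv2d_fw(R1, params[[l2]]$W, params[[l2]]$b)
    S <- Z2 + A_in
    A <- S * (S > 0)
    if (want_cache) cache$blocks[[b]] <- list(A_in = A_in, R1 = R1, A = A)
  }
  Sym <- (A + sym_transpose(A)) / 2
  Zf <- conv2d_fw(Sym, params[[nl]]$W, params[[nl]]$b)
  Zs <- (Zf + sym_transpose(Zf)) / 2
  if (want_cache) cache$Sym <- Sym
  # per-pair softmax over the channel dimension
  m <- pmax(Zs[, , 1L], Zs[, , 2L], Zs[, , 3L])
  e <- exp(Zs - as.vector(m))
  tot <- e[, , 1L] + e[, , 2L] + e[, , 3L]
  probs <- e / as.vector(tot)
  list(probs = probs, pmap = probs[, , 2L], logits = Zs, cache = cache)
}

# Weighted, masked cross-entropy over {non-contact, contact, ignored}.
# labels: L x L integer codes (0/1/2); pairs labelled `ignored` are masked
# out of the loss. Returns list(loss, dlogits, n).
contact_loss <- function(probs, labels, contact_weight = 1) {
  L <- nrow(labels)
  w <- matrix(1, L, L)
  w[labels == .STATE_CONTACT] <- contact_weight
  mask <- labels != .STATE_IGNORED
  n <- sum(mask)
  if (n == 0L)
    return(list(loss = 0, dlogits = array(0, dim(probs)), n = 0L))
  eps <- 1e-12
  p_true <- matrix(0, L, L)
  d <- array(0, dim(probs))
  for (k in 0:2) {
    sel <- labels == k
    p_true[sel] <- probs[, , k + 1L][sel]
    d[, , k + 1L] <- probs[, , k + 1L] - sel
  }
  loss <- sum(-log(p_true + eps) * w * mask) / n
  scale <- w * mask / n
  for (k in 1:3) d[, , k] <- d[, , k] * scale
  list(loss = loss, dlogits = d, n = n)
}

# Backward pass; dlogits is the gradient at the symmetrized logits.
# Returns gradients shaped like `params`.
contact_backward <- function(params, config, cache, dlogits) {
  B <- config$blocks
  nl <- length(params)
  grads <- vector("list", nl)
  dZf <- (dlogits + sym_transpose(dlogits)) / 2
  g <- conv2d_bw(cache$Sym, params[[nl]]$W, dZf)
  grads[[nl]] <- list(W = g$dW, b = g$db)
  dA <- (g$dX + sym_transpose(g$dX)) / 2
  for (b in rev(seq_len(B))) {
    l1 <- 2L * b; l2 <- 2L * b + 1L
    bc <- cache$blocks[[b]]
    dS <- dA * (bc$A > 0)
    g2 <- conv2d_bw(bc$R1, params[[l2]]$W, dS)
    grads[[l2]] <- list(W = g2$dW, b = g2$db)
    dZ1 <- g2$dX * (bc$R1 > 0)
    g1 <- conv2d_bw(bc$A_in, params[[l1]]$W, dZ1)
    grads[[l1]] <- list(W = g1$dW, b = g1$db)
    dA <- g1$dX + dS
  }
  dZ0 <- dA * (cache$A0 > 0)
  g0 <- conv2d_bw(cache$X, params[[1L]]$W, dZ0)
  grads[[1L]] <- list(W = g0$dW, b = g0$db)
  grads
}

# One SGD-with-momentum step (L2 weight decay on W, not on b).
sgd_step <- function(params, grads, velocity, lr, momentum, weight_decay) {
  for (l in seq_along(params)) {
    gW <- grads[[l]]$W + weight_decay * params[[l]]$W
    velocity[[l]]$W <- momentum * velocity[[l]]$W - lr * gW
    velocity[[l]]$b <- momentum * velocity[[l]]$b - lr * grads[[l]]$b
    params[[l]]$W <- params[[l]]$W + velocity[[l]]$W
    params[[l]]$b <- params[[l]]$b + velocity[[l]]$b
  }
  list(params = params, velocity = velocity)
}

zero_velocity <- function(params) {
  lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
}

# optimizer state + step dispatch ("sgd" momentum SGD, "adam")
init_opt_state <- function(params, optimizer) {
  if (optimizer == "adam")
    list(m = zero_velocity(params), v = zero_velocity(params), t = 0L)
  else
    list(velocity = zero_velocity(params))
}

opt_step <- function(params, grads, state, control, lr) {
  if (control$optimizer == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    state$t <- state$t + 1L
    c1 <- 1 - b1^state$t
    c2 <- 1 - b2^state$t
    for (l in seq_along(params)) {
      for (f in c("W", "b")) {
        g <- grads[[l]][[f]]
        if (f == "W") g <- g + control$weight_decay * params[[l]][[f]]
        state$m[[l]][[f]] <- b1 * state$m[[l]][[f]] + (1 - b1) * g
        state$v[[l]][[f]] <- b2 * state$v[[l]][[f]] + (1 - b2) * g^2
        params[[l]][[f]] <- params[[l]][[f]] -
          lr * (state$m[[l]][[f]] / c1) /
          (sqrt(state$v[[l]][[f]] / c2) + eps)
      }
    }
    list(params = params, state = state)
  } else {
    st <- sgd_step(params, grads, state$velocity, lr, control$momentum,
                   control$weight_decay)
    list(params = st$params, state = list(velocity = st$velocity))
  }
}

#' Predict a contact map from a feature tensor
#'
#' Runs the network forward and returns the symmetric prediction. The
#' transpose-average construction makes P\[i, j\] and P\[j, i\] bitwise
#' equal. The reported `p` is the contact-class probability of the 3-class
#' softmax, without renormalization over the other classes.
#'
#' @param model A `contact_net`, `contact_fit` or `contact_ensemble`.
#' @param features L x L x C feature tensor (C must match the model's
#'   configuration).
#' @return An object of class `prediction_map`: list with `p` (L x L
#'   contact probabilities) and `probs3` (L x L x 3 class probabilities).
#' @export
predict_contact_map <- function(model, features) {
  if (inherits(model, "contact_ensemble"))
    return(ensemble_predict(model$members, features))
  stopifnot(inherits(model, "contact_net"))
  fw <- contact_forward(model$params, model$config, features)
  prediction_map(fw$pmap, probs3 = fw$probs)
}

#' Construct a prediction map
#'
#' @param p Symmetric L x L matrix of contact probabilities.
#' @param probs3 Optional L x L x 3 class-probability array.
#' @return An object of class `prediction_map`.
#' @export
prediction_map <- function(p, probs3 = NULL) {
  p <- as.matrix(p)
  if (nrow(p) != ncol(p)) stop("prediction map must be square")
  structure(list(p = p, probs3 = probs3, length = nrow(p)),
            class = "prediction_map")
}

#' @export
print.prediction_map <- function(x, ...) {
  cat(sprintf("<prediction_map> L = %d, %d positive pairs (P > 0.5)\n",
              x$length, nrow(positive_predictions(x, 0.5))))
  invisible(x)
}

# ---- 1D secondary-structure network -----------------------------------

ss_forward <- function(params, config, X, want_cache = FALSE) {
  if (ncol(X) != config$in_channels)
    stop("input has ", ncol(X), " channels, configuration expects ",
         config$in_channels)
  B <- config$blocks
  nl <- length(params)
  cache <- if (want_cache) list(blocks = vector("list", B)) else NULL
  Z0 <- conv1d_fw(X, params[[1L]]$W, params[[1L]]$b)
  A <- Z0 * (Z0 > 0)
  if (want_cache) { cache$X <- X; cache$A0 <- A }
  for (b in seq_len(B)) {
    l1 <- 2L * b; l2 <- 2L * b + 1L
    A_in <- A
    Z1 <- conv1d_fw(A_in, params[[l1]]$W, params[[l1]]$b)
    R1 <- Z1 * (Z1 > 0)
    Z2 <- conv1d_fw(R1, params[[l2]]$W, params[[l2]]$b)
    S <- Z2 + A_in
    A <- S * (S > 0)
    if (want_cache) cache$blocks[[b]] <- list(A_in = A_in, R1 = R1, A = A)
  }
  Z <- conv1d_fw(A, params[[nl]]$W, params[[nl]]$b)
  if (want_cache) cache$A_last <- A
  m <- apply(Z, 1L, max)
  e <- exp(Z - m)
  probs <- e / rowSums(e)
  list(probs = probs, logits = Z, cache = cache)
}

ss_backward <- function(params, config, cache, dlogits) {
  B <- config$blocks
  nl <- length(params)
  grads <- vector("list", nl)
  g <- conv1d_bw(cache$A_last, params[[nl]]$W, dlogits)
  grads[[nl]] <- list(W = g$dW, b = g$db)
  dA <- g$dX
  for (b in rev(seq_len(B))) {
    l1 <- 2L * b; l2 <- 2L * b + 1L
    bc <- cache$blocks[[b]]
    dS <- dA * (bc$A > 0)
    g2 <- conv1d_bw(bc$R1, params[[l2]]$W, dS)
    grads[[l2]] <- list(W = g2$dW, b = g2$db)
    dZ1 <- g2$dX * (bc$R1 > 0)
    g1 <- conv1d_bw(bc$A_in, params[[l1]]$W, dZ1)
    grads[[l1]] <- list(W = g1$dW, b = g1$db)
    dA <- g1$dX + dS
  }
  dZ0 <- dA * (cache$A0 > 0)
  g0 <- conv1d_bw(cache$X, params[[1L]]$W, dZ0)
  grads[[1L]] <- list(W = g0$dW, b = g0$db)
  grads
}

#' Encode the 1D input of the secondary-structure network
#'
#' Concatenates the positional profile with a 21-letter one-hot sequence
#' encoding (20 amino acids + X).
#'
#' @param target A [protein_record()].
#' @param profile L x 20 profile.
#' @return L x 41 numeric matrix.
#' @export
ss_input_features <- function(target, profile) {
  L <- target$length
  profile <- as.matrix(profile)
  stopifnot(nrow(profile) == L, ncol(profile) == 20L)
  seq <- strsplit(target$sequence, "")[[1]]
  onehot <- matrix(0, L, 21L)
  idx <- match(seq, c(.AA20, "X"))
  onehot[cbind(seq_len(L), idx)] <- 1
  cbind(profile, onehot)
}

#' Predict per-residue secondary-structure probabilities
#'
#' @param model An `ss_net` or `ss_fit`.
#' @param X L x C input matrix (see [ss_input_features()]).
#' @return L x 3 matrix of (helix, strand, coil) probabilities; rows sum
#'   to 1.
#' @export
predict_ss <- function(model, X) {
  stopifnot(inherits(model, "ss_net"))
  out <- ss_forward(model$params, model$config, X)$probs
  colnames(out) <- c("H", "E", "C")
  out
}
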