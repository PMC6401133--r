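# Model fitting: contact_fit() is the central estimator; train_control()
# collects optimizer settings; ensembles follow the 5-splits x 2-weights
# protocol with arithmetic-mean consensus.

#' Training control parameters
#'
#' Optimizer and schedule for [contact_fit()] and [ss_fit()]: momentum SGD
#' with L2 weight decay, batch size 1 (inputs have variable length), and a
#' mandatory root seed from which all randomness (initialization,
#' shuffling) derives.
#'
#' @param epochs Training epochs.
#' @param lr Initial learning rate (default 0.01).
#' @param lr_decay Multiplicative learning-rate decay per epoch (default
#'   1, no decay; e.g. 0.99 anneals the rate gently, which stabilizes
#'   long single-target runs).
#' @param momentum Momentum coefficient (default 0.9).
#' @param weight_decay L2 penalty on convolution weights (default 1e-4).
#' @param contact_weight Cross-entropy weight of the contact class
#'   (default 1; the ensemble protocol uses 1 and 4).
#' @param optimizer `"sgd"` (momentum SGD, the default) or `"adam"`.
#'   Adam is adaptive and much less step-size sensitive, which matters
#'   for long single-target runs where the batch-of-one gradient is not
#'   averaged over targets.
#' @param seed Integer root seed (mandatory).
#' @param shuffle Reshuffle target order each epoch.
#' @param verbose Print per-epoch losses.
#' @return An object of class `train_control`.
#' @export
train_control <- function(epochs = 30L, lr = 0.01, lr_decay = 1,
                          momentum = 0.9, weight_decay = 1e-4,
                          contact_weight = 1, optimizer = c("sgd", "adam"),
                          seed, shuffle = TRUE, verbose = FALSE) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("train_control requires an explicit seed")
  optimizer <- match.arg(optimizer)
  stopifnot(epochs >= 1L, lr > 0, lr_decay > 0, lr_decay <= 1,
            momentum >= 0, momentum < 1, weight_decay >= 0,
            contact_weight > 0)
  structure(list(epochs = as.integer(epochs), lr = lr, lr_decay = lr_decay,
                 momentum = momentum, weight_decay = weight_decay,
                 contact_weight = contact_weight, optimizer = optimizer,
                 seed = as.integer(seed), shuffle = isTRUE(shuffle),
                 verbose = isTRUE(verbose)),
            class = "train_control")
}

# normalize a training item into list(id, features, labels-matrix)
as_train_item <- function(item, config, what = "target") {
  if (is.null(item$features)) stop(what, " lacks a 'features' tensor")
  lab <- item$labels
  if (inherits(lab, "contact_map")) lab <- lab$states
  if (is.null(lab)) stop(what, " lacks 'labels'")
  d <- dim(item$features)
  if (length(d) != 3L || d[1L] != d[2L])
    stop(what, " features must be an L x L x C array")
  if (d[3L] != config$in_channels)
    stop(what, " has ", d[3L], " feature channels; configuration expects ",
         config$in_channels)
  if (!all(dim(lab) == d[1:2])) stop(what, " labels do not match features")
  list(id = if (is.null(item$id)) what else item$id,
       features = item$features, labels = lab)
}

#' Fit the fully convolutional residual contact network
#'
#' Trains the 3-class (non-contact / contact / ignored) contact network by
#' momentum SGD on weighted cross-entropy, one variable-length target per
#' step. Pairs labelled `ignored` are masked out of the loss. Training is
#' deterministic given `control$seed`.
#'
#' @param data List of training targets; each element is a list with
#'   `features` (L x L x C tensor, see [assemble_features()]) and `labels`
#'   (a [contact_map()] or L x L state matrix), optionally `id`.
#' @param config A [contact_net_config()].
#' @param control A [train_control()].
#' @param validation Optional list of held-out targets (same shape as
#'   `data`) whose loss is reported per epoch.
#' @return An object of class `c("contact_fit", "contact_net")` with the
#'   trained parameters, the configuration, the control settings and a
#'   per-epoch loss trace. Methods: [print()], [summary()], [coef()],
#'   [predict()], [plot()], [residuals()], [simulate()].
#' @examples
#' \donttest{
#' tgt <- generate_target(L = 30, seed = 7)
#' fit <- contact_fit(list(tgt), config = contact_net_config(filters = 8, blocks = 2),
#'                    control = train_control(epochs = 3, seed = 1))
#' predict(fit, tgt$features)
#' }
#' @export
contact_fit <- function(data, config = contact_net_config(),
                        control = train_control(seed = 1L),
                        validation = NULL) {
  stopifnot(inherits(config, "contact_net_config"),
            inherits(control, "train_control"))
  if (!is.list(data) || !length(data)) stop("data must be a non-empty list")
  items <- lapply(seq_along(data), function(k)
    as_train_item(data[[k]], config, paste0("target ", k)))
  usable <- vapply(items, function(it) any(it$labels != .STATE_IGNORED),
                   logical(1L))
  if (any(!usable))
    warning("skipping ", sum(!usable),
            " target(s) whose labels are entirely 'ignored'")
  items <- items[usable]
  if (!length(items)) stop("no trainable targets (all labels ignored)")
  val_items <- if (!is.null(validation))
    lapply(seq_along(validation), function(k)
      as_train_item(validation[[k]], config, paste0("validation target ", k)))

  set.seed(control$seed)
  params <- init_conv_params(config)
  opt <- init_opt_state(params, control$optimizer)
  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))
  for (ep in seq_len(control$epochs)) {
    lr_ep <- control$lr * control$lr_decay^(ep - 1L)
    ord <- if (control$shuffle) sample.int(length(items)) else seq_along(items)
    ep_loss <- 0
    for (k in ord) {
      it <- items[[k]]
      fw <- contact_forward(params, config, it$features, want_cache = TRUE)
      ls <- contact_loss(fw$probs, it$labels,
                         contact_weight = control$contact_weight)
      ep_loss <- ep_loss + ls$loss
      if (ls$n == 0L) next   # all ignored: zero loss, zero gradient
      grads <- contact_backward(params, config, fw$cache, ls$dlogits)
      st <- opt_step(params, grads, opt, control, lr_ep)
      params <- st$params
      opt <- st$state
    }
    vl <- NA_real_
    if (!is.null(val_items)) {
      vl <- mean(vapply(val_items, function(it) {
        fw <- contact_forward(params, config, it$features)
        contact_loss(fw$probs, it$labels,
                     contact_weight = control$contact_weight)$loss
      }, numeric(1L)))
    }
    trace <- rbind(trace, data.frame(epoch = ep,
                                     train_loss = ep_loss / length(items),
                                     val_loss = vl))
    if (control$verbose)
      message(sprintf("epoch %3d  train %.4f  val %s", ep,
                      ep_loss / length(items),
                      if (is.na(vl)) "-" else sprintf("%.4f", vl)))
  }
  structure(list(config = config, params = params, control = control,
                 loss = trace, n_targets = length(items),
                 target_ids = vapply(items, `[[`, character(1L), "id"),
                 call = match.call()),
            class = c("contact_fit", "contact_net"))
}

#' @export
print.contact_fit <- function(x, ...) {
  cat(sprintf(
    "Contact network fit: %d conv layers, %s parameters\n",
    n_conv_layers(x$config), format(n_parameters(x$config), big.mark = ",")))
  cat(sprintf("  trained on %d target(s), %d epochs, contact-class weight %g, seed %d\n",
              x$n_targets, x$control$epochs, x$control$contact_weight,
              x$control$seed))
  n <- nrow(x$loss)
  cat(sprintf("  final train loss %.4f%s\n", x$loss$train_loss[n],
              if (is.na(x$loss$val_loss[n])) ""
              else sprintf(", validation loss %.4f", x$loss$val_loss[n])))
  invisible(x)
}

#' @export
summary.contact_fit <- function(object, ...) {
  out <- list(config = object$config,
              n_conv_layers = n_conv_layers(object$config),
              n_parameters = n_parameters(object$config),
              n_targets = object$n_targets,
              control = object$control, loss = object$loss)
  class(out) <- "summary.contact_fit"
  out
}

#' @export
print.summary.contact_fit <- function(x, ...) {
  cat("Fully convolutional residual contact network\n")
  cat(sprintf("  input channels : %d\n", x$config$in_channels))
  cat(sprintf("  filters        : %d (3 x 3 kernels)\n", x$config$filters))
  cat(sprintf("  residual blocks: %d\n", x$config$blocks))
  cat(sprintf("  conv layers    : %d\n", x$n_conv_layers))
  cat(sprintf("  parameters     : %s\n", format(x$n_parameters, big.mark = ",")))
  cat(sprintf("  training       : %d target(s), %d epochs, lr %g, momentum %g, L2 %g, weight %g\n",
              x$n_targets, x$control$epochs, x$control$lr,
              x$control$momentum, x$control$weight_decay,
              x$control$contact_weight))
  n <- nrow(x$loss)
  if (n) cat(sprintf("  final loss     : train %.4f%s\n", x$loss$train_loss[n],
                     if (is.na(x$loss$val_loss[n])) ""
                     else sprintf(", val %.4f", x$loss$val_loss[n])))
  invisible(x)
}

#' @export
coef.contact_fit <- function(object, flatten = FALSE, ...) {
  if (!flatten) return(object$params)
  unlist(lapply(object$params, function(p) c(p$W, p$b)))
}

#' @export
predict.contact_net <- function(object, newdata, ...) {
  if (is.array(newdata) && length(dim(newdata)) == 3L)
    return(predict_contact_map(object, newdata))
  if (is.list(newdata) && !is.null(newdata$features))
    return(predict_contact_map(object, newdata$features))
  if (is.list(newdata))
    return(lapply(newdata, function(it)
      predict_contact_map(object, if (is.list(it)) it$features else it)))
  stop("newdata must be a feature tensor or a (list of) target(s)")
}

#' @export
plot.contact_fit <- function(x, ...) {
  plot(x$loss$epoch, x$loss$train_loss, type = "l", xlab = "epoch",
       ylab = "cross-entropy loss", main = "Training trace", ...)
  if (!all(is.na(x$loss$val_loss))) {
    lines(x$loss$epoch, x$loss$val_loss, lty = 2L)
    legend("topright", legend = c("train", "validation"), lty = 1:2,
           bty = "n")
  }
  invisible(x)
}

#' @export
residuals.contact_fit <- function(object, data, ...) {
  if (missing(data)) stop("supply the targets to compute residuals on")
  lapply(data, function(it) {
    it <- as_train_item(it, object$config)
    p <- predict_contact_map(object, it$features)$p
    obs <- (it$labels == .STATE_CONTACT) * 1
    r <- obs - p
    r[it$labels == .STATE_IGNORED] <- NA_real_
    r
  })
}

#' @export
simulate.contact_fit <- function(object, nsim = 1, seed = NULL, data, ...) {
  if (missing(data)) stop("supply the target(s) whose maps to simulate")
  if (!is.null(seed)) set.seed(seed)
  one <- function(features) {
    p <- predict_contact_map(object, features)$p
    L <- nrow(p)
    replicate(nsim, {
      u <- matrix(0, L, L)
      up <- upper.tri(p)
      u[up] <- runif(sum(up))
      m <- (u < p) & up
      (m | t(m)) * 1L
    }, simplify = FALSE)
  }
  if (is.array(data)) one(data)
  else lapply(data, function(it) one(if (is.list(it)) it$features else it))
}

# ---- ensemble protocol -------------------------------------------------

#' Plan the split/weight ensemble
#'
#' Splits the training ids `n_splits` times into a validation subset of
#' `validation_size` ids and a training remainder, under the constraint
#' that validation subsets are pairwise disjoint; each split is trained
#' once per contact-class weight, yielding `n_splits * length(weights)`
#' jobs (10 with the defaults).
#'
#' @param ids Character or integer vector of target ids.
#' @param n_splits Number of splits (default 5).
#' @param validation_size Ids per validation subset.
#' @param seed Integer seed for the partitioning.
#' @param weights Contact-class weights (default `c(1, 4)`).
#' @return An object of class `ensemble_plan`: list of jobs, each with
#'   `split`, `weight`, `train_ids`, `val_ids` and a derived `seed`.
#' @export
make_ensemble_splits <- function(ids, n_splits = 5L, validation_size,
                                 seed, weights = c(1, 4)) {
  stopifnot(length(ids) >= 2L, n_splits >= 1L, validation_size >= 1L)
  if (anyDuplicated(ids)) stop("ids must be unique")
  if (n_splits * validation_size > length(ids))
    stop("not enough ids for ", n_splits, " disjoint validation subsets of ",
         validation_size, " (have ", length(ids), ")")
  set.seed(seed)
  shuffled <- sample(ids)
  jobs <- list()
  for (s in seq_len(n_splits)) {
    val <- shuffled[((s - 1L) * validation_size + 1L):(s * validation_size)]
    train <- setdiff(ids, val)
    for (w in weights) {
      jobs[[length(jobs) + 1L]] <- list(
        split = s, weight = w, train_ids = train, val_ids = val,
        seed = (seed + 1000L * s + round(w)) %% .Machine$integer.max)
    }
  }
  structure(jobs, class = "ensemble_plan",
            seed = as.integer(seed), n_splits = as.integer(n_splits),
            validation_size = as.integer(validation_size))
}

#' @export
print.ensemble_plan <- function(x, ...) {
  cat(sprintf("<ensemble_plan> %d jobs (%d splits x weights {%s})\n",
              length(x), attr(x, "n_splits"),
              paste(unique(vapply(x, `[[`, numeric(1L), "weight")),
                    collapse = ", ")))
  invisible(x)
}

#' Train the split/weight ensemble
#'
#' @param data Named list of targets (names are the ids in the plan), each
#'   with `features` and `labels`.
#' @param plan An [make_ensemble_splits()] plan; built from `names(data)`
#'   when `NULL`.
#' @param config A [contact_net_config()].
#' @param control A [train_control()]; each job overrides its
#'   `contact_weight` and `seed` from the plan.
#' @param n_splits,validation_size,seed Used to build the plan when `plan`
#'   is `NULL`.
#' @return An object of class `contact_ensemble`.
#' @export
train_ensemble <- function(data, plan = NULL,
                           config = contact_net_config(),
                           control = train_control(seed = 1L),
                           n_splits = 5L, validation_size = NULL,
                           seed = control$seed) {
  if (is.null(names(data)) || anyDuplicated(names(data)))
    stop("data must be a named list with unique target ids")
  if (is.null(plan)) {
    if (is.null(validation_size))
      validation_size <- max(1L, floor(length(data) / (2L * n_splits)))
    plan <- make_ensemble_splits(names(data), n_splits = n_splits,
                                 validation_size = validation_size,
                                 seed = seed)
  }
  members <- lapply(plan, function(job) {
    ctl <- control
    ctl$contact_weight <- job$weight
    ctl$seed <- job$seed
    contact_fit(data[job$train_ids], config = config, control = ctl,
                validation = data[job$val_ids])
  })
  structure(list(members = members, plan = plan, config = config),
            class = "contact_ensemble")
}

#' @export
print.contact_ensemble <- function(x, ...) {
  cat(sprintf("<contact_ensemble> %d members (arithmetic-mean consensus)\n",
              length(x$members)))
  invisible(x)
}

#' Arithmetic-mean consensus prediction of an ensemble
#'
#' @param models List of `contact_net`/`contact_fit` members sharing one
#'   configuration.
#' @param features L x L x C feature tensor.
#' @return A [prediction_map()]: the element-wise mean of the members'
#'   probability maps.
#' @export
ensemble_predict <- function(models, features) {
  if (inherits(models, "contact_ensemble")) models <- models$members
  stopifnot(is.list(models), length(models) >= 1L)
  preds <- lapply(models, function(m) predict_contact_map(m, features))
  L <- preds[[1L]]$length
  if (!all(vapply(preds, `[[`, integer(1L), "length") == L))
    stop("ensemble members produced maps of different sizes")
  p <- Reduce(`+`, lapply(preds, `[[`, "p")) / length(preds)
  probs3 <- Reduce(`+`, lapply(preds, `[[`, "probs3")) / length(preds)
  prediction_map(p, probs3 = probs3)
}

#' @export
predict.contact_ensemble <- function(object, newdata, ...) {
  if (is.array(newdata) && length(dim(newdata)) == 3L)
    return(ensemble_predict(object$members, newdata))
  if (is.list(newdata) && !is.null(newdata$features))
    return(ensemble_predict(object$members, newdata$features))
  lapply(newdata, function(it)
    ensemble_predict(object$members, if (is.list(it)) it$features else it))
}

#' Training manifest of an ensemble
#'
#' @param ensemble A [train_ensemble()] result.
#' @return A list (JSON-ready) recording splits, weights and seeds.
#' @export
ensemble_manifest <- function(ensemble) {
  stopifnot(inherits(ensemble, "contact_ensemble"))
  list(n_members = length(ensemble$members),
       config = unclass(ensemble$config),
       jobs = lapply(ensemble$plan, function(j)
         list(split = j$split, weight = j$weight, seed = j$seed,
              n_train = length(j$train_ids), n_val = length(j$val_ids),
              val_ids = j$val_ids)))
}

# ---- secondary-structure fit ------------------------------------------

#' Fit the 1D secondary-structure network
#'
#' @param data List of items, each with `x` (L x C input,
#'   [ss_input_features()]) and `y` (length-L labels: integers 1..3 or
#'   letters in H/E/C).
#' @param config An [ss_net_config()].
#' @param control A [train_control()] (the contact-class weight is
#'   ignored).
#' @return An object of class `c("ss_fit", "ss_net")`.
#' @export
ss_fit <- function(data, config = ss_net_config(),
                   control = train_control(seed = 1L)) {
  stopifnot(inherits(config, "ss_net_config"), length(data) >= 1L)
  items <- lapply(data, function(it) {
    y <- it$y
    if (is.character(y)) y <- match(y, c("H", "E", "C"))
    if (anyNA(y)) stop("secondary-structure labels must be 1..3 or H/E/C")
    list(x = as.matrix(it$x), y = as.integer(y))
  })
  set.seed(control$seed)
  params <- init_conv_params(config)
  opt <- init_opt_state(params, control$optimizer)
  trace <- numeric(control$epochs)
  for (ep in seq_len(control$epochs)) {
    ord <- if (control$shuffle) sample.int(length(items)) else seq_along(items)
    ep_loss <- 0
    for (k in ord) {
      it <- items[[k]]
      fw <- ss_forward(params, config, it$x, want_cache = TRUE)
      L <- nrow(it$x)
      onehot <- matrix(0, L, config$out_channels)
      onehot[cbind(seq_len(L), it$y)] <- 1
      p_true <- fw$probs[cbind(seq_len(L), it$y)]
      ep_loss <- ep_loss + mean(-log(p_true + 1e-12))
      dlogits <- (fw$probs - onehot) / L
      grads <- ss_backward(params, config, fw$cache, dlogits)
      st <- opt_step(params, grads, opt, control,
                     control$lr * control$lr_decay^(ep - 1L))
      params <- st$params
      opt <- st$state
    }
    trace[ep] <- ep_loss / length(items)
    if (control$verbose) message(sprintf("epoch %3d  loss %.4f", ep, trace[ep]))
  }
  structure(list(config = config, params = params, control = control,
                 loss = data.frame(epoch = seq_len(control$epochs),
                                   train_loss = trace)),
            class = c("ss_fit", "ss_net"))
}

#' @export
print.ss_fit <- function(x, ...) {
  cat(sprintf("<ss_fit> %d conv layers (1D), final loss %.4f\n",
              n_conv_layers(x$config), tail(x$loss$train_loss, 1L)))
  invisible(x)
}

#' @export
predict.ss_net <- function(object, newdata, ...) {
  predict_ss(object, newdata)
}
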