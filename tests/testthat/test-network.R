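small_cfg <- contact_net_config(filters = 8L, blocks = 2L)

test_that("the default architecture has 40 conv layers and the closed-form parameter count", {
  cfg <- contact_net_config()
  expect_identical(n_conv_layers(cfg), 40L)
  closed <- (3 * 3 * 51 * 64 + 64) + 19 * 2 * (3 * 3 * 64 * 64 + 64) +
    (3 * 3 * 64 * 3 + 3)
  expect_identical(n_parameters(cfg), closed)
  # the built model's actual parameter vectors agree with the formula
  net <- build_contact_network(contact_net_config(filters = 4L, blocks = 3L),
                               seed = 1L)
  actual <- sum(vapply(net$params, function(p) length(p$W) + length(p$b),
                       numeric(1L)))
  expect_identical(actual,
                   as.numeric(n_parameters(contact_net_config(filters = 4L,
                                                              blocks = 3L))))
  expect_error(contact_net_config(filters = 0L), ">= 1")
})

test_that("zeroed final weights give the uniform 3-class softmax", {
  net <- build_contact_network(small_cfg, seed = 2L, zero_final = TRUE)
  X <- array(rnorm(7L * 7L * 51L), c(7L, 7L, 51L))
  pm <- predict_contact_map(net, X)
  expect_true(all(abs(pm$probs3 - 1 / 3) < 1e-12))
  expect_true(all(abs(pm$p - 1 / 3) < 1e-12))
})

test_that("predictions are bitwise symmetric, normalized, and deterministic", {
  for (seed in 1:5) {
    net <- build_contact_network(small_cfg, seed = seed)
    L <- sample(4:16, 1L)
    X <- array(rnorm(L * L * 51L), c(L, L, 51L))
    pm <- predict_contact_map(net, X)
    expect_identical(pm$p, t(pm$p))                       # exact, bitwise
    tot <- pm$probs3[, , 1L] + pm$probs3[, , 2L] + pm$probs3[, , 3L]
    expect_true(all(abs(tot - 1) < 1e-6))
    expect_true(all(pm$p >= 0 & pm$p <= 1))
    expect_identical(pm$p, predict_contact_map(net, X)$p) # deterministic
  }
  net <- build_contact_network(small_cfg, seed = 1L)
  bad <- array(0, c(5L, 5L, 50L))
  expect_error(predict_contact_map(net, bad), "channels")
})

test_that("an all-ignored label map yields zero loss and zero gradient", {
  loss_fn <- contactnet:::contact_loss
  net <- build_contact_network(small_cfg, seed = 3L)
  X <- array(rnorm(6L * 6L * 51L), c(6L, 6L, 51L))
  fw <- contactnet:::contact_forward(net$params, small_cfg, X,
                                     want_cache = TRUE)
  lab <- matrix(2L, 6L, 6L)
  ls <- loss_fn(fw$probs, lab)
  expect_identical(ls$loss, 0)
  expect_true(all(ls$dlogits == 0))
  # and contact_fit skips such targets with a warning
  ok <- list(features = X, labels = matrix(0L, 6L, 6L))
  bad <- list(features = X, labels = lab)
  expect_warning(
    contact_fit(list(ok, bad), config = small_cfg,
                control = train_control(epochs = 1L, seed = 1L)),
    "ignored")
  expect_error(
    suppressWarnings(contact_fit(list(bad), config = small_cfg,
                                 control = train_control(epochs = 1L, seed = 1L))),
    "no trainable targets")
})

test_that("training is deterministic given the seed", {
  tgt <- generate_target(L = 30L, seed = 21L, depth = 40L)
  ctl <- train_control(epochs = 3L, seed = 9L)
  f1 <- contact_fit(list(tgt), config = small_cfg, control = ctl)
  f2 <- contact_fit(list(tgt), config = small_cfg, control = ctl)
  expect_identical(coef(f1, flatten = TRUE), coef(f2, flatten = TRUE))
  expect_identical(f1$loss, f2$loss)
})

test_that("ensemble consensus is the arithmetic mean of member maps", {
  nets <- lapply(1:10, function(s) build_contact_network(small_cfg, seed = s))
  X <- array(rnorm(9L * 9L * 51L), c(9L, 9L, 51L))
  cons <- ensemble_predict(nets, X)
  # explicit summation oracle
  acc <- matrix(0, 9L, 9L)
  for (n in nets) acc <- acc + predict_contact_map(n, X)$p
  expect_equal(cons$p, acc / 10, tolerance = 1e-15)
  # identical members: mean equals any member
  same <- ensemble_predict(list(nets[[1L]], nets[[1L]]), X)
  expect_identical(same$p, predict_contact_map(nets[[1L]], X)$p)
  # pairwise mean at a single pair: members disagreeing at p and q give (p+q)/2
  two <- ensemble_predict(nets[1:2], X)
  expect_equal(two$p[2L, 5L],
               (predict_contact_map(nets[[1L]], X)$p[2L, 5L] +
                predict_contact_map(nets[[2L]], X)$p[2L, 5L]) / 2)
})

test_that("ensemble splits are disjoint and yield 5 x 2 jobs", {
  ids <- sprintf("t%04d", 1:4000)
  plan <- make_ensemble_splits(ids, n_splits = 5L, validation_size = 800L,
                               seed = 1L)
  expect_length(plan, 10L)
  vals <- unique(lapply(plan, `[[`, "val_ids"))
  expect_length(vals, 5L)
  for (a in seq_along(vals)) {
    expect_length(vals[[a]], 800L)
    for (b in seq_along(vals))
      if (a != b) expect_length(intersect(vals[[a]], vals[[b]]), 0L)
  }
  expect_setequal(vapply(plan, `[[`, numeric(1L), "weight"), c(1, 4))
  expect_error(make_ensemble_splits(ids[1:10], n_splits = 5L,
                                    validation_size = 800L, seed = 1L),
               "not enough ids")
})

test_that("the 1D secondary-structure network outputs normalized 3-state rows", {
  cfg <- ss_net_config(filters = 8L, blocks = 2L)
  net <- build_ss_network(cfg, seed = 4L)
  x1 <- matrix(rnorm(41L), 1L, 41L)
  p1 <- predict_ss(net, x1)
  expect_identical(dim(p1), c(1L, 3L))
  expect_equal(sum(p1), 1, tolerance = 1e-9)
  for (L in c(5L, 23L)) {
    x <- matrix(rnorm(L * 41L), L, 41L)
    p <- predict_ss(net, x)
    expect_identical(dim(p), c(L, 3L))
    expect_equal(rowSums(p), rep(1, L), tolerance = 1e-9)
  }
  expect_identical(n_conv_layers(ss_net_config()), 10L)
})

test_that("the secondary-structure network can overfit labeled toy folds", {
  tgts <- lapply(1:3, function(k) generate_target(L = 40L, seed = 300L + k,
                                                  depth = 40L,
                                                  features = FALSE))
  data <- lapply(tgts, function(tg)
    list(x = ss_input_features(tg$record, compute_profile(tg$aln)),
         y = tg$ss_labels))
  fit <- ss_fit(data, config = ss_net_config(filters = 16L, blocks = 2L),
                control = train_control(epochs = 150L, lr = 0.05, seed = 2L))
  acc <- mean(unlist(lapply(data, function(it) {
    pred <- max.col(predict(fit, it$x))
    pred == match(it$y, c("H", "E", "C"))
  })))
  expect_gte(acc, 0.9)
})
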