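mm <- asNamespace("megamorph")

test_that("backpropagated gradients match numeric differentiation", {
  set.seed(42)
  params <- mm$nn_init(c(2, 3), 3, seed = 9, hidden = 5)
  params$feat_norm <- list(mu = rnorm(2 * 3 + mm$N_MOMENT_FEATURES, 0, 0.1),
                           sd = runif(2 * 3 + mm$N_MOMENT_FEATURES, 0.5, 2))
  params$skip$W[] <- rnorm(length(params$skip$W), 0, 0.3)
  X <- array(runif(8 * 8 * 4), c(8, 8, 4, 1))
  y <- c(1, 2, 3, 2)
  loss_fn <- function(p) mm$ce_loss_grad(mm$nn_forward(p, X)$logits, y)$loss
  fwd <- mm$nn_forward(params, X, keep = TRUE)
  gr <- mm$nn_backward(params, fwd, mm$ce_loss_grad(fwd$logits, y)$grad)
  check <- function(set, g) {
    for (i in sample(length(g), min(3, length(g)))) {
      eps <- 1e-6
      num <- (loss_fn(set(params, i, eps)) - loss_fn(set(params, i, -eps))) /
        (2 * eps)
      expect_lt(abs(num - g[i]), 1e-7)
    }
  }
  check(function(p, i, e) { p$conv[[1]]$W[i] <- p$conv[[1]]$W[i] + e; p },
        gr$conv[[1]]$W)
  check(function(p, i, e) { p$conv[[2]]$W[i] <- p$conv[[2]]$W[i] + e; p },
        gr$conv[[2]]$W)
  check(function(p, i, e) { p$conv[[1]]$b[i] <- p$conv[[1]]$b[i] + e; p },
        gr$conv[[1]]$b)
  check(function(p, i, e) { p$head1$W[i] <- p$head1$W[i] + e; p }, gr$head1$W)
  check(function(p, i, e) { p$head2$W[i] <- p$head2$W[i] + e; p }, gr$head2$W)
  check(function(p, i, e) { p$skip$W[i] <- p$skip$W[i] + e; p }, gr$skip$W)

  # regression branch (L1 loss)
  t <- rnorm(4)
  pr <- mm$nn_init(c(2, 3), 1, seed = 3, hidden = 5)
  lf <- function(p) mm$l1_loss_grad(mm$nn_forward(p, X)$logits, t)$loss
  fwd1 <- mm$nn_forward(pr, X, keep = TRUE)
  gr1 <- mm$nn_backward(pr, fwd1, mm$l1_loss_grad(fwd1$logits, t)$grad)
  i <- 5; eps <- 1e-6
  pp <- pr; pp$conv[[1]]$W[i] <- pp$conv[[1]]$W[i] + eps
  pm <- pr; pm$conv[[1]]$W[i] <- pm$conv[[1]]$W[i] - eps
  expect_lt(abs((lf(pp) - lf(pm)) / (2 * eps) - gr1$conv[[1]]$W[i]), 1e-7)
})

test_that("convolution matches a direct nested-loop reference", {
  set.seed(3)
  X <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  W <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  Y <- mm$conv_forward(X, W, b)$Y
  ref <- array(0, c(6, 6, 2, 3))
  for (i in 1:6) for (j in 1:6) for (n in 1:2) for (o in 1:3) {
    acc <- b[o]
    for (di in -1:1) for (dj in -1:1) for (c in 1:2) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= 6 && jj >= 1 && jj <= 6) {
        acc <- acc + X[ii, jj, n, c] * W[di + 2, dj + 2, c, o]
      }
    }
    ref[i, j, n, o] <- acc
  }
  expect_equal(Y, ref, tolerance = 1e-12)
})

test_that("moment descriptors measure silhouette size and shape", {
  # a centered bright disk: ax_major ~ ax_minor ~ r/(2H) scale
  H <- 32
  img <- matrix(0, H, H)
  xs <- matrix(rep(seq_len(H), each = H), H, H) - 16.5
  ys <- matrix(rep(seq_len(H), H), H, H) - 16.5
  img[xs^2 + ys^2 <= 8^2] <- 0.9
  X <- array(img - 0.15, c(H, H, 1, 1))
  f <- mm$input_moment_features(X)
  expect_equal(unname(f[1, "ax_major"]), unname(f[1, "ax_minor"]),
               tolerance = 0.05)
  # a horizontal bar: major >> minor, rmax ~ half length
  img2 <- matrix(0, H, H)
  img2[15:18, 5:28] <- 0.9
  X2 <- array(img2 - 0.15, c(H, H, 1, 1))
  f2 <- mm$input_moment_features(X2)
  expect_gt(f2[1, "ax_major"] / f2[1, "ax_minor"], 3)
  expect_equal(unname(f2[1, "rmax"]) * H, 12, tolerance = 1.5)
  # invariance under the augmentation pool
  for (type in mm$AUG_TRIVIAL) {
    Xa <- X2
    Xa[, , 1, 1] <- mm$augment_image(X2[, , 1, 1], type, mag = 0.8)
    if (type == "scale") next        # scale jitter is size-changing
    expect_equal(mm$input_moment_features(Xa)[1, ], f2[1, ],
                 tolerance = 1e-9)
  }
})

test_that("augmentations compose as lattice symmetries", {
  img <- matrix(runif(36), 6, 6)
  r90 <- mm$augment_image(img, "rot90")
  expect_equal(mm$augment_image(r90, "rot90"),
               mm$augment_image(img, "rot180"))
  expect_equal(mm$augment_image(mm$augment_image(img, "hflip"), "hflip"), img)
  expect_equal(mm$augment_image(img, "rot270"),
               mm$augment_image(mm$augment_image(img, "rot180"), "rot90"))
})

test_that("training is deterministic and checkpoints at min val loss", {
  set.seed(1)
  n <- 24
  images <- array(runif(16 * 16 * n, 0, 0.2), c(16, 16, n))
  for (k in 1:n) {
    if (k %% 2 == 0) images[6:11, 6:11, k] <- 0.9 else images[8:9, 4:13, k] <- 0.9
  }
  y <- rep(1:2, n / 2)
  tr <- 1:16; va <- 17:20
  f1 <- mm$nn_train(images, y, tr, va, 2, "classify", c(2, 3), epochs = 3,
                    lr = 1e-2, batch_size = 8, weight_decay = 0.01,
                    augment_policy = "trivial", seed = 5)
  f2 <- mm$nn_train(images, y, tr, va, 2, "classify", c(2, 3), epochs = 3,
                    lr = 1e-2, batch_size = 8, weight_decay = 0.01,
                    augment_policy = "trivial", seed = 5)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loss_curve, f2$loss_curve)
  expect_equal(f1$checkpoint_epoch,
               which.min(f1$loss_curve$val_loss))
})

test_that("a frozen base stays bit-identical through training", {
  set.seed(2)
  n <- 16
  images <- array(runif(16 * 16 * n, 0, 0.2), c(16, 16, n))
  targets <- log1p(stats::rlnorm(n, 1, 1))
  base <- mm$nn_init(c(2, 3), 2, seed = 7)
  probe <- mm$avg_backbone_probe(base, mm$make_batch(images, 1:8, "none"))
  base$feat_norm <- list(mu = colMeans(probe),
                         sd = pmax(apply(probe, 2, stats::sd), 1e-6))
  before <- base$conv
  fit <- mm$nn_train(images, targets, 1:12, 13:16, 1, "regress", c(2, 3),
                     epochs = 2, lr = 1e-2, batch_size = 8,
                     weight_decay = 0.01, augment_policy = "geometric",
                     seed = 5, base_params = base, frozen_base = TRUE)
  expect_identical(fit$params$conv, before)
  # unfrozen training changes the base
  fit2 <- mm$nn_train(images, targets, 1:12, 13:16, 1, "regress", c(2, 3),
                      epochs = 2, lr = 1e-2, batch_size = 8,
                      weight_decay = 0.01, augment_policy = "geometric",
                      seed = 5, base_params = base, frozen_base = FALSE)
  expect_false(identical(fit2$params$conv, before))
})
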