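# Lightweight convolutional network engine.
#
# Arrays are laid out (H, W, N, C) so that flattening to a
# [H*W*N, C] matrix is free; a same-padded 3x3 convolution is then nine
# shifted matrix multiplications against [Cin, Cout] weight slices,
# which keeps every heavy operation inside BLAS. The backbone is a stem
# average-pool followed by conv(3x3) + ReLU + average-pool blocks and a
# global average pool; heads are single dense layers. Average pooling
# (rather than max) keeps gradients exact and training bit-reproducible.

# ---- array primitives -----------------------------------------------------

# Same-padded 3x3 convolution via im2col: one cached index gather turns
# the padded input into a [H*W*N, 9*Cin] matrix whose product with the
# reshaped kernel is the whole convolution. Column order is channel
# fastest, then di, then dj, matching aperm(W, c(3, 1, 2, 4)).

.im2col_cache <- new.env(parent = emptyenv())

im2col_idx <- function(H, W_, N, C) {
  key <- paste(H, W_, N, C, sep = "x")
  cached <- .im2col_cache[[key]]
  if (!is.null(cached)) return(cached)
  Hp <- H + 2; Wp <- W_ + 2
  iv <- rep(seq_len(H), times = W_ * N)
  jv <- rep(rep(seq_len(W_), each = H), times = N)
  nv <- rep(seq_len(N), each = H * W_)
  b0 <- iv + 1 + Hp * jv + Hp * Wp * (nv - 1)
  offs <- as.vector(vapply(-1:1, function(dj) {
    vapply(-1:1, function(di) di + Hp * dj + Hp * Wp * N * (seq_len(C) - 1),
           numeric(C))
  }, matrix(0, C, 3)))
  idx <- outer(b0, offs, "+")
  storage.mode(idx) <- "integer"
  if (length(idx) < 4e6) .im2col_cache[[key]] <- idx
  idx
}

pad_hw <- function(X) {
  d <- dim(X)
  Xp <- array(0, c(d[1] + 2, d[2] + 2, d[3], d[4]))
  Xp[2:(d[1] + 1), 2:(d[2] + 1), , ] <- X
  Xp
}

conv_w9 <- function(W) {
  d <- dim(W)
  matrix(aperm(W, c(3, 1, 2, 4)), 9 * d[3], d[4])
}

conv_forward <- function(X, W, b) {
  d <- dim(X)
  cin <- d[4]; cout <- dim(W)[4]
  rows <- d[1] * d[2] * d[3]
  Xcol <- pad_hw(X)[im2col_idx(d[1], d[2], d[3], cin)]
  dim(Xcol) <- c(rows, 9 * cin)
  Y <- Xcol %*% conv_w9(W)
  Y <- Y + matrix(b, rows, cout, byrow = TRUE)
  list(Y = array(Y, c(d[1], d[2], d[3], cout)), Xcol = Xcol, in_dim = d)
}

conv_backward <- function(Xcol, in_dim, W, dY) {
  d <- in_dim
  cin <- d[4]; cout <- dim(W)[4]
  rows <- d[1] * d[2] * d[3]
  dYm <- dY
  dim(dYm) <- c(rows, cout)
  dW9 <- crossprod(Xcol, dYm)
  dW <- aperm(array(dW9, c(cin, 3, 3, cout)), c(2, 3, 1, 4))
  dXcol <- tcrossprod(dYm, conv_w9(W))
  dXp <- array(0, c(d[1] + 2, d[2] + 2, d[3], cin))
  k <- 0L
  for (dj in -1:1) for (di in -1:1) {
    blk <- dXcol[, k * cin + seq_len(cin), drop = FALSE]
    dim(blk) <- c(d[1], d[2], d[3], cin)
    ii <- (2:(d[1] + 1)) + di
    jj <- (2:(d[2] + 1)) + dj
    dXp[ii, jj, , ] <- dXp[ii, jj, , , drop = FALSE] + blk
    k <- k + 1L
  }
  list(dX = dXp[2:(d[1] + 1), 2:(d[2] + 1), , , drop = FALSE],
       dW = dW, db = colSums(dYm))
}

avgpool2 <- function(X) {
  d <- dim(X)
  io <- seq(1, d[1], 2); jo <- seq(1, d[2], 2)
  (X[io, jo, , , drop = FALSE] + X[io + 1, jo, , , drop = FALSE] +
     X[io, jo + 1, , , drop = FALSE] + X[io + 1, jo + 1, , , drop = FALSE]) / 4
}

avgpool2_backward <- function(dY, in_dim) {
  dX <- array(0, in_dim)
  io <- seq(1, in_dim[1], 2); jo <- seq(1, in_dim[2], 2)
  g <- dY / 4
  dX[io, jo, , ] <- g
  dX[io + 1, jo, , ] <- g
  dX[io, jo + 1, , ] <- g
  dX[io + 1, jo + 1, , ] <- g
  dX
}

# global pooling: per-channel mean and root-mean-square. The RMS
# channel carries a second-order statistic, which helps the head build
# ratio/log-like quantities (area fractions, contour densities) that
# separate the silhouette classes; both are invariant to the flip and
# lattice-rotation augmentations.
gap_forward <- function(X) {
  d <- dim(X)
  M <- X
  dim(M) <- c(d[1] * d[2], d[3] * d[4])
  mu <- matrix(colMeans(M), d[3], d[4])
  ms <- matrix(colMeans(M^2), d[3], d[4])
  list(feats = cbind(mu, sqrt(ms + 1e-8)), rms = sqrt(ms + 1e-8))
}

gap_backward <- function(dF, X, rms) {
  d <- dim(X)
  hw <- d[1] * d[2]
  C <- d[4]
  dmu <- dF[, seq_len(C), drop = FALSE]
  drms <- dF[, C + seq_len(C), drop = FALSE]
  ds <- drms * 0.5 / rms                       # d(loss)/d(mean square)
  dX <- array(rep(as.vector(dmu), each = hw) / hw, d)
  dX + X * array(rep(as.vector(ds), each = hw), d) * (2 / hw)
}

# ---- parameter containers -------------------------------------------------

nn_init <- function(channels, n_out, seed, hidden = 32L) {
  with_substream(seed, "init", {
    cin <- 1L
    conv <- lapply(channels, function(cout) {
      W <- array(stats::rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                 c(3, 3, cin, cout))
      p <- list(W = W, b = numeric(cout))
      cin <<- cout
      p
    })
    nf <- 2L * cin + N_MOMENT_FEATURES   # mean + rms per channel + moments
    list(
      conv = conv,
      head1 = list(W = matrix(stats::rnorm(nf * hidden, 0, sqrt(2 / nf)),
                              nf, hidden),
                   b = numeric(hidden)),
      head2 = list(W = matrix(stats::rnorm(hidden * n_out, 0,
                                           sqrt(2 / hidden)),
                              hidden, n_out),
                   b = numeric(n_out)),
      # zero-initialized linear shortcut from the standardized features
      # to the output: the low-variance linear solution is reachable
      # without going through the hidden layer
      skip = list(W = matrix(0, nf, n_out))
    )
  })
}

nn_forward <- function(params, X, keep = FALSE) {
  acts <- list()
  A <- avgpool2(X)                                   # stem pool
  for (l in seq_along(params$conv)) {
    cf <- conv_forward(A, params$conv[[l]]$W, params$conv[[l]]$b)
    Z <- cf$Y
    if (keep) {
      acts[[paste0("xcol", l)]] <- cf$Xcol
      acts[[paste0("indim", l)]] <- cf$in_dim
      acts[[paste0("z", l)]] <- Z
    }
    R <- pmax(Z, 0)
    A <- avgpool2(R)
    if (keep) acts[[paste0("rdim", l)]] <- dim(R)
  }
  acts$gap_in <- A
  gp <- gap_forward(A)
  feats <- cbind(gp$feats, input_moment_features(X))
  if (!is.null(params$feat_norm)) {
    feats <- sweep(sweep(feats, 2, params$feat_norm$mu, "-"), 2,
                   params$feat_norm$sd, "/")
    acts$feat_mask <- abs(feats) < FEAT_CLIP
    # winsorize: a frame far outside the probe range must not blow up
    # the (non-saturating) L1 head updates
    feats <- pmin(pmax(feats, -FEAT_CLIP), FEAT_CLIP)
  }
  n <- nrow(feats)
  z1 <- feats %*% params$head1$W +
    matrix(params$head1$b, n, length(params$head1$b), byrow = TRUE)
  a1 <- pmax(z1, 0)
  logits <- a1 %*% params$head2$W + feats %*% params$skip$W +
    matrix(params$head2$b, n, length(params$head2$b), byrow = TRUE)
  acts$rms <- gp$rms
  acts$head_z <- z1
  acts$head_a <- a1
  list(logits = logits, feats = feats, acts = acts)
}

nn_backward <- function(params, fwd, dlogits, frozen_base = FALSE) {
  grads <- list(head2 = list(
    W = crossprod(fwd$acts$head_a, dlogits),
    b = colSums(dlogits)
  ))
  grads$skip <- list(W = crossprod(fwd$feats, dlogits))
  da1 <- tcrossprod(dlogits, params$head2$W)
  dz1 <- da1 * (fwd$acts$head_z > 0)
  grads$head1 <- list(W = crossprod(fwd$feats, dz1), b = colSums(dz1))
  if (frozen_base) {
    grads$conv <- NULL
    return(grads)
  }
  dfeats <- tcrossprod(dz1, params$head1$W) +
    tcrossprod(dlogits, params$skip$W)
  if (!is.null(params$feat_norm)) {
    dfeats <- dfeats * fwd$acts$feat_mask     # clipped features: no grad
    dfeats <- sweep(dfeats, 2, params$feat_norm$sd, "/")
  }
  npool <- ncol(dfeats) - N_MOMENT_FEATURES  # moment features: no gradient
  dA <- gap_backward(dfeats[, seq_len(npool), drop = FALSE],
                     fwd$acts$gap_in, fwd$acts$rms)
  grads$conv <- vector("list", length(params$conv))
  for (l in rev(seq_along(params$conv))) {
    dR <- avgpool2_backward(dA, fwd$acts[[paste0("rdim", l)]])
    dZ <- dR * (fwd$acts[[paste0("z", l)]] > 0)
    cb <- conv_backward(fwd$acts[[paste0("xcol", l)]],
                        fwd$acts[[paste0("indim", l)]],
                        params$conv[[l]]$W, dZ)
    grads$conv[[l]] <- list(W = cb$dW, b = cb$db)
    dA <- cb$dX
  }
  grads
}

# ---- AdamW ----------------------------------------------------------------

adamw_state <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         how = "list", classes = "ANY")
}

# weight_decay may be a scalar or a named list with per-group values
# (conv, mlp, skip): the high-capacity hidden branch needs far more
# shrinkage than the linear shortcut on datasets with few specimens
adamw_step <- function(params, grads, state, step, lr, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  wd <- if (is.list(weight_decay)) {
    weight_decay
  } else {
    list(conv = weight_decay, mlp = weight_decay, skip = weight_decay)
  }
  upd <- function(p, g, s, decay) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^step)
    vhat <- s$v / (1 - beta2^step)
    p <- p - lr * (mhat / (sqrt(vhat) + eps) + decay * p)
    list(p = p, s = s)
  }
  for (l in seq_along(grads$conv %||% list())) {
    for (nm in c("W", "b")) {
      r <- upd(params$conv[[l]][[nm]], grads$conv[[l]][[nm]],
               state$conv[[l]][[nm]],
               if (nm == "W") wd$conv else 0)   # biases are not decayed
      params$conv[[l]][[nm]] <- r$p
      state$conv[[l]][[nm]] <- r$s
    }
  }
  for (hd in c("head1", "head2")) {
    if (is.null(grads[[hd]])) next
    for (nm in c("W", "b")) {
      r <- upd(params[[hd]][[nm]], grads[[hd]][[nm]], state[[hd]][[nm]],
               if (nm == "W") wd$mlp else 0)
      params[[hd]][[nm]] <- r$p
      state[[hd]][[nm]] <- r$s
    }
  }
  if (!is.null(grads$skip)) {
    r <- upd(params$skip$W, grads$skip$W, state$skip$W, wd$skip)
    params$skip$W <- r$p
    state$skip$W <- r$s
  }
  list(params = params, state = state)
}

# Global moment descriptors of the raw input silhouette: foreground
# area fraction and the major/minor axis lengths from the eigenvalues
# of the spatial second-moment (covariance) matrix of the bright
# pixels. Rotation-invariant analogues of the imaging device's own
# size features; they enter the head alongside the learned pooled
# features and need no gradient (nothing upstream of the input is
# trainable).
input_moment_features <- function(X) {
  d <- dim(X)
  H <- d[1]; W_ <- d[2]; N <- d[3]
  M <- X
  dim(M) <- c(H * W_, N)
  w <- (M > 0.25) * 1   # hard foreground mask: invariant to the
                        # brightness/contrast augmentations, which keep
                        # silhouette pixels well above this cut
  iv <- rep(seq_len(H), times = W_) / H
  jv <- rep(seq_len(W_), each = H) / H
  q <- colSums(w) + 1e-8
  ci <- colSums(w * iv) / q
  cj <- colSums(w * jv) / q
  mii <- colSums(w * iv^2) / q - ci^2
  mjj <- colSums(w * jv^2) / q - cj^2
  mij <- colSums(w * iv * jv) / q - ci * cj
  tr2 <- (mii + mjj) / 2
  disc <- sqrt(pmax((mii - mjj)^2 / 4 + mij^2, 0))
  # edge density: mean absolute forward difference, a perimeter proxy
  Wmat <- w
  dim(Wmat) <- c(H, W_, N)
  ed <- (colSums(colSums(abs(Wmat[-1, , , drop = FALSE] -
                               Wmat[-H, , , drop = FALSE]))) +
           colSums(colSums(abs(Wmat[, -1, , drop = FALSE] -
                                 Wmat[, -W_, , drop = FALSE])))) / (H * W_)
  # radial fourth moment (rods vs blobs at equal spread) and maximum
  # radial extent (a caliper-style half-length, the Feret analogue)
  d2 <- outer(iv, ci, function(a, b) (a - b)^2) +
    outer(jv, cj, function(a, b) (a - b)^2)
  m4 <- (colSums(w * d2^2) / q)^(1 / 4)
  rmax <- sqrt(apply(d2 * w, 2, max))
  raw <- cbind(afrac = q / (H * W_),
               ax_major = sqrt(pmax(tr2 + disc, 0)),
               ax_minor = sqrt(pmax(tr2 - disc, 0)),
               edge = ed,
               rad4 = m4,
               rmax = rmax)
  # log-scale copies make power laws linear in the features; the
  # quadratic terms (log-length squared and log-length times shape)
  # let a linear readout express smooth allometric curvature and
  # shape-conditional slopes — the interactions that carry
  # species-specific length-mass scaling
  lg <- log(raw + 1e-4)
  # the size anchor is the maximum radial extent: unlike the
  # gyration-based axis it measures half the body length regardless of
  # the silhouette's shape family
  s0 <- lg[, "rmax"]
  cbind(raw, lg,
        s0sq = s0^2,
        s0_afrac = s0 * lg[, "afrac"],
        s0_major = s0 * lg[, "ax_major"],
        s0_minor = s0 * lg[, "ax_minor"],
        s0_edge = s0 * lg[, "edge"])
}

N_MOMENT_FEATURES <- 17L
FEAT_CLIP <- 6

# raw (unstandardized) pooled + moment features for one batch
avg_backbone_probe <- function(params, X) {
  aux <- input_moment_features(X)
  A <- avgpool2(X)
  for (l in seq_along(params$conv)) {
    cf <- conv_forward(A, params$conv[[l]]$W, params$conv[[l]]$b)
    A <- avgpool2(pmax(cf$Y, 0))
  }
  cbind(gap_forward(A)$feats, aux)
}

# ---- losses ---------------------------------------------------------------

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

ce_loss_grad <- function(logits, y_idx) {
  P <- softmax_rows(logits)
  n <- nrow(P)
  loss <- -mean(log(pmax(P[cbind(seq_len(n), y_idx)], 1e-12)))
  G <- P
  G[cbind(seq_len(n), y_idx)] <- G[cbind(seq_len(n), y_idx)] - 1
  list(loss = loss, grad = G / n)
}

l1_loss_grad <- function(pred, target) {
  n <- length(target)
  r <- pred[, 1] - target
  list(loss = mean(abs(r)), grad = matrix(sign(r) / n, n, 1))
}

# ---- augmentation ---------------------------------------------------------

# Regression keeps only size-preserving transforms (the silhouette
# scale carries the biomass signal); classification additionally sees
# photometric and mild scale jitter, which discourages the network
# from keying on individual training specimens' exact sizes.
AUG_GEOMETRIC <- c("identity", "hflip", "vflip", "rot90", "rot180", "rot270")
AUG_TRIVIAL <- c(AUG_GEOMETRIC, "brightness", "contrast")

augment_image <- function(img, type, mag = 0) {
  switch(type,
    identity = img,
    hflip = img[, rev(seq_len(ncol(img)))],
    vflip = img[rev(seq_len(nrow(img))), ],
    rot90 = t(img)[, rev(seq_len(nrow(img)))],
    rot180 = img[rev(seq_len(nrow(img))), rev(seq_len(ncol(img)))],
    rot270 = t(img[, rev(seq_len(ncol(img)))]),
    brightness = img + mag * 0.2,
    contrast = (img - mean(img)) * (1 + mag * 0.5) + mean(img),
    scale = {
      s <- 1 + 0.15 * mag
      h <- nrow(img); w <- ncol(img)
      ci <- (h + 1) / 2; cj <- (w + 1) / 2
      si <- pmin(pmax(round(ci + (seq_len(h) - ci) / s), 1), h)
      sj <- pmin(pmax(round(cj + (seq_len(w) - cj) / s), 1), w)
      img[si, sj]
    },
    img
  )
}

# batch tensor (T, T, n, 1) from stored images, optionally augmented;
# consumes RNG when policy is not "none"
make_batch <- function(images, idx, policy = "none") {
  Tp <- dim(images)[1]
  X <- array(0, c(Tp, Tp, length(idx), 1))
  pool <- switch(policy, trivial = AUG_TRIVIAL, geometric = AUG_GEOMETRIC, NULL)
  for (k in seq_along(idx)) {
    img <- images[, , idx[k]]
    if (!is.null(pool)) {
      type <- sample(pool, 1)
      img <- augment_image(img, type, mag = stats::runif(1, -1, 1))
    }
    X[, , k, 1] <- img
  }
  X - 0.15                  # near-background zero: silhouettes drive the sums
}

# head-only forward/backward on cached standardized features
head_forward <- function(params, feats_std) {
  n <- nrow(feats_std)
  z1 <- feats_std %*% params$head1$W +
    matrix(params$head1$b, n, length(params$head1$b), byrow = TRUE)
  a1 <- pmax(z1, 0)
  logits <- a1 %*% params$head2$W + feats_std %*% params$skip$W +
    matrix(params$head2$b, n, length(params$head2$b), byrow = TRUE)
  list(logits = logits, z1 = z1, a1 = a1)
}

head_grads <- function(params, feats_std, hf, dlogits) {
  da1 <- tcrossprod(dlogits, params$head2$W)
  dz1 <- da1 * (hf$z1 > 0)
  list(
    head2 = list(W = crossprod(hf$a1, dlogits), b = colSums(dlogits)),
    head1 = list(W = crossprod(feats_std, dz1), b = colSums(dz1)),
    skip = list(W = crossprod(feats_std, dlogits))
  )
}

# extra multiplicative shrinkage on all head weights reading the
# high-dimensional pooled features: with few training specimens these
# memorize specimen identity much faster than the five fixed
# descriptors, so they get a stronger effective weight decay
shrink_pooled <- function(params, npool, lr_ep, rate = 0.15) {
  f <- 1 - lr_ep * rate
  params$head1$W[seq_len(npool), ] <- params$head1$W[seq_len(npool), ] * f
  params$skip$W[seq_len(npool), ] <- params$skip$W[seq_len(npool), ] * f
  params
}

# L1 (least absolute deviations) fit of the regression head by IRLS:
# design = [1 | standardized features | hidden ReLU basis]; weights
# 1/max(|r|, delta) re-solve a ridge-penalized weighted least squares
# until the absolute loss stabilizes. Penalties per column group:
# fixed moment descriptors lightest, pooled conv features and the
# hidden basis heavier (they memorize specimens fastest).
irls_l1_head <- function(params, ftr, ttr, npool, iters = 12L,
                         delta = 0.05) {
  n <- nrow(ftr)
  z1 <- ftr %*% params$head1$W +
    matrix(params$head1$b, n, length(params$head1$b), byrow = TRUE)
  a1 <- pmax(z1, 0)
  D <- cbind(1, ftr, a1)
  nf <- ncol(ftr)
  h <- ncol(a1)
  lambda <- c(0, rep(0.3, npool), rep(0.005, nf - npool), rep(0.02, h))
  w <- c(params$head2$b, params$skip$W[, 1], params$head2$W[, 1])
  for (it in seq_len(iters)) {
    r <- as.vector(D %*% w) - ttr
    wt <- 1 / pmax(abs(r), delta)
    A <- crossprod(D * wt, D) + diag(lambda * n)
    w <- solve(A, crossprod(D * wt, ttr))[, 1]
  }
  params$head2$b <- w[1]
  params$skip$W[, 1] <- w[1 + seq_len(nf)]
  params$head2$W[, 1] <- w[1 + nf + seq_len(h)]
  params
}

# ---- training loop --------------------------------------------------------

# shared loop for classification (targets = integer class index) and
# regression (targets = numeric, transformed). Returns params of the
# min-validation-loss epoch plus the full loss curve.
nn_train <- function(images, targets, train_idx, val_idx, n_out, task,
                     channels, epochs, lr, batch_size, weight_decay,
                     augment_policy, seed, base_params = NULL,
                     frozen_base = FALSE) {
  params <- nn_init(channels, n_out, seed)
  if (!is.null(base_params)) {
    params$conv <- base_params$conv
    params$feat_norm <- base_params$feat_norm
  }
  if (is.null(params$feat_norm)) {
    # deterministic feature standardization from a probe of training
    # frames: the pooled mean/rms channels differ in scale by orders of
    # magnitude, and standardizing them at initialization conditions
    # the head's optimization without any train-time statistics
    probe <- sort(train_idx)[seq_len(min(256L, length(train_idx)))]
    pf <- NULL
    for (bi in split(probe, ceiling(seq_along(probe) / 64))) {
      pf <- rbind(pf, avg_backbone_probe(params, make_batch(images, bi,
                                                            "none")))
    }
    mu <- colMeans(pf)
    sd_ <- apply(pf, 2, stats::sd)
    # floor relative to the most variable feature: near-constant
    # channels are muted rather than amplified by standardization
    sd_ <- pmax(sd_, 0.05 * max(sd_, 1e-8), 1e-8)
    params$feat_norm <- list(mu = mu, sd = sd_)
  }
  state <- adamw_state(params)
  # Polyak-momentum velocities for the full-batch head refinement
  vel <- list(
    head1 = list(W = params$head1$W * 0, b = params$head1$b * 0),
    head2 = list(W = params$head2$W * 0, b = params$head2$b * 0),
    skip = list(W = params$skip$W * 0)
  )
  curve <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))
  best <- list(loss = Inf, params = params, epoch = 0L)
  step <- 0L
  npool <- nrow(params$head1$W) - N_MOMENT_FEATURES
  with_substream(seed, "trainloop", {
    for (ep in seq_len(epochs)) {
      # half-cosine learning-rate decay over the epoch budget
      lr_ep <- lr * 0.5 * (1 + cos(pi * (ep - 1) / epochs))
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      tr_loss <- 0
      for (bi in batches) {
        X <- make_batch(images, bi, augment_policy)
        fwd <- nn_forward(params, X, keep = !frozen_base)
        lg <- if (task == "classify") {
          ce_loss_grad(fwd$logits, targets[bi])
        } else {
          l1_loss_grad(fwd$logits, targets[bi])
        }
        grads <- nn_backward(params, fwd, lg$grad, frozen_base = frozen_base)
        step <- step + 1L
        # minibatch AdamW drives the backbone only; the head is fit by
        # the full-batch refinement below, where plain gradient descent
        # generalizes markedly better than adaptive updates on the few
        # effective observations (frames cluster by specimen). The
        conv_lr <- lr_ep
        r <- adamw_step(params, list(conv = grads$conv), state, step,
                        conv_lr, weight_decay)
        params <- r$params; state <- r$state
        tr_loss <- tr_loss + lg$loss * length(bi)
      }
      # full-batch gradient-descent head refinement on this epoch's
      # (frozen) backbone features; the head state persists across
      # epochs, so it converges while the backbone drifts slowly
      ftr <- NULL
      for (bi in split(sort(train_idx),
                       ceiling(seq_along(train_idx) / 256))) {
        ftr <- rbind(ftr, avg_backbone_probe(params, make_batch(images, bi,
                                                                "none")))
      }
      ftr <- sweep(sweep(ftr, 2, params$feat_norm$mu, "-"), 2,
                   params$feat_norm$sd, "/")
      ftr <- pmin(pmax(ftr, -FEAT_CLIP), FEAT_CLIP)
      ttr <- targets[sort(train_idx)]
      if (task == "classify") {
        # Polyak-momentum gradient descent on the cross-entropy. The
        # head and its velocity persist across epochs, so only the
        # first epoch needs a long refinement run; later epochs track
        # the slowly drifting backbone features with top-up steps.
        glr <- 0.15; mom <- 0.9
        n_refine <- if (ep == 1) 240L else 60L
        for (hs in seq_len(n_refine)) {
          hf <- head_forward(params, ftr)
          lg <- ce_loss_grad(hf$logits, ttr)
          hg <- head_grads(params, ftr, hf, lg$grad)
          for (hd in c("head1", "head2")) {
            for (nm in c("W", "b")) {
              decay <- if (nm == "W") 0.05 else 0  # biases not decayed
              vel[[hd]][[nm]] <- mom * vel[[hd]][[nm]] +
                hg[[hd]][[nm]] + decay * params[[hd]][[nm]]
              params[[hd]][[nm]] <- params[[hd]][[nm]] -
                glr * vel[[hd]][[nm]]
            }
          }
          vel$skip$W <- mom * vel$skip$W + hg$skip$W
          params$skip$W <- params$skip$W - glr * vel$skip$W
          # extra shrinkage on weights reading the high-dimensional
          # pooled features: they memorize specimen identity much
          # faster than the fixed moment descriptors
          params <- shrink_pooled(params, npool, glr, rate = 0.05)
        }
      } else {
        # The regression readout is linear in [features, hidden ReLU
        # basis], so the L1 objective is solved directly by
        # iteratively reweighted least squares: deterministic, a few
        # closed-form steps, immune to the flat-gradient stalls that
        # plague first-order L1 optimization. Between solves, plain
        # gradient steps adapt the hidden basis itself — the
        # species-conditional allometric slopes are interactions that
        # no linear readout of the raw descriptors can express.
        n_blocks <- if (ep == 1) 12L else 2L
        for (blk in seq_len(n_blocks)) {
          params <- irls_l1_head(params, ftr, ttr, npool)
          for (hs in seq_len(40)) {
            hf <- head_forward(params, ftr)
            lg <- l1_loss_grad(hf$logits, ttr)
            hg <- head_grads(params, ftr, hf, lg$grad)
            params$head1$W <- params$head1$W -
              0.08 * (hg$head1$W + 0.01 * params$head1$W)
            params$head1$b <- params$head1$b - 0.08 * hg$head1$b
          }
        }
        params <- irls_l1_head(params, ftr, ttr, npool)
      }
      vl <- nn_eval_loss(params, images, targets, val_idx, task, batch_size)
      curve <- rbind(curve, data.frame(epoch = ep,
                                       train_loss = tr_loss / length(ord),
                                       val_loss = vl))
      if (vl < best$loss) best <- list(loss = vl, params = params, epoch = ep)
    }
  })
  list(params = best$params, checkpoint_epoch = best$epoch, loss_curve = curve)
}

nn_eval_loss <- function(params, images, targets, idx, task, batch_size) {
  total <- 0
  for (bi in split(idx, ceiling(seq_along(idx) / batch_size))) {
    X <- make_batch(images, bi, "none")
    fwd <- nn_forward(params, X)
    lg <- if (task == "classify") {
      ce_loss_grad(fwd$logits, targets[bi])
    } else {
      l1_loss_grad(fwd$logits, targets[bi])
    }
    total <- total + lg$loss * length(bi)
  }
  total / length(idx)
}

nn_predict <- function(params, images, idx, batch_size = 64) {
  out <- NULL
  for (bi in split(idx, ceiling(seq_along(idx) / batch_size))) {
    X <- make_batch(images, bi, "none")
    out <- rbind(out, nn_forward(params, X)$logits)
  }
  out
}
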