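# Minimal CNN engine on base R arrays.
#
# Tensors are arrays [H, W, C, N] (time frames, PCA components, feature
# depth, batch). Convolutions are stride-1 with "same" zero padding (even
# kernels pad one extra row/column at the bottom/right); pooling is 2x2 max
# with stride 2, padding odd extents with -Inf. Forward passes cache what
# backward needs; training uses Adam on the categorical cross-entropy.

conv_pad <- function(k) {
  before <- (k - 1L) %/% 2L
  c(before, (k - 1L) - before)
}

# Precompute im2col gather indices for an input of shape [H, W, C] under a
# [kh, kw] kernel with "same" padding. Returns the padded shape and an
# integer matrix idx [kh*kw*C, H*W]: column q = output position (row-major
# over H fastest), rows = kernel taps in (dh, dw, c) order.
conv_plan <- function(H, W, C, kh, kw) {
  ph <- conv_pad(kh); pw <- conv_pad(kw)
  Hp <- H + sum(ph); Wp <- W + sum(pw)
  oi <- rep(seq_len(H), times = W)            # output row per position
  oj <- rep(seq_len(W), each = H)             # output col per position
  taps <- expand.grid(dh = 0:(kh - 1L), dw = 0:(kw - 1L), c = seq_len(C))
  idx <- matrix(0L, nrow = nrow(taps), ncol = H * W)
  for (r in seq_len(nrow(taps))) {
    ii <- oi + taps$dh[r]                     # 1-based row in padded array
    jj <- oj + taps$dw[r]
    idx[r, ] <- ii + (jj - 1L) * Hp + (taps$c[r] - 1L) * Hp * Wp
  }
  list(Hp = Hp, Wp = Wp, ph = ph, pw = pw, idx = idx,
       H = H, W = W, C = C, kh = kh, kw = kw)
}

pad_input <- function(x, plan) {
  d <- dim(x); N <- d[4]
  xp <- array(0, dim = c(plan$Hp, plan$Wp, plan$C, N))
  xp[plan$ph[1] + seq_len(d[1]), plan$pw[1] + seq_len(d[2]), , ] <- x
  xp
}

conv_forward <- function(x, Wk, b, plan) {
  d <- dim(x); N <- d[4]
  K <- nrow(plan$idx); Q <- ncol(plan$idx)
  xp <- pad_input(x, plan)
  dim(xp) <- c(plan$Hp * plan$Wp * plan$C, N)
  cols <- xp[as.vector(plan$idx), , drop = FALSE]   # [K*Q, N]
  dim(cols) <- c(K, Q, N)
  cols <- aperm(cols, c(2, 3, 1))                   # [Q, N, K]
  dim(cols) <- c(Q * N, K)
  Wm <- matrix(Wk, nrow = K)                        # [K, F]
  out <- cols %*% Wm
  out <- sweep(out, 2, b, `+`)                      # [Q*N, F]
  f <- ncol(Wm)
  dim(out) <- c(plan$H, plan$W, N, f)
  list(out = aperm(out, c(1, 2, 4, 3)), cols = cols)
}

conv_backward <- function(dout, cache_cols, Wk, plan, N) {
  K <- nrow(plan$idx); Q <- ncol(plan$idx)
  f <- dim(dout)[3]
  dm <- aperm(dout, c(1, 2, 4, 3))                  # [H, W, N, F]
  dim(dm) <- c(Q * N, f)
  Wm <- matrix(Wk, nrow = K)
  dW <- crossprod(cache_cols, dm)                   # [K, F]
  db <- colSums(dm)
  dcols <- dm %*% t(Wm)                             # [Q*N, K]
  dim(dcols) <- c(Q, N, K)
  dxp <- matrix(0, plan$Hp * plan$Wp * plan$C, N)
  for (r in seq_len(K)) {
    dxp[plan$idx[r, ], ] <- dxp[plan$idx[r, ], ] + dcols[, , r]
  }
  dim(dxp) <- c(plan$Hp, plan$Wp, plan$C, N)
  dx <- dxp[plan$ph[1] + seq_len(plan$H), plan$pw[1] + seq_len(plan$W), , ,
            drop = FALSE]
  list(dx = dx, dW = array(dW, dim = dim(Wk)), db = db)
}

# 2x2 max pooling, stride 2; odd extents padded with -Inf (so output size is
# ceiling(H/2) x ceiling(W/2)). Ties route the gradient to the first element.
pool_forward <- function(x) {
  d <- dim(x)
  Ho <- ceiling(d[1] / 2); Wo <- ceiling(d[2] / 2)
  xp <- array(-Inf, dim = c(2 * Ho, 2 * Wo, d[3], d[4]))
  xp[seq_len(d[1]), seq_len(d[2]), , ] <- x
  odd_r <- seq(1, 2 * Ho, by = 2); odd_c <- seq(1, 2 * Wo, by = 2)
  r1 <- xp[odd_r, , , , drop = FALSE]       # [Ho, 2Wo, C, N]
  r2 <- xp[odd_r + 1L, , , , drop = FALSE]
  m_row <- r1 >= r2
  rowmax <- pmax(r1, r2)
  c1 <- rowmax[, odd_c, , , drop = FALSE]   # [Ho, Wo, C, N]
  c2 <- rowmax[, odd_c + 1L, , , drop = FALSE]
  m_col <- c1 >= c2
  out <- pmax(c1, c2)
  list(out = out, m_row = m_row, m_col = m_col, in_dim = d,
       Ho = Ho, Wo = Wo)
}

pool_backward <- function(dout, cache) {
  d <- cache$in_dim; Ho <- cache$Ho; Wo <- cache$Wo
  odd_r <- seq(1, 2 * Ho, by = 2); odd_c <- seq(1, 2 * Wo, by = 2)
  drowmax <- array(0, dim = c(Ho, 2 * Wo, d[3], d[4]))
  drowmax[, odd_c, , ] <- dout * cache$m_col
  drowmax[, odd_c + 1L, , ] <- dout * !cache$m_col
  dxp <- array(0, dim = c(2 * Ho, 2 * Wo, d[3], d[4]))
  dxp[odd_r, , , ] <- drowmax * cache$m_row
  dxp[odd_r + 1L, , , ] <- drowmax * !cache$m_row
  dxp[seq_len(d[1]), seq_len(d[2]), , , drop = FALSE]
}

relu_forward <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_backward <- function(dout, cache) dout * cache$mask

dense_forward <- function(x, W, b) {
  out <- x %*% W
  list(out = sweep(out, 2, b, `+`), x = x)
}
dense_backward <- function(dout, cache, W) {
  list(dx = dout %*% t(W), dW = crossprod(cache$x, dout), db = colSums(dout))
}

dropout_forward <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, mask = NULL))
  mask <- matrix(stats::runif(length(x)) >= p, nrow(x), ncol(x)) / (1 - p)
  list(out = x * mask, mask = mask)
}
dropout_backward <- function(dout, cache) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

#' Softmax class probabilities
#'
#' Converts raw class scores `h(x, y_i)` into the probability distribution
#' `P(y = i | x) = exp(h_i) / sum_j exp(h_j)`, with overflow-safe shifting
#' (softmax is invariant to adding a constant to all scores).
#'
#' @param scores numeric vector of scores, or a matrix with one row per case.
#' @return probabilities of the same shape; each case sums to 1.
#' @export
softmax <- function(scores) {
  if (is.null(scores) || length(scores) == 0L) stop("scores must be non-empty")
  if (is.matrix(scores)) {
    z <- scores - apply(scores, 1, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    z <- scores - max(scores)
    e <- exp(z)
    e / sum(e)
  }
}

# --- network assembly -------------------------------------------------------

branch_kernels <- function(variant) {
  switch(variant,
         idpc = list(c(2L, 4L), c(4L, 2L)),
         dpc1 = list(c(2L, 4L), c(2L, 4L)),
         dpc2 = list(c(4L, 2L), c(4L, 2L)),
         single = list(c(2L, 2L)),
         stop("unknown network variant: ", variant))
}

branch_filters <- function() c(10L, 20L, 20L)

init_weight <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

# Output spatial size of one branch given input [H, W] (conv same, two pools)
branch_out_dim <- function(H, W) {
  h <- ceiling(ceiling(H / 2) / 2); w <- ceiling(ceiling(W / 2) / 2)
  c(h, w)
}

#' Build a dual-parallel-channel convolutional network
#'
#' The improved dual-parallel-channel CNN (`"idpc"`) runs two convolutional
#' branches side by side on the reduced spectrogram tensor: branch 1 uses
#' time-elongated 2x4 kernels (rows = time frames, columns = spectral
#' components), branch 2 the transposed 4x2 kernels, so one branch focuses on
#' temporally continuous structure and the other on spectrally continuous
#' structure. Each branch stacks three convolutions with 10, 20 and 20
#' filters, with 2x2 max pooling after the first two; the flattened branch
#' outputs are concatenated into a fully connected head of 40, 10 and 4
#' units (ReLU activations, dropout 0.5 between the fully connected layers)
#' ending in a softmax over the four gestures. Ablations: `"dpc1"` duplicates
#' branch 1, `"dpc2"` duplicates branch 2, `"single"` is one branch with
#' square 2x2 kernels. The four sEMG channels enter as input depth, letting
#' the first convolution mix muscles.
#'
#' @param variant `"idpc"`, `"dpc1"`, `"dpc2"` or `"single"`.
#' @param input_shape integer vector `(frames, components, channels)`; at the
#'   defaults `(8, 8, 4)`.
#' @param seed integer seed for weight initialisation (He-scaled normal).
#' @param dropout dropout probability between fully connected layers.
#' @return object of class `dpc_cnn` holding the architecture spec, plans
#'   and parameter arrays.
#' @export
build_network <- function(variant = c("idpc", "dpc1", "dpc2", "single"),
                          input_shape = c(8L, 8L, 4L), seed = 1L,
                          dropout = 0.5) {
  variant <- match.arg(variant)
  H <- input_shape[1]; W <- input_shape[2]; C <- input_shape[3]
  kernels <- branch_kernels(variant)
  filt <- branch_filters()
  if (H < max(vapply(kernels, `[`, integer(1), 1)) ||
      W < max(vapply(kernels, `[`, integer(1), 2))) {
    stop("input ", H, "x", W, " too small for the first convolution kernel")
  }
  bo <- branch_out_dim(H, W)
  if (any(bo < 1)) stop("input too small to survive the pooling stack")
  flat_per_branch <- bo[1] * bo[2] * filt[3]
  flat <- flat_per_branch * length(kernels)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)

  branches <- lapply(kernels, function(kk) {
    kh <- kk[1]; kw <- kk[2]
    dims_in <- list(c(H, W, C), c(ceiling(H / 2), ceiling(W / 2), filt[1]),
                    c(ceiling(H / 2), ceiling(W / 2), filt[2]))
    # conv3 runs on the post-pool-2 grid
    dims_in[[3]] <- c(bo[1], bo[2], filt[2])
    layers <- list()
    for (li in 1:3) {
      din <- dims_in[[li]]
      plan <- conv_plan(din[1], din[2], din[3], kh, kw)
      fan_in <- kh * kw * din[3]
      layers[[li]] <- list(
        plan = plan,
        W = init_weight(c(kh, kw, din[3], filt[li]), fan_in),
        b = numeric(filt[li]))
    }
    layers
  })
  head_dims <- c(flat, 40L, 10L, 4L)
  head <- lapply(1:3, function(li) {
    list(W = init_weight(c(head_dims[li], head_dims[li + 1]), head_dims[li]),
         b = numeric(head_dims[li + 1]))
  })
  structure(list(variant = variant, input_shape = input_shape,
                 kernels = kernels, filters = filt,
                 branches = branches, head = head,
                 dropout = dropout, flat = flat,
                 classes = gesture_classes(), seed = as.integer(seed)),
            class = "dpc_cnn")
}

#' Number of trainable parameters of a network
#' @param net a `dpc_cnn`.
#' @return integer parameter count.
#' @export
network_param_count <- function(net) {
  stopifnot(inherits(net, "dpc_cnn"))
  n <- 0L
  for (br in net$branches) for (ly in br) n <- n + length(ly$W) + length(ly$b)
  for (ly in net$head) n <- n + length(ly$W) + length(ly$b)
  n
}

branch_forward <- function(x, branch) {
  caches <- list()
  h <- x
  for (li in 1:3) {
    cv <- conv_forward(h, branch[[li]]$W, branch[[li]]$b, branch[[li]]$plan)
    rl <- relu_forward(cv$out)
    if (li < 3) {
      pl <- pool_forward(rl$out)
      h <- pl$out
      caches[[li]] <- list(conv = cv, relu = rl, pool = pl)
    } else {
      h <- rl$out
      caches[[li]] <- list(conv = cv, relu = rl)
    }
  }
  N <- dim(h)[4]
  flat <- matrix(aperm(h, c(4, 1, 2, 3)), nrow = N)  # row-per-sample flatten
  list(flat = flat, caches = caches, out_dim = dim(h))
}

branch_backward <- function(dflat, branch, caches, out_dim) {
  N <- out_dim[4]
  dh <- aperm(array(dflat, dim = c(N, out_dim[1], out_dim[2], out_dim[3])),
              c(2, 3, 4, 1))
  grads <- vector("list", 3)
  for (li in 3:1) {
    ch <- caches[[li]]
    if (li < 3) dh <- pool_backward(dh, ch$pool)
    dh <- relu_backward(dh, ch$relu)
    bb <- conv_backward(dh, ch$conv$cols, branch[[li]]$W, branch[[li]]$plan, N)
    grads[[li]] <- list(dW = bb$dW, db = bb$db)
    dh <- bb$dx
  }
  list(grads = grads)
}

cnn_forward <- function(net, x, training = FALSE) {
  # x: array [H, W, C, N]
  br_out <- lapply(net$branches, branch_forward, x = x)
  flat <- do.call(cbind, lapply(br_out, `[[`, "flat"))
  c1 <- dense_forward(flat, net$head[[1]]$W, net$head[[1]]$b)
  r1 <- relu_forward(c1$out)
  d1 <- dropout_forward(r1$out, net$dropout, training)
  c2 <- dense_forward(d1$out, net$head[[2]]$W, net$head[[2]]$b)
  r2 <- relu_forward(c2$out)
  d2 <- dropout_forward(r2$out, net$dropout, training)
  c3 <- dense_forward(d2$out, net$head[[3]]$W, net$head[[3]]$b)
  probs <- softmax(c3$out)
  list(probs = probs, logits = c3$out,
       cache = list(br = br_out, flat = flat, c1 = c1, r1 = r1, d1 = d1,
                    c2 = c2, r2 = r2, d2 = d2, c3 = c3))
}

cnn_backward <- function(net, cache, dlogits) {
  g <- list(head = vector("list", 3), branches = vector("list",
                                                        length(net$branches)))
  b3 <- dense_backward(dlogits, cache$c3, net$head[[3]]$W)
  g$head[[3]] <- list(dW = b3$dW, db = b3$db)
  dd2 <- dropout_backward(b3$dx, cache$d2)
  dr2 <- relu_backward(dd2, cache$r2)
  b2 <- dense_backward(dr2, cache$c2, net$head[[2]]$W)
  g$head[[2]] <- list(dW = b2$dW, db = b2$db)
  dd1 <- dropout_backward(b2$dx, cache$d1)
  dr1 <- relu_backward(dd1, cache$r1)
  b1 <- dense_backward(dr1, cache$c1, net$head[[1]]$W)
  g$head[[1]] <- list(dW = b1$dW, db = b1$db)
  dflat <- b1$dx
  off <- 0L
  for (bi in seq_along(net$branches)) {
    w <- ncol(cache$br[[bi]]$flat)
    dpart <- dflat[, off + seq_len(w), drop = FALSE]
    g$branches[[bi]] <- branch_backward(dpart, net$branches[[bi]],
                                        cache$br[[bi]]$caches,
                                        cache$br[[bi]]$out_dim)$grads
    off <- off + w
  }
  g
}

cross_entropy <- function(probs, y_idx) {
  -mean(log(pmax(probs[cbind(seq_len(nrow(probs)), y_idx)], 1e-12)))
}

# Flatten/unflatten parameters for the optimizer
cnn_params <- function(net) {
  p <- list()
  for (bi in seq_along(net$branches)) for (li in 1:3) {
    p[[paste0("b", bi, "c", li, "W")]] <- net$branches[[bi]][[li]]$W
    p[[paste0("b", bi, "c", li, "b")]] <- net$branches[[bi]][[li]]$b
  }
  for (li in 1:3) {
    p[[paste0("hd", li, "W")]] <- net$head[[li]]$W
    p[[paste0("hd", li, "b")]] <- net$head[[li]]$b
  }
  p
}

cnn_set_params <- function(net, p) {
  for (bi in seq_along(net$branches)) for (li in 1:3) {
    net$branches[[bi]][[li]]$W <- p[[paste0("b", bi, "c", li, "W")]]
    net$branches[[bi]][[li]]$b <- p[[paste0("b", bi, "c", li, "b")]]
  }
  for (li in 1:3) {
    net$head[[li]]$W <- p[[paste0("hd", li, "W")]]
    net$head[[li]]$b <- p[[paste0("hd", li, "b")]]
  }
  net
}

cnn_grads_list <- function(net, g) {
  out <- list()
  for (bi in seq_along(net$branches)) for (li in 1:3) {
    out[[paste0("b", bi, "c", li, "W")]] <- g$branches[[bi]][[li]]$dW
    out[[paste0("b", bi, "c", li, "b")]] <- g$branches[[bi]][[li]]$db
  }
  for (li in 1:3) {
    out[[paste0("hd", li, "W")]] <- g$head[[li]]$dW
    out[[paste0("hd", li, "b")]] <- g$head[[li]]$db
  }
  out
}

#' Train a dual-parallel-channel CNN
#'
#' Mini-batch training with the Adam optimizer on the categorical
#' cross-entropy paired with the softmax output. In each iteration a batch is
#' drawn at random from the training set. Optionally a fraction of the
#' training data is held out for early stopping on validation loss (the
#' parameters of the best validation epoch are restored). Training is
#' deterministic given the seed.
#'
#' @param net a `dpc_cnn` from [build_network()].
#' @param x array `H x W x C x N` of training inputs.
#' @param y factor or character vector of gesture labels, length `N`.
#' @param epochs maximum epochs (default 50).
#' @param batch_size mini-batch size (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed integer seed governing batching, dropout and any validation
#'   split.
#' @param val_frac fraction held out for early stopping (0 disables; default 0).
#' @param patience early-stop patience in epochs (used when `val_frac > 0`).
#' @return the trained network, with `history` (per-epoch mean training loss,
#'   and validation loss when enabled) and `training_config` attached.
#' @export
cnn_train <- function(net, x, y, epochs = 50L, batch_size = 32L, lr = 1e-3,
                      seed = 1L, val_frac = 0, patience = 10L) {
  stopifnot(inherits(net, "dpc_cnn"))
  y <- as.character(y)
  if (length(unique(y)) < 2L) {
    stop("training set contains a single class; refusing to train")
  }
  y_idx <- match(y, net$classes)
  if (anyNA(y_idx)) stop("labels outside the gesture classes")
  N <- dim(x)[4]
  stopifnot(length(y_idx) == N)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)

  val_idx <- integer(0)
  if (val_frac > 0) {
    val_idx <- sample(N, max(1L, floor(val_frac * N)))
    # keep at least two classes in the training part
    if (length(unique(y_idx[-val_idx])) < 2L) val_idx <- integer(0)
  }
  tr_idx <- setdiff(seq_len(N), val_idx)

  params <- cnn_params(net)
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_val <- Inf; best_params <- params; wait <- 0L
  n_tr <- length(tr_idx)
  batches_per_epoch <- max(1L, ceiling(n_tr / batch_size))

  for (ep in seq_len(epochs)) {
    ep_loss <- 0
    for (it in seq_len(batches_per_epoch)) {
      bidx <- tr_idx[sample.int(n_tr, min(batch_size, n_tr))]
      xb <- x[, , , bidx, drop = FALSE]
      yb <- y_idx[bidx]
      net <- cnn_set_params(net, params)
      fw <- cnn_forward(net, xb, training = TRUE)
      loss <- cross_entropy(fw$probs, yb)
      ep_loss <- ep_loss + loss
      onehot <- matrix(0, length(yb), length(net$classes))
      onehot[cbind(seq_along(yb), yb)] <- 1
      dlogits <- (fw$probs - onehot) / length(yb)
      grads <- cnn_grads_list(net, cnn_backward(net, fw$cache, dlogits))
      t_step <- t_step + 1
      for (k in names(params)) {
        m[[k]] <- beta1 * m[[k]] + (1 - beta1) * grads[[k]]
        v[[k]] <- beta2 * v[[k]] + (1 - beta2) * grads[[k]]^2
        mhat <- m[[k]] / (1 - beta1^t_step)
        vhat <- v[[k]] / (1 - beta2^t_step)
        params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    train_loss <- ep_loss / batches_per_epoch
    val_loss <- NA_real_
    if (length(val_idx) > 0) {
      net <- cnn_set_params(net, params)
      fv <- cnn_forward(net, x[, , , val_idx, drop = FALSE], training = FALSE)
      val_loss <- cross_entropy(fv$probs, y_idx[val_idx])
      if (val_loss < best_val - 1e-6) {
        best_val <- val_loss; best_params <- params; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) {
          history <- rbind(history, data.frame(epoch = ep,
                                               train_loss = train_loss,
                                               val_loss = val_loss))
          break
        }
      }
    }
    history <- rbind(history, data.frame(epoch = ep, train_loss = train_loss,
                                         val_loss = val_loss))
  }
  final <- if (length(val_idx) > 0) best_params else params
  net <- cnn_set_params(net, final)
  net$history <- history
  net$training_config <- list(epochs = epochs, batch_size = batch_size,
                              lr = lr, seed = as.integer(seed),
                              val_frac = val_frac, patience = patience)
  net
}

#' Class probabilities from a trained network
#'
#' Runs the forward pass with dropout disabled, so repeated inference on the
#' same input is identical.
#'
#' @param net a trained `dpc_cnn`.
#' @param x array `H x W x C x N` (or a single `H x W x C` input).
#' @return matrix `N x 4` of class probabilities (columns named by gesture).
#' @export
cnn_predict <- function(net, x) {
  stopifnot(inherits(net, "dpc_cnn"))
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  exp_dim <- net$input_shape
  if (!all(dim(x)[1:3] == exp_dim)) {
    stop("input shape ", paste(dim(x)[1:3], collapse = "x"),
         " does not match the network input ", paste(exp_dim, collapse = "x"))
  }
  probs <- cnn_forward(net, x, training = FALSE)$probs
  colnames(probs) <- net$classes
  probs
}

# Numerical-vs-analytic gradient agreement on a random slice of parameters;
# returns the maximum relative difference. Used by the test suite.
cnn_gradient_check <- function(net, x, y_idx, n_checks = 10L, h = 1e-5,
                               seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  params <- cnn_params(net)
  fw <- cnn_forward(net, x, training = FALSE)
  onehot <- matrix(0, length(y_idx), length(net$classes))
  onehot[cbind(seq_along(y_idx), y_idx)] <- 1
  dlogits <- (fw$probs - onehot) / length(y_idx)
  grads <- cnn_grads_list(net, cnn_backward(net, fw$cache, dlogits))
  loss_at <- function(p) {
    nn <- cnn_set_params(net, p)
    cross_entropy(cnn_forward(nn, x, training = FALSE)$probs, y_idx)
  }
  keys <- sample(names(params), min(n_checks, length(params)))
  rel <- numeric(0)
  for (k in keys) {
    i <- sample(length(params[[k]]), 1)
    pp <- params; pp[[k]][i] <- pp[[k]][i] + h
    pm <- params; pm[[k]][i] <- pm[[k]][i] - h
    num <- (loss_at(pp) - loss_at(pm)) / (2 * h)
    ana <- grads[[k]][i]
    denom <- max(abs(num), abs(ana), 1e-8)
    rel <- c(rel, abs(num - ana) / denom)
  }
  max(rel)
}
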