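## Internal neural-network machinery: parameter containers, the feedforward
## head, Adam, and the combined forward/backward pass around the C++ LSTM.
## Gate order everywhere is [input, forget, cell, output]; initialization is
## uniform(-1/sqrt(H), 1/sqrt(H)) per layer, the convention of common LSTM
## implementations. Callers own the RNG state (set.seed upstream).

lstm_init <- function(n_in, width, layers) {
  k <- 1 / sqrt(width)
  lapply(seq_len(layers), function(l) {
    d <- if (l == 1L) n_in else width
    list(W = matrix(runif(d * 4 * width, -k, k), d, 4 * width),
         U = matrix(runif(width * 4 * width, -k, k), width, 4 * width),
         b = runif(4 * width, -k, k))
  })
}

dense_init <- function(dims) {
  # dims: c(d_in, hidden..., d_out)
  lapply(seq_len(length(dims) - 1L), function(i) {
    k <- 1 / sqrt(dims[i])
    list(W = matrix(runif(dims[i] * dims[i + 1L], -k, k), dims[i], dims[i + 1L]),
         b = runif(dims[i + 1L], -k, k))
  })
}

dense_forward <- function(layers, Z) {
  acts <- vector("list", length(layers))
  a <- Z
  for (i in seq_along(layers)) {
    a <- sweep(a %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    if (i < length(layers)) a <- pmax(a, 0)  # ReLU on hidden layers
    acts[[i]] <- a
  }
  list(out = a, acts = acts, input = Z)
}

dense_backward <- function(layers, fwd, dOut) {
  grads <- vector("list", length(layers))
  d <- dOut
  for (i in rev(seq_along(layers))) {
    if (i < length(layers)) d <- d * (fwd$acts[[i]] > 0)
    a_in <- if (i == 1L) fwd$input else fwd$acts[[i - 1L]]
    grads[[i]] <- list(W = crossprod(a_in, d), b = colSums(d))
    d <- tcrossprod(d, layers[[i]]$W)
  }
  list(grads = grads, dZ = d)
}

## ---- full model forward/backward ------------------------------------------

## X: array (B, channels, T); S: matrix (B, n_static) or NULL.
## params: list(lstm = <layer list>, head = <dense layer list>).
net_forward <- function(params, X, S = NULL) {
  Ws <- lapply(params$lstm, `[[`, "W")
  Us <- lapply(params$lstm, `[[`, "U")
  bs <- lapply(params$lstm, `[[`, "b")
  fw <- lstm_forward_cpp(Ws, Us, bs, X)
  L <- length(params$lstm)
  B <- dim(X)[1]; T <- dim(X)[3]
  H <- dim(fw$H[[L]])[2]
  Z <- aperm(fw$H[[L]], c(1, 3, 2))
  dim(Z) <- c(B * T, H)
  if (!is.null(S)) Z <- cbind(Z, S[rep(seq_len(B), times = T), , drop = FALSE])
  dfw <- dense_forward(params$head, Z)
  list(pred = matrix(dfw$out, B, T), lstm = fw, dense = dfw,
       B = B, T = T, H = H)
}

## dPred: matrix (B, T). Returns gradients in the shape of params.
net_backward <- function(params, X, fwd, dPred) {
  B <- fwd$B; T <- fwd$T; H <- fwd$H
  dOut <- matrix(as.numeric(dPred), B * T, 1)
  db <- dense_backward(params$head, fwd$dense, dOut)
  dH <- db$dZ[, seq_len(H), drop = FALSE]
  dim(dH) <- c(B, T, H)
  dHtop <- aperm(dH, c(1, 3, 2))
  Ws <- lapply(params$lstm, `[[`, "W")
  Us <- lapply(params$lstm, `[[`, "U")
  bs <- lapply(params$lstm, `[[`, "b")
  lg <- lstm_backward_cpp(Ws, Us, bs, X, fwd$lstm$H, fwd$lstm$G, fwd$lstm$C,
                          dHtop)
  lstm_grads <- lapply(seq_along(params$lstm), function(l) {
    list(W = lg$dW[[l]], U = lg$dU[[l]], b = as.numeric(lg$db[[l]]))
  })
  list(lstm = lstm_grads, head = db$grads)
}

## ---- flatten / unflatten so Adam can treat parameters uniformly ----------

flatten_params <- function(params) {
  out <- list()
  for (l in seq_along(params$lstm)) {
    for (nm in c("W", "U", "b")) {
      out[[sprintf("lstm.%d.%s", l, nm)]] <- params$lstm[[l]][[nm]]
    }
  }
  for (l in seq_along(params$head)) {
    for (nm in c("W", "b")) {
      out[[sprintf("head.%d.%s", l, nm)]] <- params$head[[l]][[nm]]
    }
  }
  out
}

unflatten_params <- function(flat, template) {
  for (l in seq_along(template$lstm)) {
    for (nm in c("W", "U", "b")) {
      template$lstm[[l]][[nm]] <- flat[[sprintf("lstm.%d.%s", l, nm)]]
    }
  }
  for (l in seq_along(template$head)) {
    for (nm in c("W", "b")) {
      template$head[[l]][[nm]] <- flat[[sprintf("head.%d.%s", l, nm)]]
    }
  }
  template
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(flat) {
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0),
       t = 0L)
}

## L2-coupled weight decay (added to the gradient), applied to weights and
## biases alike. Only names in `trainable` are updated.
adam_step <- function(flat, grads, state, lr, wd, trainable,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in trainable) {
    g <- grads[[nm]] + wd * flat[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    flat[[nm]] <- flat[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

## ---- data preparation ------------------------------------------------------

## trials -> X array (n, 4, 300); Y matrix (n, 300)
trials_to_xy <- function(trials) {
  n <- length(trials)
  T <- length(trials[[1]]$torque)
  X <- array(0, c(n, 4L, T))
  Y <- matrix(0, n, T)
  for (i in seq_len(n)) {
    X[i, , ] <- t(trials[[i]]$activations)
    Y[i, ] <- trials[[i]]$torque
  }
  list(X = X, Y = Y)
}

## static feature matrix: sex in {0,1} (male = 1) + the six measurements
statics_matrix <- function(trials) {
  mat <- t(vapply(trials, function(tr) {
    s <- tr$statics
    if (is.null(s)) stop("trial has no static features", call. = FALSE)
    c(sex = as.numeric(s$sex == "male"), height = s$height, mass = s$mass,
      mvc = s$mvc_torque, forearm = s$forearm_length,
      elbow_width = s$elbow_width, upper_arm = s$upper_arm_length)
  }, numeric(7)))
  mat
}

## z-score scaler for the numeric statics (sex column left as 0/1); fitted
## on training subjects only
fit_scaler <- function(S) {
  center <- colMeans(S)
  scale <- apply(S, 2, sd)
  center[1] <- 0
  scale[1] <- 1
  scale[scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(S, scaler) {
  sweep(sweep(S, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

## ---- training loop ---------------------------------------------------------

## Mini-batch Adam on MSE. `trainable`: names of flat parameters to update.
## If val is supplied (list(X, S, Y)), tracks validation MSE and keeps the
## best parameters with early-stopping patience.
train_network <- function(params, trainable, X, S, Y, cfg, val = NULL) {
  # start the output at the target mean so training spends its steps on
  # shape, not on travelling to the torque scale
  nh <- length(params$head)
  out_b <- sprintf("head.%d.b", nh)
  if (cfg$epochs > 0 && out_b %in% trainable) {
    params$head[[nh]]$b <- rep(mean(Y), length(params$head[[nh]]$b))
  }
  flat <- flatten_params(params)
  state <- adam_init(flat)
  n <- dim(X)[1]
  bs <- min(cfg$batch_size, n)
  best_val <- Inf
  best_flat <- flat
  wait <- 0L
  history <- numeric(0)
  for (epoch in seq_len(cfg$epochs)) {
    idx <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1, n, by = bs)) {
      take <- idx[start:min(start + bs - 1L, n)]
      Xb <- X[take, , , drop = FALSE]
      Sb <- if (is.null(S)) NULL else S[take, , drop = FALSE]
      Yb <- Y[take, , drop = FALSE]
      params <- unflatten_params(flat, params)
      fwd <- net_forward(params, Xb, Sb)
      err <- fwd$pred - Yb
      ep_loss <- ep_loss + sum(err^2)
      dPred <- 2 * err / length(err)
      grads <- flatten_params(net_backward(params, Xb, fwd, dPred))
      upd <- adam_step(flat, grads, state, cfg$learning_rate,
                       cfg$weight_decay, trainable)
      flat <- upd$flat
      state <- upd$state
    }
    history <- c(history, ep_loss / (n * dim(Y)[2]))
    if (!is.null(val)) {
      params <- unflatten_params(flat, params)
      vp <- net_forward(params, val$X, val$S)$pred
      vmse <- mean((vp - val$Y)^2)
      if (vmse < best_val - 1e-12) {
        best_val <- vmse
        best_flat <- flat
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  }
  if (!is.null(val)) flat <- best_flat
  list(params = unflatten_params(flat, params), history = history,
       val_mse = if (is.null(val)) NA_real_ else best_val)
}

count_params <- function(params) {
  sum(vapply(flatten_params(params), length, 0L))
}
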