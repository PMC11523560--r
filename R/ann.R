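#' Network architecture configuration
#'
#' The sequence backbone is a stack of unidirectional LSTM layers consuming
#' the 4 activation channels per time step; its per-step output is
#' concatenated with the encoded static features and fed to a feedforward
#' stack with ReLU hidden units ending in a single torque output per step.
#' Defaults follow the selected direct-learning architecture: 3 LSTM layers
#' of width 24, 2 feedforward hidden layers of width 23.
#'
#' @param lstm_layers,lstm_width LSTM depth and hidden width (>= 1).
#' @param ff_layers,ff_width Feedforward hidden depth and width (>= 1).
#' @param unfrozen_backend_layers Number of backend (topmost) LSTM layers
#'   left trainable during fine-tuning; restricted to 0, 1 or 2.
#' @return An object of class `arch_config`.
#' @export
arch_config <- function(lstm_layers = 3L, lstm_width = 24L,
                        ff_layers = 2L, ff_width = 23L,
                        unfrozen_backend_layers = 0L) {
  if (any(c(lstm_layers, lstm_width, ff_layers, ff_width) < 1)) {
    stop("widths and layer counts must be >= 1", call. = FALSE)
  }
  if (!unfrozen_backend_layers %in% 0:2) {
    stop("`unfrozen_backend_layers` must be 0, 1 or 2", call. = FALSE)
  }
  if (unfrozen_backend_layers > lstm_layers) {
    stop("cannot unfreeze more layers than the LSTM has", call. = FALSE)
  }
  structure(list(lstm_layers = as.integer(lstm_layers),
                 lstm_width = as.integer(lstm_width),
                 ff_layers = as.integer(ff_layers),
                 ff_width = as.integer(ff_width),
                 unfrozen_backend_layers = as.integer(unfrozen_backend_layers)),
            class = "arch_config")
}

#' Training configuration
#'
#' Adam with an MSE loss and L2 weight decay applied to weights and biases.
#' Defaults follow the selected direct-learning hyperparameters (learning
#' rate 6.4e-3, weight decay 4.5e-2); the transfer fine-tuning selection was
#' learning rate 9.0e-3 and weight decay 9.4e-2.
#'
#' @param learning_rate,weight_decay Positive reals.
#' @param epochs Training epochs.
#' @param batch_size Trials per mini-batch.
#' @param seed RNG seed covering initialization and batch shuffling.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement) when a validation set is supplied.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 6.4e-3, weight_decay = 4.5e-2,
                         epochs = 300L, batch_size = 4L, seed = 0L,
                         patience = 30L) {
  if (learning_rate <= 0 || weight_decay <= 0) {
    stop("learning_rate and weight_decay must be positive", call. = FALSE)
  }
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed), patience = as.integer(patience)),
            class = "train_config")
}

new_flex_model <- function(arch, params, n_static, n_channels, scaler,
                           provenance) {
  structure(list(arch = arch, params = params, n_static = n_static,
                 n_channels = n_channels, scaler = scaler,
                 provenance = provenance),
            class = "flex_model")
}

#' @export
print.flex_model <- function(x, ...) {
  cat(sprintf(
    "<flex_model> [%s] %d LSTM layers x %d, %s head, %d parameters\n",
    x$provenance, x$arch$lstm_layers, x$arch$lstm_width,
    if (is.null(x$params$head)) "no" else
      sprintf("%d x %d feedforward", x$arch$ff_layers, x$arch$ff_width),
    count_params(x$params)))
  invisible(x)
}

#' Build an untrained model
#'
#' @param arch An [arch_config()].
#' @param n_static Number of static features (7; 0 for a backbone-only
#'   model).
#' @param n_channels Number of activation channels (4).
#' @param seed Seed for weight initialization.
#' @return A `flex_model` with random weights, provenance `"direct"`.
#' @export
build_model <- function(arch, n_static = 7L, n_channels = 4L, seed = 0L) {
  stopifnot(inherits(arch, "arch_config"))
  old <- .Random.seed_guard(seed)
  on.exit(old())
  params <- list(
    lstm = lstm_init(n_channels, arch$lstm_width, arch$lstm_layers),
    head = dense_init(c(arch$lstm_width + n_static,
                        rep(arch$ff_width, arch$ff_layers), 1L)))
  new_flex_model(arch, params, n_static, n_channels, scaler = NULL,
                 provenance = "direct")
}

## names of the flat parameters belonging to the head plus the last
## `unfrozen` LSTM layers
trainable_names <- function(params, unfrozen) {
  L <- length(params$lstm)
  keep <- character(0)
  if (unfrozen > 0) {
    for (l in seq(L - unfrozen + 1L, L)) {
      keep <- c(keep, sprintf("lstm.%d.%s", l, c("W", "U", "b")))
    }
  }
  for (l in seq_along(params$head)) {
    keep <- c(keep, sprintf("head.%d.%s", l, c("W", "b")))
  }
  keep
}

prepare_training_data <- function(trials, model, scaler = NULL) {
  xy <- trials_to_xy(trials)
  S <- NULL
  if (model$n_static > 0) {
    S0 <- statics_matrix(trials)
    if (is.null(scaler)) scaler <- fit_scaler(S0)
    S <- apply_scaler(S0, scaler)
  }
  list(X = xy$X, Y = xy$Y, S = S, scaler = scaler)
}

#' Pre-train the sequence backbone on simulated trials
#'
#' Trains the LSTM backbone plus a temporary per-step linear readout to
#' regress simulated torque from simulated muscle activations with an MSE
#' loss; the readout is discarded afterwards and only the backbone weights
#' are kept (a fresh feedforward head is attached during fine-tuning).
#' Simulated trials carry no static features.
#'
#' @param sim_trials List of simulated [flex_trial()]s.
#' @param arch An [arch_config()].
#' @param cfg A [train_config()].
#' @return A `flex_model` with provenance `"pretrained"` (backbone only).
#' @export
pretrain_backbone <- function(sim_trials, arch, cfg) {
  if (length(sim_trials) == 0L) stop("empty simulated dataset", call. = FALSE)
  if (any(!vapply(sim_trials, function(t) is.null(t$statics), TRUE))) {
    stop("simulated trials must carry no static features", call. = FALSE)
  }
  old <- .Random.seed_guard(cfg$seed)
  on.exit(old())
  params <- list(lstm = lstm_init(4L, arch$lstm_width, arch$lstm_layers),
                 head = dense_init(c(arch$lstm_width, 1L)))  # linear readout
  xy <- trials_to_xy(sim_trials)
  fit <- train_network(params, names(flatten_params(params)),
                       xy$X, NULL, xy$Y, cfg)
  fit$params$head <- NULL  # readout discarded at hand-off
  m <- new_flex_model(arch, fit$params, n_static = 0L, n_channels = 4L,
                      scaler = NULL, provenance = "pretrained")
  attr(m, "history") <- fit$history
  m
}

#' Fine-tune a pre-trained backbone on recorded-style trials
#'
#' Attaches a fresh feedforward head (consuming the backbone's per-step
#' output concatenated with the 7 encoded static features) to the
#' pre-trained LSTM, freezes all backbone layers except the last
#' `arch$unfrozen_backend_layers`, and trains on the recorded-style trials.
#' Frozen parameters are bitwise unchanged by training.
#'
#' @param pretrained A [pretrain_backbone()] result.
#' @param rec_train List of recorded-style [flex_trial()]s (with statics).
#' @param arch An [arch_config()]; LSTM dimensions must match the backbone.
#' @param cfg A [train_config()].
#' @param val Optional validation trials for early stopping.
#' @return A `flex_model` with provenance `"transfer"`.
#' @export
finetune_transfer <- function(pretrained, rec_train, arch, cfg, val = NULL) {
  stopifnot(inherits(pretrained, "flex_model"))
  if (pretrained$provenance != "pretrained") {
    stop("`pretrained` must come from pretrain_backbone()", call. = FALSE)
  }
  if (arch$lstm_layers != pretrained$arch$lstm_layers ||
      arch$lstm_width != pretrained$arch$lstm_width) {
    stop("LSTM dimensions must match the pre-trained backbone", call. = FALSE)
  }
  train_head_model(rec_train, arch, cfg,
                   lstm = pretrained$params$lstm,
                   unfrozen = arch$unfrozen_backend_layers,
                   provenance = "transfer", val = val)
}

#' Train a model directly on recorded-style trials
#'
#' Same architecture as the transfer model but all parameters are trained
#' from random initialization on the recorded-style data only.
#'
#' @inheritParams finetune_transfer
#' @param rec_train List of recorded-style [flex_trial()]s.
#' @return A `flex_model` with provenance `"direct"`.
#' @export
train_direct <- function(rec_train, arch, cfg, val = NULL) {
  train_head_model(rec_train, arch, cfg, lstm = NULL,
                   unfrozen = arch$lstm_layers, provenance = "direct",
                   val = val)
}

train_head_model <- function(rec_train, arch, cfg, lstm, unfrozen,
                             provenance, val = NULL) {
  if (length(rec_train) == 0L) stop("empty training set", call. = FALSE)
  old <- .Random.seed_guard(cfg$seed)
  on.exit(old())
  params <- list(
    lstm = if (is.null(lstm)) lstm_init(4L, arch$lstm_width, arch$lstm_layers)
           else lstm,
    head = dense_init(c(arch$lstm_width + 7L,
                        rep(arch$ff_width, arch$ff_layers), 1L)))
  model <- new_flex_model(arch, params, n_static = 7L, n_channels = 4L,
                          scaler = NULL, provenance = provenance)
  dat <- prepare_training_data(rec_train, model)
  model$scaler <- dat$scaler
  vdat <- NULL
  if (!is.null(val)) {
    v <- prepare_training_data(val, model, scaler = dat$scaler)
    vdat <- list(X = v$X, S = v$S, Y = v$Y)
  }
  trainable <- trainable_names(params, unfrozen)
  fit <- train_network(params, trainable, dat$X, dat$S, dat$Y, cfg, val = vdat)
  model$params <- fit$params
  attr(model, "history") <- fit$history
  attr(model, "val_mse") <- fit$val_mse
  model
}

#' Predict torque sequences
#'
#' @param object A trained `flex_model` (with a feedforward head).
#' @param trials List of [flex_trial()]s.
#' @param ... Unused.
#' @return A numeric matrix, one row per trial, one column per time step
#'   (newton-meters).
#' @export
predict.flex_model <- function(object, trials, ...) {
  if (is.null(object$params$head)) {
    stop("backbone-only model: attach a head with finetune_transfer()",
         call. = FALSE)
  }
  xy <- trials_to_xy(trials)
  S <- NULL
  if (object$n_static > 0) {
    S <- apply_scaler(statics_matrix(trials), object$scaler)
  }
  net_forward(object$params, xy$X, S)$pred
}

#' Hyperparameter search space
#'
#' Ranges of the random search: learning rate and weight decay are drawn
#' log-uniformly, hidden widths from a discrete set, and (for transfer
#' fine-tuning) the number of unfrozen backend LSTM layers from
#' \{0, 1, 2\}. The selected configurations (learning rates 6.4e-3 and
#' 9.0e-3, weight decays 4.5e-2 and 9.4e-2, width 24) all lie inside the
#' default ranges.
#'
#' @param lr_range,wd_range Length-2 log-uniform ranges.
#' @param widths Discrete hidden widths.
#' @param unfrozen Candidate unfrozen backend layer counts.
#' @param n_draws Number of random draws.
#' @param cv_folds Cross-validation folds (5).
#' @return An object of class `search_space`.
#' @export
search_space <- function(lr_range = c(1e-4, 1e-1), wd_range = c(1e-4, 1),
                         widths = c(8L, 16L, 24L, 32L, 48L),
                         unfrozen = 0:2, n_draws = 30L, cv_folds = 5L) {
  if (n_draws < 1) stop("`n_draws` must be >= 1", call. = FALSE)
  structure(list(lr_range = lr_range, wd_range = wd_range, widths = widths,
                 unfrozen = unfrozen, n_draws = as.integer(n_draws),
                 cv_folds = as.integer(cv_folds)),
            class = "search_space")
}

## subject-wise fold assignment: partition unique subjects, never trials
subject_folds <- function(trials, k) {
  subs <- unique(vapply(trials, `[[`, "", "subject_id"))
  if (length(subs) < k) {
    stop("fewer subjects than cross-validation folds", call. = FALSE)
  }
  shuffled <- sample(subs)
  split(shuffled, rep(seq_len(k), length.out = length(shuffled)))
}

#' Random hyperparameter search with subject-wise cross-validation
#'
#' Draws `space$n_draws` configurations, evaluates each by `space$cv_folds`
#' subject-wise cross-validation (folds partition subjects, never trials)
#' under the requested learning mode, and returns the configuration with
#' the lowest mean validation MSE. Ties are broken by smaller parameter
#' count, then draw order.
#'
#' @param space A [search_space()].
#' @param data Recorded-style training trials.
#' @param mode `"direct"` or `"transfer"`.
#' @param seed Seed for draws and fold assignment.
#' @param pretrained Backbone for `mode = "transfer"`.
#' @param base_cfg A [train_config()] supplying epochs/batch/patience.
#' @return A list with `best` (list of `arch`, `cfg`, `mean_mse`) and
#'   `cv_table` (data frame: one row per draw x fold).
#' @export
random_search <- function(space, data, mode = c("direct", "transfer"),
                          seed = 0L, pretrained = NULL,
                          base_cfg = train_config()) {
  mode <- match.arg(mode)
  stopifnot(inherits(space, "search_space"))
  if (mode == "transfer" && is.null(pretrained)) {
    stop("transfer mode needs a pre-trained backbone", call. = FALSE)
  }
  old <- .Random.seed_guard(seed)
  on.exit(old())
  folds <- subject_folds(data, space$cv_folds)
  draws <- lapply(seq_len(space$n_draws), function(i) {
    list(
      lr = exp(runif(1, log(space$lr_range[1]), log(space$lr_range[2]))),
      wd = exp(runif(1, log(space$wd_range[1]), log(space$wd_range[2]))),
      width = space$widths[sample.int(length(space$widths), 1L)],
      unfrozen = if (mode == "transfer")
        space$unfrozen[sample.int(length(space$unfrozen), 1L)] else 0L)
  })
  sub_of <- vapply(data, `[[`, "", "subject_id")
  rows <- list()
  summary <- data.frame(draw = seq_len(space$n_draws), mean_mse = NA_real_,
                        n_params = NA_integer_)
  for (i in seq_along(draws)) {
    d <- draws[[i]]
    arch <- if (mode == "transfer") {
      arch_config(pretrained$arch$lstm_layers, pretrained$arch$lstm_width,
                  ff_layers = 2L, ff_width = d$width,
                  unfrozen_backend_layers = d$unfrozen)
    } else {
      arch_config(lstm_layers = 3L, lstm_width = d$width,
                  ff_layers = 2L, ff_width = d$width)
    }
    cfg <- train_config(d$lr, d$wd, epochs = base_cfg$epochs,
                        batch_size = base_cfg$batch_size,
                        seed = base_cfg$seed + i,
                        patience = base_cfg$patience)
    mses <- numeric(length(folds))
    for (f in seq_along(folds)) {
      val_tr <- data[sub_of %in% folds[[f]]]
      trn_tr <- data[!sub_of %in% folds[[f]]]
      model <- if (mode == "transfer") {
        finetune_transfer(pretrained, trn_tr, arch, cfg, val = val_tr)
      } else {
        train_direct(trn_tr, arch, cfg, val = val_tr)
      }
      pred <- predict(model, val_tr)
      mses[f] <- mean((pred - trials_to_xy(val_tr)$Y)^2)
      rows[[length(rows) + 1L]] <- data.frame(
        draw = i, fold = f, lr = d$lr, wd = d$wd, width = d$width,
        unfrozen = d$unfrozen, mse = mses[f])
    }
    summary$mean_mse[i] <- mean(mses)
    summary$n_params[i] <- count_params(
      build_model(arch, n_static = 7L, seed = 0L)$params)
  }
  ord <- order(summary$mean_mse, summary$n_params, summary$draw)
  best_i <- ord[1]
  d <- draws[[best_i]]
  list(best = list(draw = best_i, lr = d$lr, wd = d$wd, width = d$width,
                   unfrozen = d$unfrozen,
                   mean_mse = summary$mean_mse[best_i]),
       cv_table = do.call(rbind, rows), summary = summary)
}
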