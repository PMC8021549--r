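#' Training/architecture configuration for the impact-detection networks
#'
#' The four candidate architectures (`"M1"`–`"M4"`) all consume a 6-channel,
#' 200-sample kinematic window. Training defaults follow the study recipe:
#' stochastic gradient descent, batch size 32, 20 epochs, learning rate 0.01,
#' momentum 0.9.
#'
#' @param architecture_id One of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param batch_size,epochs,learning_rate,momentum SGD hyperparameters.
#' @param seed Integer seed governing weight initialization, epoch shuffling
#'   and dropout.
#' @param fusion For M3/M4, how the two 1D blocks are combined before the 2D
#'   convolution; `"stack"` (the default and only implemented reading) stacks
#'   the per-channel feature rows of both blocks into one single-channel
#'   image.
#' @return A `mignet_config` list.
#' @export
mignet_config <- function(architecture_id = c("M4", "M1", "M2", "M3"),
                          batch_size = 32, epochs = 20, learning_rate = 0.01,
                          momentum = 0.9, seed = 1, fusion = "stack") {
  architecture_id <- toupper(architecture_id[1])
  if (!architecture_id %in% c("M1", "M2", "M3", "M4")) {
    stop("unknown architecture_id '", architecture_id,
         "'; valid ids: M1, M2, M3, M4", call. = FALSE)
  }
  fusion <- match.arg(fusion, "stack")
  stopifnot(batch_size >= 1, epochs >= 1, learning_rate > 0,
            momentum >= 0, momentum < 1)
  structure(list(architecture_id = architecture_id,
                 input_shape = c(channels = 6L, samples = mg_const$n_samples),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed), fusion = fusion),
            class = "mignet_config")
}

# Node-list description of each architecture. `in_` refers to earlier node
# indices (0 = network input); omitted means "previous node".
arch_nodes <- function(id) {
  n <- function(op, ...) c(list(op = op), list(...))
  switch(id,
    M1 = list(
      n("conv1d", filters = 64, kernel = 3), n("relu"),
      n("conv1d", filters = 64, kernel = 3), n("relu"),
      n("maxpool1d"),
      n("conv1d", filters = 128, kernel = 3), n("relu"),
      n("conv1d", filters = 128, kernel = 3), n("relu"),
      n("gap"), n("dropout", rate = 0.5),
      n("dense", units = 1), n("head", activation = "sigmoid")),
    M2 = list(
      n("conv1d", filters = 128, kernel = 8), n("relu"), n("batchnorm"),
      n("conv1d", filters = 128, kernel = 5), n("relu"), n("batchnorm"),
      n("conv1d", filters = 128, kernel = 3), n("relu"), n("batchnorm"),
      n("gap"),
      n("dense", units = 2), n("head", activation = "softmax")),
    M3 = list(
      n("conv1d", filters = 48, kernel = 15), n("relu"),      # 1
      n("maxpool1d"), n("dropout", rate = 0.4),               # block 1 -> 4
      n("conv1d", filters = 96, kernel = 15), n("relu"),
      n("maxpool1d"), n("dropout", rate = 0.4),               # block 2 -> 8
      n("fuse_stack", in_ = c(4L, 8L)),
      n("conv2d", filters = 96, kh = 3, kw = 15), n("relu"),
      n("gap"), n("dropout", rate = 0.4),
      n("dense", units = 1), n("head", activation = "sigmoid")),
    M4 = list(
      n("conv1d", filters = 64, kernel = 5), n("relu"),
      n("maxpool1d"), n("batchnorm"), n("dropout", rate = 0.4),   # block 1 -> 5
      n("conv1d", filters = 128, kernel = 10), n("relu"),
      n("maxpool1d"), n("batchnorm"), n("dropout", rate = 0.4),   # block 2 -> 10
      n("fuse_stack", in_ = c(5L, 10L)),
      n("conv2d", filters = 64, kh = 3, kw = 15), n("relu"),
      n("gap"), n("batchnorm"),
      n("dropout", rate = 0.4),
      n("dense", units = 2), n("head", activation = "softmax"))
  )
}

#' Build an (untrained) impact-detection network
#'
#' Instantiates the layer stack of the requested architecture with seeded
#' Glorot-uniform weight initialization. M1 and M3 end in a single sigmoid
#' unit (trained with binary cross-entropy); M2 and M4 end in a two-unit
#' softmax (two-class cross-entropy). In M3/M4 the outputs of the two 1D
#' convolution blocks are fused into a single-channel 2D feature image —
#' the first block's map max-pooled along time to the common length, then
#' the per-channel feature rows of both blocks stacked — over which the 2D
#' convolution runs its 3 x 15 patch with 3 x 1 stride, one patch row-step
#' per stacked feature triple.
#'
#' @param config A [mignet_config()].
#' @return A `mignet_model` object (untrained).
#' @export
#' @examples
#' m <- build_mignet(mignet_config("M4", seed = 1))
#' glance(m)
build_mignet <- function(config = mignet_config()) {
  stopifnot(inherits(config, "mignet_config"))
  nodes <- arch_nodes(config$architecture_id)
  params <- list()
  state <- list()
  # shape walk: list(kind, T, C) ("1d"), (kind, R, W) ("2d"), (kind, C) ("vec")
  shp <- list(list(kind = "1d", T = mg_const$n_samples, C = 6L))
  with_seed_mg(config$seed, {
    for (i in seq_along(nodes)) {
      nd <- nodes[[i]]
      ins <- if (!is.null(nd$in_)) nd$in_ else i - 1L
      s <- shp[[ins[1] + 1L]]
      nm <- sprintf("n%02d", i)
      out <- s
      if (nd$op == "conv1d") {
        kC <- nd$kernel * s$C
        params[[paste0(nm, "_W")]] <-
          glorot_uniform(kC, nd$filters, kC, nd$kernel * nd$filters)
        params[[paste0(nm, "_b")]] <- numeric(nd$filters)
        out$C <- nd$filters
      } else if (nd$op == "conv2d") {
        kk <- nd$kh * nd$kw
        params[[paste0(nm, "_W")]] <-
          glorot_uniform(kk, nd$filters, kk, kk * nd$filters)
        params[[paste0(nm, "_b")]] <- numeric(nd$filters)
        out <- list(kind = "1d", T = (s$R %/% nd$kh) * s$W, C = nd$filters)
      } else if (nd$op == "dense") {
        params[[paste0(nm, "_W")]] <-
          glorot_uniform(s$C, nd$units, s$C, nd$units)
        params[[paste0(nm, "_b")]] <- numeric(nd$units)
        out$C <- nd$units
      } else if (nd$op == "batchnorm") {
        params[[paste0(nm, "_gamma")]] <- rep(1, s$C)
        params[[paste0(nm, "_beta")]] <- numeric(s$C)
        state[[paste0(nm, "_mean")]] <- numeric(s$C)
        state[[paste0(nm, "_var")]] <- rep(1, s$C)
      } else if (nd$op == "maxpool1d") {
        out$T <- s$T %/% 2L
      } else if (nd$op == "gap") {
        out <- list(kind = "vec", C = s$C)
      } else if (nd$op == "fuse_stack") {
        a <- shp[[ins[1] + 1L]]; b <- shp[[ins[2] + 1L]]
        out <- list(kind = "2d", R = a$C + b$C, W = b$T)
      }
      nodes[[i]]$in_ <- ins
      nodes[[i]]$name <- nm
      shp[[i + 1L]] <- out
    }
  })
  structure(list(config = config, nodes = nodes, shapes = shp,
                 params = params, state = state,
                 velocity = purrr::map(params, ~ .x * 0),
                 trained = FALSE, history = NULL, norm_stats = NULL,
                 class_weights = NULL, data_fingerprint = NULL,
                 format_version = 1L),
            class = "mignet_model")
}

#' @export
print.mignet_model <- function(x, ...) {
  cat(sprintf("<mignet_model %s> %s, %d parameters\n",
              x$config$architecture_id,
              if (x$trained) "trained" else "untrained",
              sum(purrr::map_int(x$params, length))))
  invisible(x)
}

#' Layer inventory of a built network
#'
#' One row per layer with its operation and salient hyperparameters, for
#' inspecting a built stack against its published description.
#'
#' @param model A `mignet_model`.
#' @return A tibble: `layer`, `op`, `filters`, `kernel`, `rate`, `units`,
#'   `activation`.
#' @export
mignet_layers <- function(model) {
  stopifnot(inherits(model, "mignet_model"))
  purrr::map_dfr(seq_along(model$nodes), function(i) {
    nd <- model$nodes[[i]]
    tibble::tibble(
      layer = i, op = nd$op,
      filters = nd$filters %||% NA_integer_,
      kernel = if (nd$op == "conv2d") sprintf("%dx%d", nd$kh, nd$kw)
               else if (!is.null(nd$kernel)) as.character(nd$kernel)
               else NA_character_,
      rate = nd$rate %||% NA_real_,
      units = nd$units %||% NA_integer_,
      activation = nd$activation %||% NA_character_)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Forward pass. X: (T, N, C). Returns head pre-activations Z, per-node
# caches, and (in training mode) updated batchnorm running stats.
mignet_forward <- function(model, X, train = FALSE) {
  outs <- vector("list", length(model$nodes) + 1L)
  caches <- vector("list", length(model$nodes))
  outs[[1L]] <- X
  state <- model$state
  p <- model$params
  Z <- NULL
  for (i in seq_along(model$nodes)) {
    nd <- model$nodes[[i]]
    nm <- nd$name
    xin <- outs[[nd$in_[1] + 1L]]
    res <- switch(nd$op,
      conv1d = conv1d_fwd(xin, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]],
                          nd$kernel),
      conv2d = conv2d_fwd(xin, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]],
                          nd$kh, nd$kw),
      relu = relu_fwd(xin),
      maxpool1d = maxpool1d_fwd(xin),
      dropout = dropout_fwd(xin, nd$rate, train),
      gap = gap_fwd(xin),
      dense = dense_fwd(xin, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]]),
      batchnorm = {
        r <- bn_fwd(xin, p[[paste0(nm, "_gamma")]], p[[paste0(nm, "_beta")]],
                    state[[paste0(nm, "_mean")]], state[[paste0(nm, "_var")]],
                    train)
        state[[paste0(nm, "_mean")]] <- r$run_mean
        state[[paste0(nm, "_var")]] <- r$run_var
        r
      },
      fuse_stack = fuse_stack_fwd(outs[[nd$in_[1] + 1L]],
                                  outs[[nd$in_[2] + 1L]]),
      head = list(out = xin, cache = NULL)
    )
    outs[[i + 1L]] <- res$out
    caches[i] <- list(res$cache)    # [[<- would drop NULL caches
    if (nd$op == "head") Z <- xin
  }
  list(Z = Z, outs = outs, caches = caches, state = state)
}

# Backward pass from head-gradient dZ; returns named gradient list.
mignet_backward <- function(model, fwd, dZ) {
  p <- model$params
  grads <- list()
  douts <- vector("list", length(model$nodes) + 1L)
  douts[[length(model$nodes) + 1L]] <- dZ
  add_grad <- function(slot, val) {
    if (is.null(douts[[slot]])) douts[[slot]] <<- val
    else douts[[slot]] <<- douts[[slot]] + val
  }
  for (i in rev(seq_along(model$nodes))) {
    nd <- model$nodes[[i]]
    nm <- nd$name
    dY <- douts[[i + 1L]]
    if (is.null(dY)) next
    cache <- fwd$caches[[i]]
    if (nd$op == "conv1d") {
      r <- conv1d_bwd(dY, cache, p[[paste0(nm, "_W")]])
      grads[[paste0(nm, "_W")]] <- r$dW
      grads[[paste0(nm, "_b")]] <- r$db
      add_grad(nd$in_[1] + 1L, r$dX)
    } else if (nd$op == "conv2d") {
      r <- conv2d_bwd(dY, cache, p[[paste0(nm, "_W")]])
      grads[[paste0(nm, "_W")]] <- r$dW
      grads[[paste0(nm, "_b")]] <- r$db
      add_grad(nd$in_[1] + 1L, r$dX)
    } else if (nd$op == "dense") {
      r <- dense_bwd(dY, cache, p[[paste0(nm, "_W")]])
      grads[[paste0(nm, "_W")]] <- r$dW
      grads[[paste0(nm, "_b")]] <- r$db
      add_grad(nd$in_[1] + 1L, r$dX)
    } else if (nd$op == "batchnorm") {
      r <- bn_bwd(dY, cache, p[[paste0(nm, "_gamma")]])
      grads[[paste0(nm, "_gamma")]] <- r$dgamma
      grads[[paste0(nm, "_beta")]] <- r$dbeta
      add_grad(nd$in_[1] + 1L, r$dX)
    } else if (nd$op == "relu") {
      add_grad(nd$in_[1] + 1L, relu_bwd(dY, cache))
    } else if (nd$op == "maxpool1d") {
      add_grad(nd$in_[1] + 1L, maxpool1d_bwd(dY, cache))
    } else if (nd$op == "dropout") {
      add_grad(nd$in_[1] + 1L, dropout_bwd(dY, cache))
    } else if (nd$op == "gap") {
      add_grad(nd$in_[1] + 1L, gap_bwd(dY, cache))
    } else if (nd$op == "fuse_stack") {
      r <- fuse_stack_bwd(dY, cache)
      add_grad(nd$in_[1] + 1L, r$dA)
      add_grad(nd$in_[2] + 1L, r$dB)
    } else if (nd$op == "head") {
      add_grad(nd$in_[1] + 1L, dY)
    }
  }
  grads
}


# Re-estimate batchnorm running statistics after training: dropout inflates
# train-time activation variance, so statistics accumulated during training
# mismatch the dropout-free inference distribution (the classic
# dropout->batchnorm variance shift). One pass over the training data with
# dropout disabled, accumulating an exact arithmetic mean of batch
# statistics, realigns the stored statistics with the inference path.
refresh_bn_stats <- function(model, X, batch_size, act) {
  if (length(model$state) == 0) return(model)
  model$state <- purrr::map(model$state, ~ 0 * .x)
  n <- dim(X)[2]
  b <- 0L
  for (lo in seq(1L, n, by = batch_size)) {
    hi <- min(lo + batch_size - 1L, n)
    b <- b + 1L
    st <- mignet_step_cpp(model$nodes, model$params, model$state,
                          X[, lo:hi, , drop = FALSE],
                          integer(hi - lo + 1L), rep(1, hi - lo + 1L),
                          TRUE, FALSE, act, dropout_on = FALSE,
                          bn_momentum = (b - 1) / b)
    model$state <- st$state
  }
  model
}

head_activation <- function(model) {
  model$nodes[[length(model$nodes)]]$activation
}

# Eval-mode forward on an already-normalized (T, N, C) array, batched to
# bound memory; returns p(true impact) per event.
mignet_prob <- function(model, X, batch = 256L) {
  n <- dim(X)[2]
  act <- head_activation(model)
  p <- numeric(n)
  for (lo in seq(1L, n, by = batch)) {
    hi <- min(lo + batch - 1L, n)
    st <- mignet_step_cpp(model$nodes, model$params, model$state,
                          X[, lo:hi, , drop = FALSE],
                          integer(hi - lo + 1L), rep(1, hi - lo + 1L),
                          FALSE, FALSE, act)
    p[lo:hi] <- st$p
  }
  p
}

# Reference (R-level, double precision) forward probability; used to
# cross-check the compiled single-precision engine.
mignet_prob_ref <- function(model, X) {
  act <- head_activation(model)
  Z <- mignet_forward(model, X, train = FALSE)$Z
  if (act == "sigmoid") as.vector(sigmoid(Z)) else softmax2(Z)[, 2L]
}

#' Train an impact-detection network
#'
#' Stochastic gradient descent with the configuration's learning rate,
#' momentum, batch size and epoch count. Each example's loss is multiplied by
#' its class weight (by default the inverse-frequency weights of the
#' *training* partition, see [compute_class_weights()]), so the imbalanced
#' classes contribute equally. By default events are standardized per channel
#' with statistics computed from the training set only; the statistics are
#' stored on the model and re-applied by [predict.mignet_model()]. Identical
#' seed and data reproduce the run exactly.
#'
#' @param model An untrained (or warm) `mignet_model`.
#' @param train_events,val_events Labeled event tibbles; validation is
#'   optional and never trained on.
#' @param class_weights Named weights (`TRUE_IMPACT`, `FALSE_EVENT`);
#'   default computed from `train_events`.
#' @param normalize Standardize channels using training-set statistics
#'   (default `TRUE`; `FALSE` trains on raw units).
#' @param shuffle Reshuffle batches every epoch (seeded; default `TRUE`).
#' @param verbose Print per-epoch metrics.
#' @return The trained `mignet_model`, with `$history` holding per-epoch
#'   train/validation loss and accuracy.
#' @export
train_mignet <- function(model, train_events, val_events = NULL,
                         class_weights = NULL, normalize = TRUE,
                         shuffle = TRUE, verbose = FALSE) {
  stopifnot(inherits(model, "mignet_model"))
  cfg <- model$config
  if (length(unique(train_events$label)) < 2L) {
    stop("training set contains a single class; cannot train a discriminator",
         call. = FALSE)
  }
  if (is.null(class_weights)) {
    class_weights <- compute_class_weights(train_events$label)
  }
  if (normalize) {
    st <- channel_stats(train_events)
    train_events <- normalize_events(train_events, st)$events
    if (!is.null(val_events)) {
      val_events <- normalize_events(val_events, st)$events
    }
    model$norm_stats <- st
  }
  X <- events_to_array(train_events)
  y <- events_to_target(train_events)
  w <- unname(class_weights[train_events$label])
  n <- length(y)
  model$data_fingerprint <- sprintf("n=%d;sum=%.8e;ysum=%d", n, sum(X), sum(y))
  model$class_weights <- class_weights
  if (!is.null(val_events)) {
    Xv <- events_to_array(val_events)
    yv <- events_to_target(val_events)
    wv <- unname(class_weights[val_events$label])
  }
  act <- head_activation(model)
  hist <- vector("list", cfg$epochs)

  with_seed_mg(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      idx <- if (shuffle) sample.int(n) else seq_len(n)
      ep_loss <- 0; ep_correct <- 0
      for (lo in seq(1L, n, by = cfg$batch_size)) {
        bi <- idx[lo:min(lo + cfg$batch_size - 1L, n)]
        st <- mignet_step_cpp(model$nodes, model$params, model$state,
                              X[, bi, , drop = FALSE], as.integer(y[bi]),
                              w[bi], TRUE, TRUE, act)
        model$state <- st$state
        if (!is.finite(st$loss)) {
          stop(sprintf("non-finite loss at epoch %d (batch starting %d); aborting",
                       ep, lo), call. = FALSE)
        }
        grads <- st$grads
        for (nm in names(grads)) {
          g <- grads[[nm]]
          if (is.matrix(model$params[[nm]]) && !is.matrix(g)) dim(g) <- dim(model$params[[nm]])
          if (!is.matrix(model$params[[nm]])) g <- as.numeric(g)
          model$velocity[[nm]] <- cfg$momentum * model$velocity[[nm]] -
            cfg$learning_rate * g
          model$params[[nm]] <- model$params[[nm]] + model$velocity[[nm]]
        }
        ep_loss <- ep_loss + st$loss * length(bi)
        ep_correct <- ep_correct + st$correct
      }
      row <- tibble::tibble(epoch = ep, train_loss = ep_loss / n,
                            train_acc = ep_correct / n,
                            val_loss = NA_real_, val_acc = NA_real_)
      if (!is.null(val_events)) {
        pv <- mignet_prob(model, Xv)
        eps <- 1e-12
        row$val_loss <- -mean(wv * (yv * log(pv + eps) +
                                      (1 - yv) * log(1 - pv + eps)))
        row$val_acc <- mean((pv >= 0.5) == (yv == 1L))
      }
      hist[[ep]] <- row
      if (verbose) {
        message(sprintf(
          "epoch %2d/%d  loss %.4f acc %.3f%s", ep, cfg$epochs,
          row$train_loss, row$train_acc,
          if (!is.null(val_events)) sprintf("  val_loss %.4f val_acc %.3f",
                                            row$val_loss, row$val_acc) else ""))
      }
    }
    model <- refresh_bn_stats(model, X, cfg$batch_size, act)
  })
  model$history <- dplyr::bind_rows(hist)
  model$trained <- TRUE
  model
}

#' Classify events with a trained network
#'
#' Applies the model's stored per-channel training statistics (when present),
#' runs an evaluation-mode forward pass, and thresholds at 0.5 — a
#' probability of exactly 0.5 is called `TRUE_IMPACT`, favoring sensitivity
#' (missing a real impact costs more than flagging an artifact).
#'
#' @param object A trained `mignet_model`.
#' @param events An event tibble.
#' @param ... Unused.
#' @return A tibble: `event_id`, `p_true`, `pred_label`.
#' @export
predict.mignet_model <- function(object, events, ...) {
  validate_events(events, shape_only = TRUE)
  if (!is.null(object$norm_stats)) {
    events <- normalize_events(events, object$norm_stats)$events
  }
  p <- mignet_prob(object, events_to_array(events))
  tibble::tibble(event_id = events$event_id, p_true = p,
                 pred_label = ifelse(p >= 0.5, "TRUE_IMPACT", "FALSE_EVENT"))
}

#' Evaluation-mode weighted loss of a model on a labeled set
#'
#' Cross-entropy of the current parameters, each example's loss multiplied by
#' its class weight; no dropout, batch statistics frozen. `reduce = "sum"`
#' returns the summed weighted loss, under which duplicating an example is
#' exactly equivalent to doubling its weight.
#'
#' @param model A `mignet_model`.
#' @param events Labeled event tibble (normalized with the model's stats if
#'   present).
#' @param class_weights Named per-class weights (default: all 1).
#' @param reduce `"mean"` or `"sum"`.
#' @return A single numeric loss value.
#' @export
mignet_loss <- function(model, events, class_weights = NULL,
                        reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  if (is.null(class_weights)) {
    class_weights <- c(TRUE_IMPACT = 1, FALSE_EVENT = 1)
  }
  if (!is.null(model$norm_stats)) {
    events <- normalize_events(events, model$norm_stats)$events
  }
  y <- events_to_target(events)
  w <- unname(class_weights[events$label])
  p <- mignet_prob(model, events_to_array(events))
  eps <- 1e-12
  l <- -w * (y * log(p + eps) + (1 - y) * log(1 - p + eps))
  if (reduce == "mean") mean(l) else sum(l)
}

#' Save / load a trained model
#'
#' The on-disk artifact is version-stamped; loading refuses files whose
#' format version does not match, and reports corrupt files as load errors.
#' A save/load round trip preserves predictions bit for bit.
#'
#' @param model A `mignet_model`.
#' @param path File path.
#' @return `path` invisibly (save); the restored `mignet_model` (load).
#' @export
save_mignet <- function(model, path) {
  stopifnot(inherits(model, "mignet_model"))
  saveRDS(list(format = "mignet_model", format_version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_mignet
#' @export
load_mignet <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt model file: ",
                                           conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, "mignet_model")) {
    stop("not a saved model artifact: ", path, call. = FALSE)
  }
  if (!identical(obj$format_version, 1L)) {
    stop("unsupported model format version: ", obj$format_version,
         call. = FALSE)
  }
  obj$model
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-epoch training history
#'
#' @param x A trained `mignet_model`.
#' @param ... Unused.
#' @return A tibble with one row per epoch: train/validation loss and
#'   accuracy.
#' @method tidy mignet_model
#' @export
tidy.mignet_model <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(0), train_loss = numeric(0),
                          train_acc = numeric(0), val_loss = numeric(0),
                          val_acc = numeric(0)))
  }
  x$history
}

#' One-row model summary
#'
#' @param x A `mignet_model`.
#' @param ... Unused.
#' @return A tibble: architecture, parameter count, epochs trained, final
#'   losses/accuracies.
#' @method glance mignet_model
#' @export
glance.mignet_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    architecture = x$config$architecture_id,
    n_parameters = sum(purrr::map_int(x$params, length)),
    trained = x$trained,
    epochs = if (is.null(h)) 0L else nrow(h),
    final_train_acc = if (is.null(h)) NA_real_ else h$train_acc[nrow(h)],
    final_val_acc = if (is.null(h)) NA_real_ else h$val_acc[nrow(h)])
}
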