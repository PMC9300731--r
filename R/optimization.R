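# Training strategies. Three update rules share one vocabulary:
#   * mtl_vanilla  - one step on the aggregated loss sum_k c_k * L_k
#   * mtl_alternate- N sequential plain gradient steps, task k evaluated at
#                    the weights left behind by task k-1
#   * mtl_io       - as alternate, but each task's gradient is transformed by
#                    that task's OWN moving-average optimizer (Adam by
#                    default), so no task ever sees another task's gradient
#                    history
# The generic functions below operate on plain numeric weight vectors with
# user-supplied per-task loss closures; train() drives the same rules through
# the compiled network path.

#' Training configuration
#'
#' @param strategy `"mtl_io"`, `"mtl_alternate"`, `"mtl_vanilla"`, or
#'   `"stl:<task>"` for a single-task run.
#' @param learning_rate Step size `eta > 0`.
#' @param epochs Number of passes over the training set.
#' @param batch_size Mini-batch size (the same batch is shared by all
#'   per-task sub-steps of one iteration).
#' @param task_order Order in which tasks take their sub-steps within one
#'   iteration; must be a permutation of the active tasks. Default
#'   od, oc, fovea, glaucoma.
#' @param seed Seed for mini-batch shuffling.
#' @param optimizer_kind `"adam"` or `"sgd"`; either a single value or a
#'   named vector per task. Governs the per-task transform of `mtl_io` and
#'   the shared optimizer of `mtl_vanilla`; `mtl_alternate` is by definition
#'   plain gradient descent.
#' @param beta1,beta2,adam_eps Adam moment decays (0.9, 0.999) and epsilon
#'   (1e-8).
#' @param loss_weights Per-task loss coefficients `c^(k)`; uniform weighting
#'   (all 1) by default.
#' @param gamma Focal-loss exponent for the glaucoma task.
#' @param sigma Saliency-map spread in pixels for the fovea target maps;
#'   `NULL` means 8 px scaled by `input_size / 512`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(strategy = "mtl_io", learning_rate = 1e-3,
                         epochs = 30L, batch_size = 8L,
                         task_order = c("od", "oc", "fovea", "glaucoma"),
                         seed = 1L, optimizer_kind = "adam",
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         loss_weights = c(od = 1, oc = 1, fovea = 1,
                                          glaucoma = 1),
                         gamma = 2, sigma = NULL) {
  ok <- strategy %in% c("mtl_io", "mtl_alternate", "mtl_vanilla") ||
    grepl("^stl:(od|oc|fovea|glaucoma)$", strategy)
  if (!ok) stop("unknown strategy: ", strategy)
  if (learning_rate < 0) stop("learning_rate must be non-negative")
  if (!all(optimizer_kind %in% c("adam", "sgd")))
    stop("optimizer_kind must be 'adam' or 'sgd'")
  structure(list(strategy = strategy, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 task_order = task_order, seed = as.integer(seed),
                 optimizer_kind = optimizer_kind, beta1 = beta1,
                 beta2 = beta2, adam_eps = adam_eps,
                 loss_weights = loss_weights, gamma = gamma, sigma = sigma),
            class = "train_config")
}

lw_for <- function(config, task) {
  w <- config$loss_weights
  if (!is.null(names(w)) && task %in% names(w)) unname(w[[task]]) else 1
}

opt_kind_for <- function(config, task) {
  k <- config$optimizer_kind
  if (length(k) == 1 && is.null(names(k))) return(unname(k))
  unname(k[[task]] %||% "adam")
}

#' Per-task optimizer state for the generic step functions
#'
#' Holds, for every task (plus a `"shared"` slot used by the aggregated
#' strategy), first/second moment accumulators over the weight vector and a
#' step counter. Task `k`'s accumulators are only ever updated by task-`k`
#' steps.
#'
#' @param tasks Character vector of task names.
#' @param n_par Length of the weight vector.
#' @return An object of class `optimizer_state`.
#' @export
optimizer_state <- function(tasks, n_par) {
  slots <- lapply(c(tasks, "shared"), function(t)
    list(m = numeric(n_par), v = numeric(n_par), t = 0L))
  names(slots) <- c(tasks, "shared")
  structure(slots, class = "optimizer_state")
}

# Adam transform of a raw gradient through one slot; returns the update
# direction m-hat(g) and the advanced slot.
adam_transform <- function(g, slot, config) {
  t <- slot$t + 1L
  m <- config$beta1 * slot$m + (1 - config$beta1) * g
  v <- config$beta2 * slot$v + (1 - config$beta2) * g^2
  mhat <- m / (1 - config$beta1^t)
  vhat <- v / (1 - config$beta2^t)
  list(dir = mhat / (sqrt(vhat) + config$adam_eps),
       slot = list(m = m, v = v, t = t))
}

check_losses <- function(losses, config) {
  if (is.null(names(losses)) || any(!nzchar(names(losses))))
    stop("losses must be a named list of per-task gradient closures")
  missing <- setdiff(config$task_order, names(losses))
  if (length(missing))
    stop("missing loss for active task(s): ", paste(missing, collapse = ", "))
}

eval_task <- function(losses, task, w, batch) {
  out <- losses[[task]](w, batch)
  if (!is.list(out) || is.null(out$grad))
    stop("loss closures must return list(value=, grad=)")
  out
}

#' One aggregated-loss update (standard multi-task step)
#'
#' Evaluates every task's gradient at the same weights `w_t` and applies a
#' single update with the summed gradient `sum_k c_k g_k` through one shared
#' optimizer state: `w <- w - eta * sum_k c_k g_k` for plain SGD.
#'
#' @param weights Numeric weight vector `w_t`.
#' @param batch Opaque data sample passed to each loss closure.
#' @param losses Named list (one entry per active task) of closures
#'   `function(w, batch)` returning `list(value=, grad=)`.
#' @param config A [train_config()].
#' @param state An [optimizer_state()] (used when `optimizer_kind = "adam"`).
#' @return `list(weights=, state=, losses=)`.
#' @export
vanilla_step <- function(weights, batch, losses, config,
                         state = optimizer_state(config$task_order,
                                                 length(weights))) {
  check_losses(losses, config)
  g <- numeric(length(weights))
  vals <- numeric(0)
  for (task in config$task_order) {
    ev <- eval_task(losses, task, weights, batch)
    cw <- lw_for(config, task)
    g <- g + cw * ev$grad
    vals[task] <- cw * ev$value
  }
  if (opt_kind_for(config, "shared") == "sgd" ||
      all(config$optimizer_kind == "sgd")) {
    weights <- weights - config$learning_rate * g
  } else {
    tr <- adam_transform(g, state$shared, config)
    state$shared <- tr$slot
    weights <- weights - config$learning_rate * tr$dir
  }
  list(weights = weights, state = state, losses = vals)
}

#' One alternating update (plain per-task gradient steps)
#'
#' Executes one plain gradient step per task in `config$task_order`, each
#' task's gradient evaluated at the intermediate weights left by the previous
#' task:
#' `w^(k) = w^(k-1) - eta * g_k(w^(k-1))`, with `w^(0)` the incoming weights.
#'
#' @inheritParams vanilla_step
#' @return `list(weights=, state=NULL, losses=)`.
#' @export
alternate_step <- function(weights, batch, losses, config) {
  check_losses(losses, config)
  vals <- numeric(0)
  for (task in config$task_order) {
    ev <- eval_task(losses, task, weights, batch)
    cw <- lw_for(config, task)
    weights <- weights - config$learning_rate * cw * ev$grad
    vals[task] <- cw * ev$value
  }
  list(weights = weights, state = NULL, losses = vals)
}

#' One alternating update with independent per-task optimizers (MTL-IO)
#'
#' As [alternate_step()], but each task's gradient is transformed by that
#' task's own exponential-moving-average mechanism before being applied:
#' `w^(k) = w^(k-1) - eta * mhat_k(g_k(w^(k-1)))`. With `optimizer_kind =
#' "sgd"` the transform is the identity and the rule coincides exactly with
#' [alternate_step()]; with Adam (default) each task keeps private first and
#' second moments, so the memory term of task `k` only ever involves previous
#' updates of task `k`.
#'
#' @inheritParams vanilla_step
#' @return `list(weights=, state=, losses=)`.
#' @export
mtl_io_step <- function(weights, batch, losses, config,
                        state = optimizer_state(config$task_order,
                                                length(weights))) {
  check_losses(losses, config)
  if (!all(config$task_order %in% names(state)))
    stop("optimizer state is missing slots for: ",
         paste(setdiff(config$task_order, names(state)), collapse = ", "))
  vals <- numeric(0)
  for (task in config$task_order) {
    ev <- eval_task(losses, task, weights, batch)
    cw <- lw_for(config, task)
    g <- cw * ev$grad
    if (opt_kind_for(config, task) == "sgd") {
      dir <- g
    } else {
      tr <- adam_transform(g, state[[task]], config)
      state[[task]] <- tr$slot
      dir <- tr$dir
    }
    weights <- weights - config$learning_rate * dir
    vals[task] <- cw * ev$value
  }
  list(weights = weights, state = state, losses = vals)
}

#' Deterministic k-fold cross-validation splits
#'
#' Shuffles the ids with the given seed and partitions them into `k`
#' near-equal validation folds; every id appears in exactly one validation
#' fold. Mirrors merging-and-shuffling a train+validation pool while keeping
#' any test set untouched.
#'
#' @param item_ids Vector of unique ids.
#' @param k Number of folds, `>= 2`.
#' @param seed RNG seed.
#' @return List of `k` elements `list(train = , val = )`.
#' @export
kfold_splits <- function(item_ids, k, seed = 1L) {
  n <- length(item_ids)
  if (anyDuplicated(item_ids)) stop("item_ids must be unique")
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k must not exceed the number of items")
  shuffled <- with_seed(seed, sample(item_ids))
  fold_of <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(f)
    list(train = shuffled[fold_of != f], val = shuffled[fold_of == f]))
}

# ---------------------------------------------------------------------------
# Network training loop
# ---------------------------------------------------------------------------

active_tasks <- function(model, config) {
  if (grepl("^stl:", config$strategy)) {
    t <- sub("^stl:", "", config$strategy)
    if (!t %in% model$config$tasks)
      stop("strategy ", config$strategy, " but model lacks task ", t)
    return(t)
  }
  intersect(config$task_order, model$config$tasks)
}

# Build the (S,S,B) target stack for one batch of a task.
batch_targets <- function(dataset, task, idx, fovea_maps) {
  S <- dim(dataset$images)[1]
  if (task == "od") return(dataset$od_masks[, , idx, drop = FALSE] * 1)
  if (task == "oc") return(dataset$oc_masks[, , idx, drop = FALSE] * 1)
  if (task == "fovea") return(fovea_maps[, , idx, drop = FALSE])
  as.numeric(dataset$labels[idx])
}

#' Train the network
#'
#' Runs seeded shuffled mini-batch epochs under the configured strategy,
#' records per-task training losses, and (when the glaucoma task is active)
#' fits the vCDR logistic classifier on the training-set predictions after
#' the network training finishes. The two glaucoma scores - the network's
#' fully-connected head and the logistic classifier on the predicted vertical
#' cup-to-disc ratio - are later averaged by [evaluate()].
#'
#' The model handle is updated in place and also returned.
#'
#' @param model An [build_model()] handle.
#' @param dataset A `fundus_dataset` (see [generate_dataset()] /
#'   [load_fundus_dataset()]) providing images plus, per active task, masks,
#'   fovea coordinates and labels.
#' @param config A [train_config()].
#' @return `list(model=, history=, classifier=)` of class `mtl_training`;
#'   `history` is a data.frame with one row per epoch and one column of mean
#'   training loss per task.
#' @export
train <- function(model, dataset, config = train_config()) {
  stopifnot(inherits(model, "mtl_model"), inherits(config, "train_config"))
  n <- dataset$n
  if (is.null(n) || n == 0) stop("dataset is empty")
  tasks <- active_tasks(model, config)
  if (length(tasks) == 0) stop("no active task shared by model and config")
  S <- model$config$input_size
  if (dim(dataset$images)[1] != S)
    stop("dataset image size ", dim(dataset$images)[1],
         " does not match model input_size ", S)
  for (t in tasks) {
    miss <- switch(t,
      od = is.null(dataset$od_masks), oc = is.null(dataset$oc_masks),
      fovea = is.null(dataset$fovea), glaucoma = is.null(dataset$labels))
    if (miss) stop("dataset lacks targets for active task: ", t)
  }
  sigma <- config$sigma %||% (8 * S / 512)

  fovea_maps <- NULL
  if ("fovea" %in% tasks) {
    fovea_maps <- array(0, c(S, S, n))
    for (i in seq_len(n)) {
      sp <- saliency_spec(dataset$fovea[i, 1], dataset$fovea[i, 2],
                          sigma, S, S)
      fovea_maps[, , i] <- make_fovea_map(sp)
    }
  }

  .net_reset_optimizers(model$ptr)
  lw <- config$loss_weights
  strat <- if (grepl("^stl:", config$strategy)) "mtl_vanilla" else
    config$strategy
  history <- NULL

  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      starts <- seq(1, n, by = config$batch_size)
      ep_loss <- stats::setNames(numeric(length(tasks)), tasks)
      nb <- 0L
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1, n)]
        xb <- dataset$images[, , , idx, drop = FALSE]
        if (strat == "mtl_vanilla") {
          .net_forward(model$ptr, xb, tasks)
          tg <- stats::setNames(
            lapply(tasks, batch_targets, dataset = dataset, idx = idx,
                   fovea_maps = fovea_maps), tasks)
          lo <- .net_backward(model$ptr, tasks, tg, lw, config$gamma, FALSE)
          if (opt_kind_for(config, "shared") == "sgd" ||
              all(config$optimizer_kind == "sgd")) {
            .net_apply_sgd(model$ptr, tasks, config$learning_rate)
          } else {
            .net_apply_adam(model$ptr, "shared", tasks, config$learning_rate,
                            config$beta1, config$beta2, config$adam_eps)
          }
          ep_loss[tasks] <- ep_loss[tasks] + lo[tasks]
        } else {
          for (t in tasks) {
            .net_forward(model$ptr, xb, t)
            tg <- stats::setNames(
              list(batch_targets(dataset, t, idx, fovea_maps)), t)
            lo <- .net_backward(model$ptr, t, tg, lw, config$gamma, FALSE)
            if (strat == "mtl_alternate" ||
                opt_kind_for(config, t) == "sgd") {
              .net_apply_sgd(model$ptr, t, config$learning_rate)
            } else {
              .net_apply_adam(model$ptr, t, t, config$learning_rate,
                              config$beta1, config$beta2, config$adam_eps)
            }
            ep_loss[t] <- ep_loss[t] + lo[[t]]
          }
        }
        nb <- nb + 1L
      }
      ep_loss <- ep_loss / nb
      if (any(!is.finite(ep_loss)))
        stop("non-finite training loss at epoch ", ep, ": ",
             paste(sprintf("%s=%g", names(ep_loss), ep_loss),
                   collapse = ", "))
      history <- rbind(history, data.frame(epoch = ep, t(ep_loss)))
    }
  })

  classifier <- NULL
  if ("glaucoma" %in% tasks && all(c("od", "oc") %in% model$config$tasks) &&
      !is.null(dataset$od_masks)) {
    vc <- predict_vcdr(model, dataset)
    if (length(unique(dataset$labels)) == 2) {
      classifier <- fit_logistic(vc, dataset$labels)
    } else {
      warning("training labels are single-class; vCDR classifier not fitted")
    }
  }
  model$classifier <- classifier
  structure(list(model = model, history = history, classifier = classifier),
            class = "mtl_training")
}

# Predicted vCDR for every image of a dataset (thresholded + main component).
predict_vcdr <- function(model, dataset, batch_size = 8L) {
  n <- dataset$n
  out <- numeric(n)
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, n)
    fw <- forward(model, dataset$images[, , , idx, drop = FALSE],
                  intersect(c("od", "oc"), model$config$tasks))
    for (j in seq_along(idx)) {
      odm <- suppressWarnings(
        largest_connected_component(fw$od[, , j] >= 0.5)$mask)
      ocm <- suppressWarnings(
        largest_connected_component(fw$oc[, , j] >= 0.5)$mask)
      rec <- compute_vcdr(odm, ocm)
      out[idx[j]] <- if (is.na(rec$vcdr)) 0 else rec$vcdr
    }
  }
  out
}
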