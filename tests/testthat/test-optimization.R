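# The scalar toy problem used throughout: two quadratic task losses
# L1 = (w - 1)^2, L2 = (w + 1)^2 with analytic gradients.
toy_losses <- list(
  t1 = function(w, batch) list(value = (w - 1)^2, grad = 2 * (w - 1)),
  t2 = function(w, batch) list(value = (w + 1)^2, grad = 2 * (w + 1)))
toy_config <- function(...) {
  train_config(task_order = c("t1", "t2"), learning_rate = 0.1,
               loss_weights = c(t1 = 1, t2 = 1), optimizer_kind = "sgd", ...)
}

test_that("aggregated updates follow the summed gradient", {
  cfg <- toy_config()
  # symmetric point: total gradient 4w = 0
  expect_equal(vanilla_step(0, NULL, toy_losses, cfg)$weights, 0)
  # w = 1: g = 0 + 4 -> w <- 1 - 0.1 * 4 = 0.6
  expect_equal(vanilla_step(1, NULL, toy_losses, cfg)$weights, 0.6)
  # a single active task reduces to a plain single-task step
  cfg1 <- train_config(task_order = "t1", learning_rate = 0.1,
                       loss_weights = c(t1 = 1), optimizer_kind = "sgd")
  expect_identical(vanilla_step(0.5, NULL, toy_losses["t1"], cfg1)$weights,
                   0.5 - 0.1 * 2 * (0.5 - 1))
  expect_error(vanilla_step(0, NULL, toy_losses["t1"], cfg), "missing loss")
})

test_that("alternating updates use intermediate weights and depend on order", {
  cfg <- toy_config()
  # hand computation: g1(0) = -2 -> w = 0.2; g2(0.2) = 2.4 -> w = -0.04
  expect_equal(alternate_step(0, NULL, toy_losses, cfg)$weights, -0.04,
               tolerance = 1e-15)
  # swapped order mirrors the trajectory
  cfg_swap <- train_config(task_order = c("t2", "t1"), learning_rate = 0.1,
                           loss_weights = c(t1 = 1, t2 = 1),
                           optimizer_kind = "sgd")
  expect_equal(alternate_step(0, NULL, toy_losses, cfg_swap)$weights, 0.04,
               tolerance = 1e-15)
  # zero learning rate leaves the weights untouched
  cfg0 <- train_config(task_order = c("t1", "t2"), learning_rate = 0,
                       optimizer_kind = "sgd")
  expect_identical(alternate_step(0.3, NULL, toy_losses, cfg0)$weights, 0.3)
})

test_that("mtl_io with sgd transform is bitwise identical to alternation", {
  set.seed(31)
  for (rep in 1:10) {
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    losses <- list(
      t1 = function(w, batch) list(value = (w - a)^2, grad = 2 * (w - a)),
      t2 = function(w, batch) list(value = (w + b)^2, grad = 2 * (w + b)))
    cfg <- toy_config()
    w <- runif(1, -1, 1)
    st <- optimizer_state(cfg$task_order, 1L)
    wa <- w; wio <- w
    for (it in 1:5) {
      wa <- alternate_step(wa, NULL, losses, cfg)$weights
      out <- mtl_io_step(wio, NULL, losses, cfg, st)
      wio <- out$weights; st <- out$state
    }
    expect_identical(wa, wio)
  }
})

test_that("the first per-task adam step moves by ~lr in the gradient sign", {
  cfg <- train_config(task_order = "t1", learning_rate = 0.1,
                      loss_weights = c(t1 = 1), optimizer_kind = "adam")
  st <- optimizer_state(c("t1", "t2"), 1L)
  out <- mtl_io_step(0, NULL, toy_losses["t1"], cfg, st)
  # g = -2; bias-corrected first step = lr * g / (sqrt(g^2) + eps)
  expect_equal(out$weights, 0.1 * 2 / (2 + 1e-8), tolerance = 1e-12)
  expect_equal(out$state$t1$t, 1L)
  expect_equal(out$state$t2$t, 0L)
})

test_that("per-task optimizer slots are isolated from foreign-task steps", {
  # task z has identically zero gradient, so its steps leave the weights
  # untouched; interleaving them must not perturb task t1's accumulators
  losses <- list(
    t1 = function(w, batch) list(value = (w - 1)^2, grad = 2 * (w - 1)),
    z = function(w, batch) list(value = 0, grad = 0 * w))
  cfg_t1 <- train_config(task_order = "t1", learning_rate = 0.01,
                         loss_weights = c(t1 = 1), optimizer_kind = "adam")
  cfg_z <- train_config(task_order = "z", learning_rate = 0.01,
                        loss_weights = c(z = 1), optimizer_kind = "adam")

  st_a <- optimizer_state(c("t1", "z"), 1L)
  w_a <- 0
  for (it in 1:3) {
    out <- mtl_io_step(w_a, NULL, losses["t1"], cfg_t1, st_a)
    w_a <- out$weights; st_a <- out$state
  }

  st_b <- optimizer_state(c("t1", "z"), 1L)
  w_b <- 0
  for (it in 1:3) {
    out <- mtl_io_step(w_b, NULL, losses["t1"], cfg_t1, st_b)
    w_b <- out$weights; st_b <- out$state
    out <- mtl_io_step(w_b, NULL, losses["z"], cfg_z, st_b)
    w_b <- out$weights; st_b <- out$state
  }
  expect_identical(st_a$t1, st_b$t1)
  expect_identical(w_a, w_b)
})

test_that("step rules match hand-computed gradients on a linear model", {
  # 2-parameter linear model, 2 tasks, 3 data points each
  X <- cbind(c(1, 2, -1), c(0.5, -1, 1.5))
  y1 <- c(1, 0, 2); y2 <- c(-1, 1, 0)
  make_loss <- function(y) function(w, batch) {
    r <- as.numeric(X %*% w) - y
    list(value = mean(r^2), grad = as.numeric(2 * t(X) %*% r / length(y)))
  }
  losses <- list(a = make_loss(y1), b = make_loss(y2))
  cfg <- train_config(task_order = c("a", "b"), learning_rate = 0.05,
                      loss_weights = c(a = 1, b = 1), optimizer_kind = "sgd")
  w0 <- c(0.2, -0.3)
  grad_at <- function(w, y) as.numeric(2 * t(X) %*% (X %*% w - y) / 3)

  # vanilla: one step on the summed gradient
  v <- vanilla_step(w0, NULL, losses, cfg)$weights
  expect_equal(v, w0 - 0.05 * (grad_at(w0, y1) + grad_at(w0, y2)),
               tolerance = 1e-10)
  # alternate: sequential steps at intermediate weights
  w_mid <- w0 - 0.05 * grad_at(w0, y1)
  expect_equal(alternate_step(w0, NULL, losses, cfg)$weights,
               w_mid - 0.05 * grad_at(w_mid, y2), tolerance = 1e-10)
  # vanilla gradient equals the sum of separately computed per-task gradients
  expect_equal(grad_at(w0, y1) + grad_at(w0, y2),
               losses$a(w0, NULL)$grad + losses$b(w0, NULL)$grad,
               tolerance = 1e-12)
})

test_that("k-fold splits partition ids deterministically", {
  ids <- sprintf("im%03d", 1:800)
  folds <- kfold_splits(ids, 5, seed = 42)
  expect_length(folds, 5)
  for (f in folds) {
    expect_length(f$val, 160)
    expect_length(f$train, 640)
    expect_length(intersect(f$val, f$train), 0)
  }
  vals <- unlist(lapply(folds, `[[`, "val"))
  expect_setequal(vals, ids)
  expect_equal(anyDuplicated(vals), 0L)
  expect_identical(folds, kfold_splits(ids, 5, seed = 42))
  expect_false(identical(folds, kfold_splits(ids, 5, seed = 43)))
  expect_error(kfold_splits(ids[1:3], 5), "exceed")
  expect_error(kfold_splits(c("a", "a", "b"), 2), "unique")
})

# ---------------------------------------------------------------------------
# Compiled network path
# ---------------------------------------------------------------------------

make_tiny_dataset <- function(n = 8, seed = 5) {
  generate_dataset(synth_params(n_images = n, image_size = 32, seed = seed))
}

train_fresh <- function(strategy, epochs = 2, seed = 9, init_seed = 33,
                        optimizer_kind = "adam", n = 8, tasks = NULL) {
  ds <- make_tiny_dataset(n)
  cfg <- tiny_config(tasks = tasks %||% c("od", "oc", "fovea", "glaucoma"))
  set.seed(init_seed)
  m <- build_model(cfg)
  fit <- train(m, ds, train_config(strategy = strategy, epochs = epochs,
                                   batch_size = 4, seed = seed,
                                   optimizer_kind = optimizer_kind,
                                   learning_rate = 1e-3))
  fit
}

test_that("network training is deterministic given the seeds", {
  f1 <- train_fresh("mtl_io")
  f2 <- train_fresh("mtl_io")
  expect_identical(f1$history, f2$history)
  expect_identical(model_parameters(f1$model), model_parameters(f2$model))
})

test_that("on the network, mtl_io with sgd equals plain alternation bitwise", {
  f_alt <- train_fresh("mtl_alternate")
  f_sgd <- train_fresh("mtl_io", optimizer_kind = "sgd")
  expect_identical(model_parameters(f_alt$model),
                   model_parameters(f_sgd$model))
  expect_identical(f_alt$history, f_sgd$history)
})

test_that("with one active task all three step rules coincide bitwise", {
  for (strat in c("mtl_vanilla", "mtl_alternate", "mtl_io")) {
    assign(paste0("p_", strat),
           model_parameters(train_fresh(strat, tasks = "od",
                                        optimizer_kind = "sgd")$model))
  }
  expect_identical(p_mtl_vanilla, p_mtl_alternate)
  expect_identical(p_mtl_alternate, p_mtl_io)
})

test_that("the aggregated backward equals the sum of per-task gradients", {
  set.seed(13)
  cfg <- tiny_config()
  m <- build_model(cfg)
  S <- 32; B <- 2
  x <- array(runif(S * S * 3 * B), c(S, S, 3, B))
  tg <- list(od = array(rbinom(S * S * B, 1, 0.3), c(S, S, B)),
             oc = array(rbinom(S * S * B, 1, 0.2), c(S, S, B)),
             fovea = array(runif(S * S * B), c(S, S, B)),
             glaucoma = c(1, 0))
  lw <- c(od = 1, oc = 1, fovea = 1, glaucoma = 1)
  tasks <- c("od", "oc", "fovea", "glaucoma")

  fundusmtl:::.net_forward(m$ptr, x, tasks)
  fundusmtl:::.net_backward(m$ptr, tasks, tg, lw, 2, FALSE)
  combined <- fundusmtl:::.net_get_grads(m$ptr)

  # accumulate per-task gradients one task at a time
  first <- TRUE
  for (t in tasks) {
    fundusmtl:::.net_forward(m$ptr, x, t)
    fundusmtl:::.net_backward(m$ptr, t, tg[t], lw, 2, !first)
    first <- FALSE
  }
  separate <- fundusmtl:::.net_get_grads(m$ptr)
  for (nm in names(combined))
    expect_equal(combined[[nm]], separate[[nm]], tolerance = 1e-5)
})

test_that("compiled gradients match finite differences of the loss", {
  set.seed(42)
  cfg <- tiny_config()
  m <- build_model(cfg)
  S <- 32; B <- 2
  x <- array(runif(S * S * 3 * B), c(S, S, 3, B))
  tg <- list(od = array(rbinom(S * S * B, 1, 0.3), c(S, S, B)),
             glaucoma = c(1, 0))
  lw <- c(od = 1, oc = 1, fovea = 1, glaucoma = 1)
  loss_for <- function(task) {
    fundusmtl:::.net_forward(m$ptr, x, task)
    as.numeric(fundusmtl:::.net_backward(m$ptr, task, tg[task], lw, 2,
                                         FALSE)[[task]])
  }
  for (task in c("od", "glaucoma")) {
    invisible(loss_for(task))
    g <- fundusmtl:::.net_get_grads(m$ptr)
    p0 <- model_parameters(m)
    sel <- c("conv1_1.weight", "conv4_2.weight", "dec3.weight",
             if (task == "od") "head_od.weight" else "fc2.weight")
    for (nm in sel) {
      ga <- g[[nm]]
      i <- which.max(abs(ga))
      h <- 2e-2
      p <- p0; p[[nm]][i] <- p[[nm]][i] + h
      set_model_parameters(m, p)
      lp <- loss_for(task)
      p <- p0; p[[nm]][i] <- p[[nm]][i] - h
      set_model_parameters(m, p)
      lm <- loss_for(task)
      set_model_parameters(m, p0)
      fd <- (lp - lm) / (2 * h)
      expect_equal(ga[i], fd, tolerance = 0.05)
    }
  }
})

test_that("single-task glaucoma training leaves decoder and heads untouched", {
  ds <- make_tiny_dataset()
  set.seed(3)
  m <- build_model(tiny_config())
  p0 <- model_parameters(m)
  fit <- train(m, ds, train_config(strategy = "stl:glaucoma", epochs = 1,
                                   batch_size = 4, seed = 2))
  p1 <- model_parameters(fit$model)
  for (nm in names(p0)) {
    if (grepl("^(dec|head_)", nm)) {
      expect_identical(p1[[nm]], p0[[nm]])
    } else if (grepl("weight", nm)) {
      expect_false(identical(p1[[nm]], p0[[nm]]))
    }
  }
})

test_that("training losses decrease on learnable data", {
  fit <- train_fresh("mtl_io", epochs = 6, n = 12)
  h <- fit$history
  total_first <- sum(h[1, c("od", "oc", "glaucoma")])
  total_last <- sum(h[nrow(h), c("od", "oc", "glaucoma")])
  expect_lt(total_last, total_first)
  expect_lt(h$fovea[nrow(h)], h$fovea[1])
})

test_that("train validates inputs", {
  ds <- make_tiny_dataset()
  set.seed(1)
  m <- build_model(tiny_config(tasks = "od"))
  expect_error(train(m, ds, train_config(strategy = "stl:glaucoma")),
               "lacks task")
  ds2 <- make_tiny_dataset()
  ds2$od_masks <- NULL
  expect_error(train(m, ds2, train_config(strategy = "stl:od", epochs = 1)),
               "lacks targets")
  expect_error(train_config(strategy = "nonsense"), "unknown strategy")
})
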