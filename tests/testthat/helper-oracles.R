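# Shared fixtures and independent oracles used across the test files.

# A deliberately small configuration: full architecture topology, skinny
# channel widths, so forward/backward passes take milliseconds.
tiny_config <- function(tasks = c("od", "oc", "fovea", "glaucoma"),
                        input_size = 32) {
  model_config(input_size = input_size,
               encoder_widths = list(c(2, 2), c(3, 3), c(4, 4, 4),
                                     c(5, 5, 5), c(5, 5, 5)),
               decoder_widths = c(5, 4, 4, 3),
               classifier_hidden = 4,
               tasks = tasks)
}

# Closed-form parameter count from the layer table alone (conv:
# k^2*cin*cout + cout; fc: nin*nout + nout). Written independently of the
# package's enumeration over allocated arrays.
closed_form_count <- function(config) {
  enc <- config$encoder_widths
  dec <- config$decoder_widths
  tasks <- config$tasks
  total <- 0
  cin <- 3
  for (b in seq_along(enc)) for (cout in enc[[b]]) {
    total <- total + 9 * cin * cout + cout
    cin <- cout
  }
  has_decoder <- any(c("od", "oc", "fovea") %in% tasks)
  if (has_decoder) {
    skip_c <- vapply(enc[4:1], function(w) w[length(w)], 0)
    prev <- enc[[5]][length(enc[[5]])]
    for (s in 1:4) {
      total <- total + 9 * (prev + skip_c[s]) * dec[s] + dec[s]
      prev <- dec[s]
    }
    n_heads <- sum(c("od", "oc", "fovea") %in% tasks)
    total <- total + n_heads * (dec[4] * 1 + 1)
  }
  if ("glaucoma" %in% tasks) {
    h <- config$classifier_hidden
    bott <- enc[[5]][length(enc[[5]])]
    total <- total + (bott * h + h) + (h * 1 + 1)
  }
  total
}

# Exhaustive 8-connected flood fill in plain R (queue-based), independent of
# the compiled labeling.
flood_fill_largest <- function(mask) {
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  visited <- matrix(FALSE, nrow(m), ncol(m))
  best <- NULL
  best_size <- 0L
  for (r0 in seq_len(nrow(m))) for (c0 in seq_len(ncol(m))) {
    if (!m[r0, c0] || visited[r0, c0]) next
    comp <- matrix(FALSE, nrow(m), ncol(m))
    queue <- list(c(r0, c0))
    visited[r0, c0] <- TRUE
    comp[r0, c0] <- TRUE
    size <- 1L
    while (length(queue)) {
      rc <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- rc[1] + dr; cc <- rc[2] + dc
        if (rr < 1 || rr > nrow(m) || cc < 1 || cc > ncol(m)) next
        if (m[rr, cc] && !visited[rr, cc]) {
          visited[rr, cc] <- TRUE
          comp[rr, cc] <- TRUE
          size <- size + 1L
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
    if (size > best_size) { best <- comp; best_size <- size }
  }
  if (is.null(best)) matrix(FALSE, nrow(m), ncol(m)) else best
}

# Brute-force AUC: enumerate every (positive, negative) pair.
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Dense grid-search maximizer of the L2-penalized logistic log-likelihood
# (penalty on the slope only), the oracle for fit_logistic.
grid_logistic <- function(vcdrs, labels, l2_lambda,
                          w_range = c(-60, 60), b_range = c(-40, 40)) {
  obj <- function(w, b) {
    eta <- w * vcdrs + b
    sum(labels * eta - log1p(exp(eta))) - l2_lambda * w^2
  }
  best <- c(NA, NA); best_v <- -Inf
  ws <- seq(w_range[1], w_range[2], length.out = 241)
  bs <- seq(b_range[1], b_range[2], length.out = 241)
  for (refine in 1:3) {
    for (w in ws) for (b in bs) {
      v <- obj(w, b)
      if (v > best_v) { best_v <- v; best <- c(w, b) }
    }
    dw <- diff(ws[1:2]); db <- diff(bs[1:2])
    ws <- seq(best[1] - 2 * dw, best[1] + 2 * dw, length.out = 41)
    bs <- seq(best[2] - 2 * db, best[2] + 2 * db, length.out = 41)
  }
  list(weight = best[1], bias = best[2])
}

# ---------------------------------------------------------------------------
# Pure-R double-precision reference forward pass (single image), written from
# the architecture description and independent of the compiled code paths.
# ---------------------------------------------------------------------------

ref_conv3 <- function(x, W, b, relu = TRUE) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  cout <- nrow(W)
  out <- array(rep(b, each = h * w), c(h, w, cout))
  for (o in 0:8) {
    dy <- o %/% 3 - 1; dx <- o %% 3 - 1
    rs <- (1:h) + dy; cs <- (1:w) + dx
    rok <- rs >= 1 & rs <= h; cok <- cs >= 1 & cs <= w
    for (ci in seq_len(cin)) {
      shifted <- matrix(0, h, w)
      shifted[rok, cok] <- x[rs[rok], cs[cok], ci]
      for (co in seq_len(cout))
        out[, , co] <- out[, , co] + W[co, o * cin + ci] * shifted
    }
  }
  if (relu) out[out < 0] <- 0
  out
}

ref_pool2 <- function(x) {
  h <- dim(x)[1] %/% 2; w <- dim(x)[2] %/% 2
  out <- array(0, c(h, w, dim(x)[3]))
  for (r in 1:h) for (c in 1:w)
    out[r, c, ] <- apply(x[(2 * r - 1):(2 * r), (2 * c - 1):(2 * c), ,
                           drop = FALSE], 3, max)
  out
}

ref_up2 <- function(x) {
  n_in_y <- dim(x)[1]; n_in_x <- dim(x)[2]
  taps <- function(n_out, n_in) {
    f <- 0.5 * (0:(n_out - 1)) - 0.25
    i0 <- floor(f); w1 <- f - i0
    w1[i0 < 0] <- 0; i0[i0 < 0] <- 0
    i1 <- pmin(i0 + 1, n_in - 1)
    list(i0 = i0 + 1, i1 = i1 + 1, w1 = w1)
  }
  ty <- taps(2 * n_in_y, n_in_y); tx <- taps(2 * n_in_x, n_in_x)
  out <- array(0, c(2 * n_in_y, 2 * n_in_x, dim(x)[3]))
  for (r in seq_len(2 * n_in_y)) for (c in seq_len(2 * n_in_x)) {
    out[r, c, ] <-
      (1 - ty$w1[r]) * ((1 - tx$w1[c]) * x[ty$i0[r], tx$i0[c], ] +
                          tx$w1[c] * x[ty$i0[r], tx$i1[c], ]) +
      ty$w1[r] * ((1 - tx$w1[c]) * x[ty$i1[r], tx$i0[c], ] +
                    tx$w1[c] * x[ty$i1[r], tx$i1[c], ])
  }
  out
}

# Full reference forward for one (S,S,3) image given the flat parameter list.
ref_forward <- function(params, config, img) {
  enc <- config$encoder_widths
  act <- img
  skips <- list()
  for (b in 1:5) {
    for (i in seq_along(enc[[b]])) {
      nm <- sprintf("conv%d_%d", b, i)
      act <- ref_conv3(act, params[[paste0(nm, ".weight")]],
                       params[[paste0(nm, ".bias")]])
    }
    if (b < 5) {
      skips[[b]] <- act
      act <- ref_pool2(act)
    }
  }
  bottleneck <- act
  d <- bottleneck
  for (s in 1:4) {
    up <- ref_up2(d)
    cat3 <- array(c(up, skips[[5 - s]]),
                  c(dim(up)[1], dim(up)[2], dim(up)[3] + dim(skips[[5 - s]])[3]))
    nm <- paste0("dec", s)
    d <- ref_conv3(cat3, params[[paste0(nm, ".weight")]],
                   params[[paste0(nm, ".bias")]])
  }
  heads <- list()
  for (t in intersect(config$tasks, c("od", "oc", "fovea"))) {
    W <- params[[paste0("head_", t, ".weight")]]
    bb <- params[[paste0("head_", t, ".bias")]]
    z <- matrix(bb, dim(d)[1], dim(d)[2])
    for (ci in seq_len(dim(d)[3])) z <- z + W[1, ci] * d[, , ci]
    heads[[t]] <- if (t == "fovea") z else 1 / (1 + exp(-z))
  }
  if ("glaucoma" %in% config$tasks) {
    gap <- apply(bottleneck, 3, mean)
    h1 <- pmax(params[["fc1.weight"]] %*% gap + params[["fc1.bias"]], 0)
    z2 <- params[["fc2.weight"]] %*% h1 + params[["fc2.bias"]]
    heads$glaucoma <- 1 / (1 + exp(-as.numeric(z2)))
  }
  heads
}
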