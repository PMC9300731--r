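# Seeded generator of fundus-like images with exact ground truth. Each image
# carries a bright elliptical optic disc containing a brighter optic cup
# whose vertical extent realizes a drawn vCDR, a dark fovea spot 2-3 disc
# diameters away (clamped to the frame), smooth background texture and
# additive Gaussian noise. The glaucoma label is the indicator
# vCDR > threshold, and the vCDR draws are stratified so that positives make
# up ~10% of the dataset, mirroring the class imbalance of screening data.

#' Parameters of the synthetic fundus generator
#'
#' @param n_images Number of images.
#' @param image_size Side length in pixels (default 64; must be >= 32 and
#'   divisible by 16 to feed the network directly).
#' @param od_radius_range Optic-disc base radius as a fraction of the image
#'   side; vertical/horizontal semi-axes are then varied independently by up
#'   to +/-20%.
#' @param vcdr_range Range of the vertical cup-to-disc ratio draws.
#' @param fovea_offset_diameters Fovea distance from the disc center in
#'   optic-disc diameters (direction left or right; the offset is clamped so
#'   the fovea stays inside the frame).
#' @param noise_sd Additive Gaussian intensity noise.
#' @param label_rule_threshold Glaucoma label is `vcdr > threshold`.
#' @param label_noise Probability of flipping a label.
#' @param positive_prevalence Target fraction of positive labels; enforced by
#'   stratified resampling of the vCDR draws.
#' @param seed RNG seed; the full dataset is a deterministic function of it.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(n_images = 100L, image_size = 64L,
                         od_radius_range = c(0.12, 0.20),
                         vcdr_range = c(0.3, 0.9),
                         fovea_offset_diameters = c(2, 3),
                         noise_sd = 0.05, label_rule_threshold = 0.6,
                         label_noise = 0, positive_prevalence = 0.10,
                         seed = 1L) {
  if (max(od_radius_range) * 1.2 >= 0.5)
    stop("od_radius_range too large: disc would not fit in the frame")
  if (min(od_radius_range) <= 0) stop("od_radius_range must be positive")
  if (image_size < 32 || image_size %% 16 != 0)
    stop("image_size must be >= 32 and divisible by 16")
  if (vcdr_range[1] <= 0 || vcdr_range[2] >= 1 ||
      vcdr_range[1] >= vcdr_range[2])
    stop("vcdr_range must satisfy 0 < lo < hi < 1")
  th <- label_rule_threshold
  if (th <= vcdr_range[1] || th >= vcdr_range[2])
    stop("label_rule_threshold must lie inside vcdr_range")
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 od_radius_range = od_radius_range,
                 vcdr_range = vcdr_range,
                 fovea_offset_diameters = fovea_offset_diameters,
                 noise_sd = noise_sd, label_rule_threshold = th,
                 label_noise = label_noise,
                 positive_prevalence = positive_prevalence,
                 seed = as.integer(seed)),
            class = "synth_params")
}

# Rasterize an ellipse by the pixel-center inequality (no anti-aliasing).
# Centers are fractional; 0-based coordinates.
ellipse_mask <- function(S, cy, cx, ry, rx) {
  r <- seq_len(S) - 1
  cc <- seq_len(S) - 1
  outer(((r - cy) / ry)^2, ((cc - cx) / rx)^2, `+`) <= 1
}

# Smooth low-frequency background texture in [-1, 1].
smooth_texture <- function(S) {
  f <- matrix(rnorm(64), 8, 8)
  up <- .resize_bilinear(f, S, S)
  up / max(abs(up))
}

#' Generate a synthetic fundus dataset
#'
#' Deterministic given the seed. Disc and cup vertical pixel extents are
#' constructed exactly (half-integer vertical centers), so the mask-derived
#' vCDR matches the drawn vCDR up to less than one pixel row of
#' rasterization.
#'
#' @param params A [synth_params()].
#' @return A `fundus_dataset`: list with `images` `(S,S,3,n)` in `[0,1]`,
#'   `od_masks`/`oc_masks` `(S,S,n)` logical, `fovea` `(n,2)` matrix of
#'   0-based `(x, y)` coordinates, `labels` integer vector, `vcdr_true`
#'   numeric vector, `ids`, `n`, and the `params`.
#' @export
generate_dataset <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  n <- params$n_images
  S <- params$image_size
  th <- params$label_rule_threshold
  with_seed(params$seed, {
    images <- array(0, c(S, S, 3, n))
    od_masks <- array(FALSE, c(S, S, n))
    oc_masks <- array(FALSE, c(S, S, n))
    fovea <- matrix(0, n, 2, dimnames = list(NULL, c("x", "y")))
    labels <- integer(n)
    vcdr_true <- numeric(n)

    # stratified prevalence: fix the number of positives, then draw vCDR
    # uniformly within the matching side of the threshold
    n_pos <- round(params$positive_prevalence * n)
    pos <- rep(FALSE, n)
    if (n_pos > 0) pos[sample(n, n_pos)] <- TRUE

    for (i in seq_len(n)) {
      vcdr <- if (pos[i]) runif(1, th, params$vcdr_range[2]) else
        runif(1, params$vcdr_range[1], th)
      base_r <- runif(1, params$od_radius_range[1],
                      params$od_radius_range[2]) * S
      ry_od <- base_r * runif(1, 0.8, 1.2)
      rx_od <- base_r * runif(1, 0.8, 1.2)

      # exact integer vertical extents: an integer row center realizes odd
      # pixel heights, a half-integer center even heights, with the
      # semi-axis just under h/2 in either case; the cup center may sit
      # half a pixel off the disc center when the two parities differ
      h_od <- max(5L, round(2 * ry_od))
      h_oc <- max(2L, round(vcdr * h_od))
      margin <- 2
      dir <- sample(c(-1, 1), 1)  # fovea to the right (+1) or left (-1)
      cx_od <- if (dir > 0) margin + ceiling(rx_od) else
        S - 1 - margin - ceiling(rx_od)
      base_row <- floor(runif(1, S * 0.3, S * 0.7))
      cy_for <- function(h) if (h %% 2 == 1) base_row else base_row + 0.5
      rx_oc <- max(1, vcdr * rx_od)

      odm <- ellipse_mask(S, cy_for(h_od), cx_od, h_od / 2 - 0.02, rx_od)
      ocm <- ellipse_mask(S, cy_for(h_oc), cx_od, h_oc / 2 - 0.02, rx_oc)

      # fovea: 2-3 disc diameters away horizontally, clamped into frame
      offset <- runif(1, params$fovea_offset_diameters[1],
                      params$fovea_offset_diameters[2]) * 2 * rx_od
      fx <- cx_od + dir * offset
      fx <- min(max(fx, 3), S - 4)
      fy <- base_row + runif(1, -0.05, 0.05) * S
      fy <- min(max(fy, 3), S - 4)

      tex <- smooth_texture(S)
      intens <- 0.35 + 0.06 * tex
      intens[odm] <- 0.75
      intens[ocm] <- 0.90
      rr <- seq_len(S) - 1
      spot <- 0.30 * exp(-(outer((rr - fy)^2, (rr - fx)^2, `+`)) /
                           (2 * 2.5^2))
      intens <- intens - spot
      img <- array(0, c(S, S, 3))
      img[, , 1] <- intens * 1.15
      img[, , 2] <- intens
      img[, , 3] <- intens * 0.55
      img <- img + array(rnorm(S * S * 3, 0, params$noise_sd), c(S, S, 3))
      images[, , , i] <- pmin(pmax(img, 0), 1)

      od_masks[, , i] <- odm
      oc_masks[, , i] <- ocm
      fovea[i, ] <- c(fx, fy)
      vcdr_true[i] <- vcdr
      lab <- as.integer(vcdr > th)
      if (params$label_noise > 0 && runif(1) < params$label_noise)
        lab <- 1L - lab
      labels[i] <- lab
    }
    structure(list(images = images, od_masks = od_masks, oc_masks = oc_masks,
                   fovea = fovea, labels = labels, vcdr_true = vcdr_true,
                   ids = sprintf("synth_%04d", seq_len(n)), n = n,
                   params = params),
              class = "fundus_dataset")
  })
}

#' Self-consistency checks of a generated dataset
#'
#' Recomputes the vCDR from the generated masks via [compute_vcdr()] and
#' compares it with the recorded draw (tolerance 0.05), checks that the cup
#' lies inside the disc, and that the recorded fovea coordinate sits at the
#' local intensity minimum of the rendered dark spot (within 1 px on each
#' axis, after 3x3 smoothing to suppress pixel noise).
#'
#' @param dataset A `fundus_dataset` carrying ground truth.
#' @param vcdr_tol Allowed |mask vCDR - drawn vCDR|.
#' @return `list(n_violations=, violations=)`, the latter a data.frame
#'   listing every failed check per image.
#' @export
verify_ground_truth <- function(dataset, vcdr_tol = 0.05) {
  viol <- data.frame(image = integer(0), check = character(0),
                     detail = character(0))
  flag <- function(i, check, detail)
    viol <<- rbind(viol, data.frame(image = i, check = check,
                                    detail = detail))
  S <- dim(dataset$images)[1]
  for (i in seq_len(dataset$n)) {
    odm <- dataset$od_masks[, , i]
    ocm <- dataset$oc_masks[, , i]
    rec <- compute_vcdr(odm, ocm)
    dv <- abs(rec$vcdr - dataset$vcdr_true[i])
    if (is.na(rec$vcdr) || dv > vcdr_tol)
      flag(i, "vcdr", sprintf("mask %.3f vs drawn %.3f",
                              rec$vcdr, dataset$vcdr_true[i]))
    if (any(ocm & !odm)) flag(i, "oc_inside_od", "cup pixels outside disc")
    # fovea: darkest smoothed pixel near the recorded coordinate
    fx <- dataset$fovea[i, 1]; fy <- dataset$fovea[i, 2]
    lum <- (dataset$images[, , 1, i] + dataset$images[, , 2, i] +
              dataset$images[, , 3, i]) / 3
    sm <- .resize_bilinear(.resize_bilinear(lum, S %/% 2, S %/% 2), S, S)
    rr <- max(1, round(fy) + 1 - 4):min(S, round(fy) + 1 + 4)
    cc <- max(1, round(fx) + 1 - 4):min(S, round(fx) + 1 + 4)
    win <- sm[rr, cc]
    am <- which(win == min(win), arr.ind = TRUE)[1, ]
    hit_y <- rr[am[1]] - 1
    hit_x <- cc[am[2]] - 1
    if (max(abs(hit_y - fy), abs(hit_x - fx)) > 1.5)
      flag(i, "fovea_minimum",
           sprintf("min at (%d,%d), recorded (%.1f,%.1f)",
                   hit_x, hit_y, fx, fy))
  }
  list(n_violations = nrow(viol), violations = viol)
}
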