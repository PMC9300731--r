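# Task losses. All are deterministic pure functions; probabilities are
# clamped to [eps, 1 - eps] before any logarithm.
PROB_EPS <- 1e-7

#' Pixel-averaged binary cross-entropy
#'
#' `-(1/N) * sum(y * log(p) + (1 - y) * log(1 - p))` over all pixels, the
#' segmentation loss for the optic-disc and optic-cup maps.
#'
#' @param pred Numeric array of probabilities in `[0, 1]`.
#' @param target Numeric array of the same shape with values in `{0, 1}`.
#' @return Non-negative scalar loss in nats.
#' @export
bce_loss <- function(pred, target) {
  if (length(pred) != length(target) ||
      !identical(dim(pred), dim(target)))
    stop("pred and target must have the same shape")
  if (any(pred < 0 | pred > 1)) stop("pred values must lie in [0, 1]")
  if (!all(target %in% c(0, 1))) stop("target must be binary (0/1)")
  p <- pmin(pmax(as.numeric(pred), PROB_EPS), 1 - PROB_EPS)
  y <- as.numeric(target)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Summed L1 loss
#'
#' The fovea saliency-map regression loss: the SUM (not the mean) of absolute
#' deviations, `sum(|y_i - p_i|)`.
#'
#' @param pred,target Numeric arrays of the same shape.
#' @return Non-negative scalar.
#' @export
l1_loss <- function(pred, target) {
  if (length(pred) != length(target) ||
      !identical(dim(pred), dim(target)))
    stop("pred and target must have the same shape")
  sum(abs(as.numeric(pred) - as.numeric(target)))
}

#' Focal loss for imbalanced binary classification
#'
#' `-(1 - p_t)^gamma * log(p_t)` with `p_t = p` for positive labels and
#' `1 - p` otherwise. The modulating factor `(1 - p_t)^gamma` down-weights
#' confidently classified examples so that the rare positive class (about 10%
#' prevalence in glaucoma screening data) is not drowned out. With
#' `gamma = 0` the loss reduces to binary cross-entropy. The loss is
#' implemented with the standard negative sign, so it is non-negative and
#' decreases as the classifier grows confident in the correct class.
#'
#' @param prob Predicted probability (or vector of probabilities) in `[0, 1]`.
#' @param label Label(s) in `{0, 1}`, recycled against `prob`.
#' @param gamma Focusing exponent, `>= 0`; default 2.
#' @return Loss value(s) in nats, same length as `prob`.
#' @export
focal_loss <- function(prob, label, gamma = 2) {
  if (length(gamma) != 1 || is.na(gamma) || gamma < 0)
    stop("gamma must be a single value >= 0")
  if (any(prob < 0 | prob > 1)) stop("prob must lie in [0, 1]")
  if (!all(label %in% c(0, 1))) stop("label must be binary (0/1)")
  p_t <- ifelse(label == 1, prob, 1 - prob)
  p_t <- pmin(pmax(p_t, PROB_EPS), 1 - PROB_EPS)
  -(1 - p_t)^gamma * log(p_t)
}

#' Specification of a Gaussian fovea target map
#'
#' The fovea position is taught to the network as a saliency map: an
#' isotropic Gaussian (equal variances, zero covariance) centered on the
#' fovea coordinate, normalized so its maximum over the pixel grid is 1.
#'
#' @param center_x,center_y Fovea coordinate, 0-based pixels, `x` = column,
#'   `y` = row; fractional values allowed.
#' @param sigma Spread in pixels, `> 0`. The package default used during
#'   training is 8 px at an input size of 512 (i.e. 1 px at 64), scaling
#'   linearly with resolution.
#' @param height,width Map size in pixels.
#' @return An object of class `saliency_spec`.
#' @export
saliency_spec <- function(center_x, center_y, sigma, height, width) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (center_x < 0 || center_x > width - 1 ||
      center_y < 0 || center_y > height - 1)
    stop("center must lie within the map bounds")
  structure(list(center_x = center_x, center_y = center_y, sigma = sigma,
                 height = height, width = width),
            class = "saliency_spec")
}

#' Render the Gaussian fovea target map
#'
#' @param spec A [saliency_spec()].
#' @return A `height x width` matrix with values in `(0, 1]` and maximum
#'   exactly 1 (attained at the grid point nearest the center).
#' @export
make_fovea_map <- function(spec) {
  if (!inherits(spec, "saliency_spec")) stop("spec must be a saliency_spec")
  r <- seq_len(spec$height) - 1
  c <- seq_len(spec$width) - 1
  dy2 <- (r - spec$center_y)^2
  dx2 <- (c - spec$center_x)^2
  m <- exp(-(outer(dy2, dx2, `+`)) / (2 * spec$sigma^2))
  m / max(m)
}
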