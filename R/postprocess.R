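# Post-processing of raw network outputs and the evaluation metrics.
# Probability maps are thresholded at 0.5 (the sigmoid midpoint), reduced to
# their main connected component, and turned into vertical cup-to-disc
# ratios; saliency maps are reduced to a center of mass with no further
# refinement (any smoothing would shift the center of mass).

#' Keep the largest connected component of a binary mask
#'
#' Uses 8-connectivity. Removes spurious prediction specks around the single
#' elliptic structure expected in disc/cup maps.
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @return `list(mask = , empty = )`: the retained component (a subset of the
#'   input) and a flag raised when the input had no foreground at all.
#' @export
largest_connected_component <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (!any(m)) {
    warning("empty mask: no connected component to keep")
    return(list(mask = m, empty = TRUE))
  }
  lab <- .label_components(m)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  list(mask = lab == keep, empty = FALSE)
}

#' Intensity-weighted center of mass
#'
#' Negative values are clipped to zero first; no rounding is applied.
#'
#' @param map Numeric matrix with at least one strictly positive value.
#' @return `c(x = , y = )` in 0-based pixel coordinates (x = column,
#'   y = row), fractional.
#' @export
center_of_mass <- function(map) {
  if (!is.matrix(map)) stop("map must be a matrix")
  m <- pmax(map, 0)
  tot <- sum(m)
  if (tot <= 0) stop("all-zero map: no localizable mass")
  rows <- row(m) - 1
  cols <- col(m) - 1
  c(x = sum(cols * m) / tot, y = sum(rows * m) / tot)
}

#' Vertical cup-to-disc ratio from segmentation masks
#'
#' The vertical extent of a mask is `max occupied row - min occupied row + 1`
#' pixels; `vCDR = OC_height / OD_height`. An enlarged vCDR (cupping) is the
#' key fundus sign of glaucoma.
#'
#' @param od_mask,oc_mask Binary matrices, already post-processed (largest
#'   component).
#' @return `list(oc_height=, od_height=, vcdr=)`; an empty cup gives
#'   `vcdr = 0`, an empty disc gives `vcdr = NA` (undefined) with heights
#'   still reported.
#' @export
compute_vcdr <- function(od_mask, oc_mask) {
  vext <- function(m) {
    rs <- which(apply(m != 0, 1, any))
    if (length(rs) == 0) 0L else max(rs) - min(rs) + 1L
  }
  odh <- vext(od_mask)
  och <- vext(oc_mask)
  vcdr <- if (odh == 0) NA_real_ else och / odh
  structure(list(oc_height = och, od_height = odh, vcdr = vcdr),
            class = "vcdr_record")
}

#' Fit the vCDR logistic classifier
#'
#' A two-parameter logistic regression of the glaucoma label on the vertical
#' cup-to-disc ratio, `P(glaucoma) = sigmoid(weight * vcdr + bias)`. The fit
#' maximizes the log-likelihood minus an L2 penalty `lambda * weight^2` (the
#' bias is not penalized) by Newton iterations until the gradient norm drops
#' below 1e-8 (at most 100 iterations); the ridge term guarantees a finite
#' optimum even when the vCDRs separate the classes perfectly.
#'
#' @param vcdrs Numeric vector of cup-to-disc ratios.
#' @param labels Binary labels, both classes present.
#' @param l2_lambda Ridge strength on the slope, `> 0`.
#' @return An object of class `logistic_classifier` with fields `weight`,
#'   `bias`, `l2_lambda`.
#' @export
fit_logistic <- function(vcdrs, labels, l2_lambda = 1e-3) {
  if (length(vcdrs) != length(labels) || length(vcdrs) < 2)
    stop("need >= 2 paired observations")
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2)
    stop("labels must contain both classes")
  if (l2_lambda <= 0) stop("l2_lambda must be > 0")
  x <- as.numeric(vcdrs); y <- as.numeric(labels)
  theta <- c(weight = 0, bias = 0)
  for (it in seq_len(100)) {
    eta <- theta[1] * x + theta[2]
    p <- plogis(eta)
    grad <- c(sum((y - p) * x) - 2 * l2_lambda * theta[1], sum(y - p))
    if (sqrt(sum(grad^2)) < 1e-8) break
    wv <- p * (1 - p)
    H <- -matrix(c(sum(wv * x^2) + 2 * l2_lambda, sum(wv * x),
                   sum(wv * x), sum(wv)), 2, 2)
    theta <- theta - solve(H, grad)
  }
  if (!all(is.finite(theta))) stop("logistic fit diverged")
  structure(list(weight = unname(theta[1]), bias = unname(theta[2]),
                 l2_lambda = l2_lambda),
            class = "logistic_classifier")
}

#' @rdname fit_logistic
#' @param object A `logistic_classifier`.
#' @param newdata Numeric vector of vCDRs to score.
#' @param ... Unused.
#' @export
predict.logistic_classifier <- function(object, newdata, ...) {
  plogis(object$weight * as.numeric(newdata) + object$bias)
}

#' Ensemble the two glaucoma scores
#'
#' Averages the post-sigmoid probabilities of the network's fully-connected
#' classifier and of the vCDR logistic classifier; the binary call applies a
#' 0.5 threshold to the average, with the tie going positive (screening
#' favors sensitivity).
#'
#' @param fc_prob,lin_prob Probabilities in `[0, 1]` (vectorized).
#' @return `list(probability=, label=)`.
#' @export
ensemble_classify <- function(fc_prob, lin_prob) {
  if (any(fc_prob < 0 | fc_prob > 1) || any(lin_prob < 0 | lin_prob > 1))
    stop("probabilities must lie in [0, 1]")
  p <- (fc_prob + lin_prob) / 2
  list(probability = p, label = as.integer(p >= 0.5))
}

#' Dice overlap of two binary masks
#'
#' `2 |A n B| / (|A| + |B|)`; two empty masks agree perfectly (1.0).
#'
#' @param a,b Binary matrices of the same shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must have the same shape")
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pair statistic: the fraction of
#' (positive, negative) pairs in which the positive scores higher, ties
#' counting one half. The ROC polyline itself is also returned.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary labels with both classes present.
#' @return `list(auc=, roc=)`; `roc` is a data.frame of
#'   `(fpr, tpr, threshold)` points.
#' @export
auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2)
    stop("labels must contain both classes")
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  r <- rank(c(pos, neg), ties.method = "average")
  a <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  th <- sort(unique(scores), decreasing = TRUE)
  roc <- data.frame(
    fpr = c(0, vapply(th, function(t) mean(neg >= t), 0), 1),
    tpr = c(0, vapply(th, function(t) mean(pos >= t), 0), 1),
    threshold = c(Inf, th, -Inf))
  list(auc = a, roc = roc)
}

#' Euclidean fovea localization error
#'
#' @param pred,truth Length-2 coordinates `(x, y)` in a common frame.
#' @param scale Unit-conversion factor applied to the distance (default 1:
#'   raw pixels).
#' @return Non-negative scalar.
#' @export
fovea_error <- function(pred, truth, scale = 1) {
  scale * sqrt(sum((as.numeric(pred)[1:2] - as.numeric(truth)[1:2])^2))
}

#' Evaluate a trained model on a dataset
#'
#' Per image: probability maps are thresholded at 0.5 and reduced to their
#' main connected component for Dice scores and the vCDR; the fovea estimate
#' is the center of mass of the predicted saliency map; the glaucoma score is
#' the average of the network probability and of the vCDR logistic
#' classifier's probability, pooled into one AUC across the dataset.
#' Per-image failures (e.g. empty masks) are recorded in the report instead
#' of aborting it.
#'
#' @param model A trained `mtl_model`.
#' @param dataset A `fundus_dataset` with ground-truth targets.
#' @param classifier Optional `logistic_classifier`; defaults to the one
#'   fitted by [train()] and stored on the model. Without one, the ensemble
#'   falls back to the network probability alone.
#' @param batch_size Forward-pass batch size.
#' @return An object of class `metrics_report`:
#'   `list(aggregate=, per_image=, roc=)`, where `aggregate` holds
#'   mean and sd of each metric plus the pooled AUC.
#' @export
evaluate <- function(model, dataset, classifier = model$classifier,
                     batch_size = 8L) {
  n <- dataset$n
  tasks <- model$config$tasks
  S <- model$config$input_size
  per <- data.frame(image_id = dataset$ids %||% seq_len(n))
  per$dice_od <- per$dice_oc <- per$vcdr <- NA_real_
  per$fovea_x <- per$fovea_y <- per$fovea_error <- NA_real_
  per$prob_fc <- per$prob_lin <- per$prob_avg <- NA_real_
  per$label_pred <- NA_integer_
  per$note <- ""

  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, n)
    fw <- forward(model, dataset$images[, , , idx, drop = FALSE], tasks)
    for (j in seq_along(idx)) {
      i <- idx[j]
      odm <- ocm <- NULL
      if ("od" %in% tasks) {
        cc <- suppressWarnings(
          largest_connected_component(fw$od[, , j] >= 0.5))
        odm <- cc$mask
        if (cc$empty) per$note[i] <- paste0(per$note[i], "empty_od;")
        if (!is.null(dataset$od_masks))
          per$dice_od[i] <- dice(odm, dataset$od_masks[, , i])
      }
      if ("oc" %in% tasks) {
        cc <- suppressWarnings(
          largest_connected_component(fw$oc[, , j] >= 0.5))
        ocm <- cc$mask
        if (cc$empty) per$note[i] <- paste0(per$note[i], "empty_oc;")
        if (!is.null(dataset$oc_masks))
          per$dice_oc[i] <- dice(ocm, dataset$oc_masks[, , i])
      }
      if (!is.null(odm) && !is.null(ocm)) {
        rec <- compute_vcdr(odm, ocm)
        per$vcdr[i] <- if (is.na(rec$vcdr)) 0 else rec$vcdr
      }
      if ("fovea" %in% tasks) {
        cm <- tryCatch(center_of_mass(fw$fovea[, , j]), error = function(e) {
          per$note[i] <<- paste0(per$note[i], "empty_saliency;")
          NULL
        })
        if (!is.null(cm)) {
          per$fovea_x[i] <- cm["x"]; per$fovea_y[i] <- cm["y"]
          if (!is.null(dataset$fovea))
            per$fovea_error[i] <- fovea_error(cm, dataset$fovea[i, ])
        }
      }
      if ("glaucoma" %in% tasks) per$prob_fc[i] <- fw$glaucoma[j]
    }
  }

  if ("glaucoma" %in% tasks) {
    if (!is.null(classifier) && any(!is.na(per$vcdr))) {
      per$prob_lin <- predict(classifier, per$vcdr)
      en <- ensemble_classify(per$prob_fc, per$prob_lin)
    } else {
      en <- list(probability = per$prob_fc,
                 label = as.integer(per$prob_fc >= 0.5))
    }
    per$prob_avg <- en$probability
    per$label_pred <- en$label
  }

  agg <- list()
  for (m in c("dice_od", "dice_oc", "fovea_error")) {
    v <- per[[m]]
    if (any(!is.na(v)))
      agg[[m]] <- c(mean = mean(v, na.rm = TRUE), sd = sd(v, na.rm = TRUE))
  }
  roc <- NULL
  if ("glaucoma" %in% tasks && !is.null(dataset$labels) &&
      length(unique(dataset$labels)) == 2) {
    au <- auc(per$prob_avg, dataset$labels)
    agg$auc <- au$auc
    roc <- au$roc
  }
  structure(list(aggregate = agg, per_image = per, roc = roc),
            class = "metrics_report")
}

#' Write a metrics report to disk
#'
#' Predictions go to CSV (one row per image), aggregate metrics and ROC
#' points to JSON.
#'
#' @param report A `metrics_report`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    write.csv(report$per_image, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(aggregate = report$aggregate, roc = report$roc),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}
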