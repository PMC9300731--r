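# On-disk dataset layout (shared by the synthetic generator and REFUGE-style
# data):
#   root/images/<id>.png     RGB fundus image
#   root/masks/<id>.png      8-bit grayscale tri-level mask (optional)
#   root/fovea.csv           image_id, fovea_x, fovea_y   (0-based, original
#                            pixel coordinates, x = column) (optional)
#   root/labels.csv          image_id, glaucoma (0/1)     (optional)

#' Tri-level mask encoding
#'
#' Maps 8-bit gray values to (inside-disc, inside-cup): by default dark
#' pixels (<= 64) are cup (hence also disc), mid grays (65-192) disc only,
#' bright pixels background. Thresholds rather than exact values tolerate
#' resampling; `strict = TRUE` errors on values other than `exact_values`.
#'
#' @param oc_max,od_max Upper gray bounds (0-255) for cup and disc.
#' @param strict Error on unexpected gray values.
#' @param exact_values Permitted values in strict mode.
#' @return An object of class `mask_encoding`.
#' @export
mask_encoding <- function(oc_max = 64, od_max = 192, strict = FALSE,
                          exact_values = c(0, 128, 255)) {
  if (!(oc_max < od_max && od_max < 255))
    stop("need oc_max < od_max < 255")
  structure(list(oc_max = oc_max, od_max = od_max, strict = strict,
                 exact_values = exact_values),
            class = "mask_encoding")
}

decode_mask <- function(gray255, enc) {
  if (enc$strict && !all(round(gray255) %in% enc$exact_values))
    stop("unexpected gray values in mask: ",
         paste(head(setdiff(sort(unique(round(gray255))), enc$exact_values)),
               collapse = ", "))
  list(od = gray255 <= enc$od_max, oc = gray255 <= enc$oc_max)
}

encode_mask <- function(od, oc) {
  g <- matrix(255, nrow(od), ncol(od))
  g[od] <- 128
  g[oc & od] <- 0
  g
}

#' Write a dataset to the on-disk layout
#'
#' @param dataset A `fundus_dataset`.
#' @param root Output directory (created if needed).
#' @return `root`, invisibly.
#' @export
write_fundus_dataset <- function(dataset, root) {
  dir.create(file.path(root, "images"), recursive = TRUE,
             showWarnings = FALSE)
  has_masks <- !is.null(dataset$od_masks)
  if (has_masks)
    dir.create(file.path(root, "masks"), showWarnings = FALSE)
  ids <- dataset$ids %||% sprintf("img_%04d", seq_len(dataset$n))
  for (i in seq_len(dataset$n)) {
    png::writePNG(dataset$images[, , , i],
                  file.path(root, "images", paste0(ids[i], ".png")))
    if (has_masks)
      png::writePNG(encode_mask(dataset$od_masks[, , i],
                                dataset$oc_masks[, , i]) / 255,
                    file.path(root, "masks", paste0(ids[i], ".png")))
  }
  if (!is.null(dataset$fovea))
    write.csv(data.frame(image_id = ids, fovea_x = dataset$fovea[, 1],
                         fovea_y = dataset$fovea[, 2]),
              file.path(root, "fovea.csv"), row.names = FALSE)
  if (!is.null(dataset$labels))
    write.csv(data.frame(image_id = ids, glaucoma = dataset$labels),
              file.path(root, "labels.csv"), row.names = FALSE)
  invisible(root)
}

#' Load a dataset from the on-disk layout
#'
#' Images are decoded to RGB in `[0, 1]` and bilinearly resized to
#' `input_size`; masks are resized with nearest-neighbor sampling; fovea
#' coordinates are rescaled by the same factors (kept 0-based, x = column).
#' Items missing a mask, coordinate or label are flagged per task rather
#' than rejected.
#'
#' An optional `splits.csv` (`image_id,split` with values train/val/test)
#' attaches a split tag per item.
#'
#' @param root Dataset directory.
#' @param input_size Target square size (divisible by 16).
#' @param encoding A [mask_encoding()].
#' @return A `fundus_dataset` (with `od_masks`/`oc_masks`/`fovea`/`labels`
#'   set to `NULL` when absent for every item, and a logical `has` matrix
#'   flagging per-item target availability).
#' @export
load_fundus_dataset <- function(root, input_size = 64L,
                                encoding = mask_encoding()) {
  img_dir <- file.path(root, "images")
  if (!dir.exists(img_dir)) stop("no images/ directory under ", root)
  files <- sort(list.files(img_dir, pattern = "\\.(png|jpg|jpeg)$",
                           ignore.case = TRUE))
  if (length(files) == 0) stop("no images found under ", img_dir)
  ids <- sub("\\.[^.]+$", "", files)
  if (anyDuplicated(ids)) stop("duplicate image ids")
  n <- length(ids)
  S <- as.integer(input_size)

  fovea_tab <- labels_tab <- split_tab <- NULL
  fp <- file.path(root, "fovea.csv")
  if (file.exists(fp)) fovea_tab <- read.csv(fp)
  lp <- file.path(root, "labels.csv")
  if (file.exists(lp)) labels_tab <- read.csv(lp)
  sp <- file.path(root, "splits.csv")
  if (file.exists(sp)) split_tab <- read.csv(sp)

  images <- array(0, c(S, S, 3, n))
  od_masks <- oc_masks <- NULL
  fovea <- NULL
  labels <- NULL
  has <- matrix(FALSE, n, 4, dimnames = list(NULL, c("od", "oc", "fovea",
                                                     "glaucoma")))
  errors <- character(0)

  read_img <- function(path) {
    if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
    else stop("unsupported image format: ", path)
  }

  for (i in seq_len(n)) {
    img <- tryCatch(read_img(file.path(img_dir, files[i])),
                    error = function(e) conditionMessage(e))
    if (is.character(img)) {
      errors <- c(errors, paste0(ids[i], ": ", img)); next
    }
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    if (dim(img)[3] > 3) img <- img[, , 1:3]
    orig_h <- dim(img)[1]; orig_w <- dim(img)[2]
    images[, , , i] <- .resize_bilinear(img, S, S)

    mp <- file.path(root, "masks", paste0(ids[i], ".png"))
    if (file.exists(mp)) {
      gm <- png::readPNG(mp)
      if (length(dim(gm)) == 3) gm <- gm[, , 1]
      dec <- tryCatch(decode_mask(gm * 255, encoding),
                      error = function(e) conditionMessage(e))
      if (is.character(dec)) {
        errors <- c(errors, paste0(ids[i], ": ", dec))
      } else {
        if (is.null(od_masks)) {
          od_masks <- array(FALSE, c(S, S, n))
          oc_masks <- array(FALSE, c(S, S, n))
        }
        od_masks[, , i] <- resize_nearest(dec$od, S)
        oc_masks[, , i] <- resize_nearest(dec$oc, S)
        has[i, c("od", "oc")] <- TRUE
      }
    }
    if (!is.null(fovea_tab)) {
      row <- fovea_tab[fovea_tab$image_id == ids[i], ]
      if (nrow(row) == 1) {
        fx <- row$fovea_x; fy <- row$fovea_y
        if (fx < 0 || fx > orig_w - 1 || fy < 0 || fy > orig_h - 1) {
          errors <- c(errors,
                      paste0(ids[i], ": fovea coordinate out of bounds"))
        } else {
          if (is.null(fovea))
            fovea <- matrix(NA_real_, n, 2,
                            dimnames = list(NULL, c("x", "y")))
          fovea[i, ] <- c(fx * S / orig_w, fy * S / orig_h)
          has[i, "fovea"] <- TRUE
        }
      }
    }
    if (!is.null(labels_tab)) {
      row <- labels_tab[labels_tab$image_id == ids[i], ]
      if (nrow(row) == 1) {
        if (is.null(labels)) labels <- rep(NA_integer_, n)
        labels[i] <- as.integer(row$glaucoma)
        has[i, "glaucoma"] <- TRUE
      }
    }
  }
  if (length(errors)) stop("dataset errors:\n  ",
                           paste(errors, collapse = "\n  "))
  split <- NULL
  if (!is.null(split_tab)) {
    split <- split_tab$split[match(ids, split_tab$image_id)]
    bad <- !is.na(split) & !split %in% c("train", "val", "test")
    if (any(bad)) stop("unknown split tag(s): ",
                       paste(unique(split[bad]), collapse = ", "))
  }
  structure(list(images = images, od_masks = od_masks, oc_masks = oc_masks,
                 fovea = fovea, labels = labels, ids = ids, n = n,
                 has = has, split = split),
            class = "fundus_dataset")
}

# Nearest-neighbor resize of a logical/numeric matrix to S x S.
resize_nearest <- function(m, S) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(floor((seq_len(S) - 0.5) * h / S) + 1, 1), h)
  ci <- pmin(pmax(floor((seq_len(S) - 0.5) * w / S) + 1, 1), w)
  m[ri, ci]
}
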