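#' Configure the multi-task fundus network
#'
#' The backbone is a U-Net: a VGG-16 convolutional encoder (13 3x3
#' convolutions, ReLU, four 2x2 max-pools, no batch normalization, bottleneck
#' at 1/16 resolution) and a four-stage decoder. Each decoder stage performs
#' parameter-free bilinear x2 upsampling, concatenates the pre-pool activation
#' of the matching encoder block (skip connections carrying 512, 256, 128 and
#' 64 channels), and applies one 3x3 convolution + ReLU. Three 1x1
#' convolutional heads produce the optic-disc map (sigmoid), optic-cup map
#' (sigmoid) and fovea saliency map (identity); a classification head applies
#' global average pooling to the bottleneck followed by a 512 -> 256 -> 1
#' fully-connected stack with a sigmoid output.
#'
#' With the default widths the full four-task model has exactly 17,169,188
#' trainable parameters (14,714,688 of which are the canonical VGG-16
#' convolutional features).
#'
#' @param input_size Image side length in pixels; must be divisible by 16.
#'   512 is the intended size for real fundus photographs; 64 is convenient
#'   for desk-scale experiments.
#' @param encoder_widths List of five integer vectors, the output channels of
#'   each convolution per encoder block.
#' @param decoder_widths Integer vector of length 4, output channels of the
#'   four decoder stages.
#' @param classifier_hidden Hidden units of the classification head.
#' @param tasks Character subset of `c("od", "oc", "fovea", "glaucoma")`.
#'   Heads (and the whole decoder, when no map task is requested) are simply
#'   not constructed for absent tasks.
#' @param pretrained_encoder_path Optional path to an RDS file holding a named
#'   list `conv{block}_{idx}.weight` / `conv{block}_{idx}.bias` used to
#'   initialize the encoder instead of random initialization.
#' @return An object of class `mtl_config`.
#' @export
model_config <- function(input_size = 512L,
                         encoder_widths = list(c(64, 64), c(128, 128),
                                               c(256, 256, 256),
                                               c(512, 512, 512),
                                               c(512, 512, 512)),
                         decoder_widths = c(192, 96, 64, 32),
                         classifier_hidden = 256L,
                         tasks = c("od", "oc", "fovea", "glaucoma"),
                         pretrained_encoder_path = NULL) {
  input_size <- as.integer(input_size)
  if (length(input_size) != 1 || is.na(input_size) || input_size %% 16 != 0)
    stop("input_size must be a single integer divisible by 16")
  if (length(encoder_widths) != 5)
    stop("encoder_widths must have five blocks")
  if (length(decoder_widths) != 4)
    stop("decoder_widths must have exactly 4 entries")
  if (length(tasks) == 0) stop("tasks must be nonempty")
  tasks <- match.arg(tasks, c("od", "oc", "fovea", "glaucoma"),
                     several.ok = TRUE)
  if (!is.null(pretrained_encoder_path) &&
      !file.exists(pretrained_encoder_path))
    stop("pretrained encoder file not found: ", pretrained_encoder_path)
  structure(list(input_size = input_size,
                 encoder_widths = lapply(encoder_widths, as.integer),
                 decoder_widths = as.integer(decoder_widths),
                 classifier_hidden = as.integer(classifier_hidden),
                 tasks = tasks,
                 pretrained_encoder_path = pretrained_encoder_path),
            class = "mtl_config")
}

#' Restrict a configuration to a single task
#'
#' Used to build the single-task (STL) baselines: the same backbone with only
#' the head of one task attached.
#'
#' @param config An `mtl_config`.
#' @param task One of `"od"`, `"oc"`, `"fovea"`, `"glaucoma"`.
#' @return An `mtl_config` with `tasks = task`.
#' @export
single_task_config <- function(config, task) {
  task <- match.arg(task, c("od", "oc", "fovea", "glaucoma"))
  config$tasks <- task
  config
}

#' Build the network
#'
#' Allocates the network described by `config` and initializes all weights
#' with Kaiming-uniform draws (ReLU gain: bounds `sqrt(6 / fan_in)`) through
#' R's RNG; biases start at zero. Call [set.seed()] beforehand for a
#' reproducible initialization.
#'
#' @param config An [model_config()] object.
#' @return An object of class `mtl_model` (an opaque handle plus the config).
#'   The handle has reference semantics: training functions update it in
#'   place.
#' @export
build_model <- function(config) {
  if (!inherits(config, "mtl_config")) stop("config must be an mtl_config")
  ptr <- .net_create(config$input_size, config$encoder_widths,
                     config$decoder_widths, config$classifier_hidden,
                     config$tasks)
  shapes <- .net_param_shapes(ptr)
  params <- list()
  for (nm in names(shapes)) {
    sh <- shapes[[nm]]          # (cout, wcols, k)
    fan_in <- sh[2]             # conv: cin*k^2; fc: nin
    bound <- sqrt(6 / fan_in)
    params[[paste0(nm, ".weight")]] <-
      matrix(runif(sh[1] * sh[2], -bound, bound), sh[1], sh[2])
    params[[paste0(nm, ".bias")]] <- numeric(sh[1])
  }
  if (!is.null(config$pretrained_encoder_path)) {
    enc <- readRDS(config$pretrained_encoder_path)
    for (nm in names(enc)) {
      if (!nm %in% names(params))
        stop("pretrained entry does not match any encoder parameter: ", nm)
      tgt <- params[[nm]]
      v <- enc[[nm]]
      if (length(v) != length(tgt))
        stop("pretrained shape mismatch for ", nm)
      if (is.matrix(tgt)) v <- matrix(as.numeric(v), nrow(tgt), ncol(tgt))
      params[[nm]] <- v
    }
  }
  .net_set_params(ptr, params)
  structure(list(ptr = ptr, config = config, classifier = NULL),
            class = "mtl_model")
}

#' Count trainable parameters
#'
#' Exact enumeration of every trainable scalar held by the network. For a
#' convolution this equals `k^2 * c_in * c_out + c_out` and for a
#' fully-connected layer `n_in * n_out + n_out`; the count is independent of
#' `input_size` because the body is fully convolutional and the classifier is
#' fed through global average pooling.
#'
#' @param model An `mtl_model`.
#' @return Parameter count as a numeric scalar.
#' @export
count_parameters <- function(model) {
  if (!inherits(model, "mtl_model")) stop("model must be an mtl_model")
  .net_count_params(model$ptr)
}

#' Forward pass
#'
#' @param model An `mtl_model`.
#' @param images A numeric array `(S, S, 3)` for one image or `(S, S, 3, B)`
#'   for a batch, intensities in `[0, 1]`, where `S` is the configured
#'   `input_size`.
#' @param tasks Tasks to evaluate (default: all tasks of the model). Skipping
#'   map tasks also skips the decoder.
#' @return A list with, per requested task: `od`, `oc` probability arrays
#'   `(S, S, B)` in `[0, 1]`; `fovea` an unbounded real array `(S, S, B)`
#'   (identity activation); `glaucoma` a numeric vector of length `B` in
#'   `(0, 1)`.
#' @export
forward <- function(model, images, tasks = model$config$tasks) {
  S <- model$config$input_size
  d <- dim(images)
  if (is.null(d) || !length(d) %in% c(3, 4))
    stop("images must be a (S, S, 3) or (S, S, 3, B) array")
  if (length(d) == 3) dim(images) <- c(d, 1L)
  d <- dim(images)
  if (d[1] != S || d[2] != S || d[3] != 3)
    stop("images must be ", S, "x", S, " RGB (got ",
         paste(d, collapse = "x"), ")")
  .net_forward(model$ptr, images, tasks)
}

#' Extract or restore the network weights
#'
#' Weights travel as a flat named list `"<layer>.weight"` / `"<layer>.bias"`;
#' convolution weights are `(c_out, c_in * k^2)` matrices in im2col column
#' order, fully-connected weights `(n_out, n_in)` matrices.
#'
#' @param model An `mtl_model`.
#' @return Named list of numeric arrays.
#' @export
model_parameters <- function(model) .net_get_params(model$ptr)

#' @rdname model_parameters
#' @param params Named list as returned by [model_parameters()].
#' @export
set_model_parameters <- function(model, params) {
  .net_set_params(model$ptr, params)
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a named-array container (config + flat parameter list)
#' written with [saveRDS()].
#'
#' @param model An `mtl_model`.
#' @param path File path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, params = model_parameters(model),
               classifier = model$classifier), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns a rebuilt `mtl_model`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config)
  set_model_parameters(model, ck$params)
  model$classifier <- ck$classifier
  model
}

#' @export
print.mtl_model <- function(x, ...) {
  cat("Multi-task fundus network\n")
  cat("  input size :", x$config$input_size, "\n")
  cat("  tasks      :", paste(x$config$tasks, collapse = ", "), "\n")
  cat("  parameters :", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}
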