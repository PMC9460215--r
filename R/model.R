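#' Output length of a 1-D convolution
#'
#' The number of valid kernel placements when a kernel of size `kernel` is
#' slid with step `stride` over an input of length `l_in` padded with
#' `padding` zeros on each side: `floor((l_in + 2*padding - kernel)/stride) + 1`.
#'
#' @param l_in Input length (positive integer).
#' @param kernel Kernel size (>= 1).
#' @param stride Stride (>= 1).
#' @param padding Zero-padding per side (>= 0).
#' @return Integer output length.
#' @examples
#' conv_output_length(10000, 8, 4, 2)  # 2500
#' @export
conv_output_length <- function(l_in, kernel, stride, padding = 0) {
  stopifnot(l_in >= 1, kernel >= 1, stride >= 1, padding >= 0)
  if (kernel > l_in + 2 * padding)
    stop("kernel (", kernel, ") larger than padded input (", l_in + 2 * padding,
         ")", call. = FALSE)
  as.integer((l_in + 2 * padding - kernel) %/% stride + 1)
}

layer_spec <- function(layer_type, activation = "none", alpha = NA_real_,
                       kernel = NA_integer_, stride = NA_integer_,
                       padding = NA_integer_, out_channels = NA_integer_,
                       upsample_factor = NA_integer_, out_length = NA_integer_,
                       momentum = NA_real_) {
  stopifnot(layer_type %in% c("fully_connected", "upsample", "conv1d",
                              "batch_norm", "activation_only"))
  stopifnot(activation %in% c("ReLU", "LeakyReLU", "Tanh", "Softmax", "none"))
  if (layer_type == "conv1d") stopifnot(kernel >= 1, stride >= 1, padding >= 0)
  list(layer_type = layer_type, activation = activation, alpha = alpha,
       kernel = kernel, stride = stride, padding = padding,
       out_channels = out_channels, upsample_factor = upsample_factor,
       out_length = out_length, momentum = momentum)
}

new_architecture_spec <- function(name, input_shape, layers) {
  structure(list(name = name, input_shape = input_shape, layers = layers),
            class = "architecture_spec")
}

#' Generator architecture specification
#'
#' The generator maps a standard-normal noise vector of length
#' `input_length` to a spectral-frame-shaped output in \[-1, 1\]: a fully
#' connected layer to `16 * input_length` units reshaped to
#' `(input_length/4) x 64` channels, two nearest-neighbour x2 upsampling
#' stages each followed by a kernel-3 / stride-1 / padding-1 convolution
#' (ReLU) and batch normalization (momentum 0.8 on the current batch
#' statistic), and a final kernel-3 convolution to a single Tanh channel. At
#' the reference frame length 10,000 the fully connected layer has 160,000
#' output units reshaped to 2500 x 64 and the declared per-layer shapes are
#' 2500x64, 5000x64, 5000x64, 10,000x64, 10,000x32, 10,000x1.
#'
#' @param input_length Noise/frame length; must be divisible by 4. Default
#'   10,000 (the reference scale).
#' @return An `architecture_spec`.
#' @export
generator_spec <- function(input_length = 10000) {
  stopifnot(input_length >= 4, input_length %% 4 == 0)
  l4 <- input_length %/% 4L
  layers <- list(
    layer_spec("fully_connected", out_length = l4, out_channels = 64L),
    layer_spec("upsample", upsample_factor = 2L),
    layer_spec("conv1d", "ReLU", kernel = 3L, stride = 1L, padding = 1L,
               out_channels = 64L),
    layer_spec("batch_norm", momentum = 0.8),
    layer_spec("upsample", upsample_factor = 2L),
    layer_spec("conv1d", "ReLU", kernel = 3L, stride = 1L, padding = 1L,
               out_channels = 32L),
    layer_spec("batch_norm", momentum = 0.8),
    layer_spec("conv1d", "Tanh", kernel = 3L, stride = 1L, padding = 1L,
               out_channels = 1L)
  )
  new_architecture_spec("generator", c(length = input_length, channels = 1L),
                        layers)
}

#' Classifier architecture specification
#'
#' The (K+1)-class discriminator-turned-classifier: four kernel-8 / stride-4
#' convolutions (paddings 2, 0, 0, 0; channel widths 64, 64, 64, 1), each
#' followed by LeakyReLU with slope 0.2, then a fully connected Softmax head
#' over K+1 outputs -- the K real classes plus one class for generator
#' output. With K = 2 the head has 3 neurons (no tendency, tendency, fake).
#' At the reference input length 10,000 the conv-stack trace is 2500, 624,
#' 155, 37.
#'
#' @param K Number of real data classes (>= 1), default 2.
#' @param input_length Frame length, default 10,000.
#' @return An `architecture_spec`.
#' @export
classifier_spec <- function(K = 2, input_length = 10000) {
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  layers <- list(
    layer_spec("conv1d", "LeakyReLU", alpha = 0.2, kernel = 8L, stride = 4L,
               padding = 2L, out_channels = 64L),
    layer_spec("conv1d", "LeakyReLU", alpha = 0.2, kernel = 8L, stride = 4L,
               padding = 0L, out_channels = 64L),
    layer_spec("conv1d", "LeakyReLU", alpha = 0.2, kernel = 8L, stride = 4L,
               padding = 0L, out_channels = 64L),
    layer_spec("conv1d", "LeakyReLU", alpha = 0.2, kernel = 8L, stride = 4L,
               padding = 0L, out_channels = 1L),
    layer_spec("fully_connected", "Softmax", out_length = 1L,
               out_channels = as.integer(K + 1))
  )
  new_architecture_spec("classifier", c(length = input_length, channels = 1L),
                        layers)
}

#' Trace the per-layer output shapes of an architecture
#'
#' Applies the shape rules layer by layer (fully connected: declared reshape;
#' upsample: length times factor; conv1d: [conv_output_length()]; batch norm:
#' unchanged) and returns one row per layer. This validates an architecture
#' on paper, without allocating any weights.
#'
#' @param spec An `architecture_spec`.
#' @return A data frame with columns `layer`, `layer_type`, `activation`,
#'   `out_length`, `out_channels`.
#' @examples
#' trace_shapes(classifier_spec())
#' @export
trace_shapes <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  len <- spec$input_shape[["length"]]
  ch <- spec$input_shape[["channels"]]
  rows <- lapply(seq_along(spec$layers), function(i) {
    l <- spec$layers[[i]]
    if (l$layer_type == "fully_connected") {
      len <<- l$out_length; ch <<- l$out_channels
    } else if (l$layer_type == "upsample") {
      len <<- len * l$upsample_factor
    } else if (l$layer_type == "conv1d") {
      len <<- conv_output_length(len, l$kernel, l$stride, l$padding)
      ch <<- l$out_channels
    } # batch_norm / activation_only leave shapes unchanged
    data.frame(layer = i, layer_type = l$layer_type, activation = l$activation,
               out_length = as.integer(len), out_channels = as.integer(ch))
  })
  do.call(rbind, rows)
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec> %s, input %d x %d\n", x$name,
              x$input_shape[["length"]], x$input_shape[["channels"]]))
  print(trace_shapes(x))
  invisible(x)
}

#' Serialize an architecture specification to/from YAML
#'
#' The YAML form is a stable, diff-able transcription of the layer table so
#' a test suite (or a reviewer) can compare it against an independently
#' checked-in copy.
#'
#' @param spec An `architecture_spec`.
#' @param path Optional file path; if `NULL`, the YAML string is returned.
#' @return `arch_to_yaml`: YAML string or `path`; `arch_from_yaml`: the
#'   reconstructed `architecture_spec`.
#' @export
arch_to_yaml <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "architecture_spec"))
  obj <- list(name = spec$name,
              input_shape = as.list(spec$input_shape),
              layers = lapply(spec$layers, function(l) l[!is.na(l) | vapply(l, is.character, logical(1))]))
  txt <- yaml::as.yaml(obj)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname arch_to_yaml
#' @param input Path to a YAML file, or a YAML string.
#' @export
arch_from_yaml <- function(input) {
  obj <- if (file.exists(input)) yaml::read_yaml(input) else
    yaml::yaml.load(input)
  layers <- lapply(obj$layers, function(l)
    do.call(layer_spec, l[names(l) %in% names(formals(layer_spec))]))
  new_architecture_spec(obj$name,
                        c(length = as.integer(obj$input_shape$length),
                          channels = as.integer(obj$input_shape$channels)),
                        layers)
}

#' Draw generator input noise
#'
#' Standard-normal noise of the generator's input length, the convention for
#' this network family.
#'
#' @param n Number of noise vectors.
#' @param length Noise length (equals the frame length).
#' @param rng_seed Optional seed.
#' @return An `n x length` matrix.
#' @export
draw_noise <- function(n, length = 10000, rng_seed = NULL) {
  with_rng(rng_seed, matrix(stats::rnorm(n * length), nrow = n))
}
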