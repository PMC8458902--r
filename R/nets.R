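# Network architectures.
#
# Generator: n_down strided convolutions, a chain of residual blocks, and
# n_down upsample+convolution ("deconvolution") stages. Every convolution is
# followed by instance normalization and ReLU except the output stage, which
# uses a sigmoid so synthesized maps live in the same [0, 1] normalized ADC
# units as the training references.
#
# Discriminator: a fully convolutional least-squares-GAN critic (5 conv
# layers) whose output is a map of unbounded real scores.
#
# Recognition model: a VGG-style stack of 5 conv-ReLU units (benign/malignant
# classifier) whose activations provide the multi-level verification features;
# level 0 denotes the raw input image.

#' Generator architecture specification
#'
#' @param base_width channels after the first convolution; doubled at each
#'   downsampling stage.
#' @param n_residual_blocks number of residual blocks at the bottleneck.
#' @param n_down number of stride-2 convolutions (and matching upsampling
#'   "deconvolution" stages).
#' @param kernel convolution kernel size.
#' @export
generator_spec <- function(base_width = 16L, n_residual_blocks = 5L,
                           n_down = 3L, kernel = 3L) {
  stopifnot(base_width >= 1, n_residual_blocks >= 0, n_down >= 1)
  structure(list(base_width = as.integer(base_width),
                 n_residual_blocks = as.integer(n_residual_blocks),
                 n_down = as.integer(n_down), kernel = as.integer(kernel)),
            class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' @param base_width channels after the first convolution.
#' @param n_conv_layers total convolution layers (final one maps to a 1-channel
#'   score map with no saturating nonlinearity, as in a least-squares GAN).
#' @export
discriminator_spec <- function(base_width = 16L, n_conv_layers = 5L) {
  stopifnot(n_conv_layers >= 2)
  structure(list(base_width = as.integer(base_width),
                 n_conv_layers = as.integer(n_conv_layers)),
            class = "discriminator_spec")
}

#' Recognition (classifier) architecture specification
#'
#' A reduced VGG-style stack of five conv-activation units used both as a
#' benign/malignant classifier and as the feature extractor of the multi-level
#' verification loss. Feature level 0 is the raw image; levels 1..5 index the
#' conv-activation units.
#'
#' @param base_width channels of the first unit.
#' @param n_classes number of output classes.
#' @param feature_levels ordered levels at which features are extracted.
#' @export
recognition_spec <- function(base_width = 8L, n_classes = 2L,
                             feature_levels = c(0L, 1L, 3L, 5L)) {
  stopifnot(all(feature_levels %in% 0:5), !is.unsorted(feature_levels))
  structure(list(base_width = as.integer(base_width),
                 n_classes = as.integer(n_classes),
                 feature_levels = as.integer(feature_levels)),
            class = "recognition_spec")
}

#' Build the generator network
#'
#' @param spec a [generator_spec()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `adcgan_generator`.
#' @export
build_generator <- function(spec = generator_spec(), seed = 1L) {
  w <- spec$base_width; k <- spec$kernel
  net <- with_seed(seed, {
    layers <- list()
    cin <- 1L
    for (i in seq_len(spec$n_down)) {
      cout <- w * 2L^(i - 1L)
      layers <- c(layers, list(layer_conv(cin, cout, k, stride = 2L, pad = (k - 1L) %/% 2L),
                               layer_inorm(), layer_relu()))
      cin <- cout
    }
    for (i in seq_len(spec$n_residual_blocks))
      layers <- c(layers, list(layer_resblock(cin, k)))
    for (i in seq_len(spec$n_down)) {
      cout <- if (i == spec$n_down) 1L else w * 2L^(spec$n_down - 1L - i)
      layers <- c(layers, list(layer_up2(), layer_conv(cin, cout, k)))
      layers <- c(layers, if (i == spec$n_down) list(layer_sigmoid())
                          else list(layer_inorm(), layer_relu()))
      cin <- cout
    }
    layers
  })
  structure(list(spec = spec, net = net, seed = as.integer(seed)),
            class = "adcgan_generator")
}

#' Build the discriminator network
#'
#' @param spec a [discriminator_spec()].
#' @param seed integer seed for weight initialization.
#' @export
build_discriminator <- function(spec = discriminator_spec(), seed = 1L) {
  w <- spec$base_width
  n <- spec$n_conv_layers
  net <- with_seed(seed, {
    layers <- list()
    cin <- 1L
    for (i in seq_len(n - 1L)) {
      cout <- w * 2L^min(i - 1L, 2L)
      stride <- if (i <= 3L) 2L else 1L
      layers <- c(layers, list(layer_conv(cin, cout, 3L, stride = stride)))
      if (i > 1L) layers <- c(layers, list(layer_inorm()))
      layers <- c(layers, list(layer_lrelu()))
      cin <- cout
    }
    c(layers, list(layer_conv(cin, 1L, 3L)))  # linear score map
  })
  structure(list(spec = spec, net = net, seed = as.integer(seed)),
            class = "adcgan_discriminator")
}

#' Build the recognition network
#'
#' @param spec a [recognition_spec()].
#' @param image_size input resolution (needed to size the classifier head).
#' @param seed integer seed for weight initialization.
#' @export
build_recognizer <- function(spec = recognition_spec(), image_size = 64L,
                             seed = 1L) {
  w <- spec$base_width
  if (image_size %% 8L != 0L) stop("image_size must be divisible by 8")
  flat <- (image_size %/% 8L)^2 * 4L * w
  built <- with_seed(seed, {
    trunk <- list(
      layer_conv(1L, w, 3L), layer_relu(),                    # unit 1
      layer_conv(w, w, 3L), layer_relu(), layer_maxpool2(),   # unit 2
      layer_conv(w, 2L * w, 3L), layer_relu(),                # unit 3
      layer_conv(2L * w, 2L * w, 3L), layer_relu(), layer_maxpool2(),  # unit 4
      layer_conv(2L * w, 4L * w, 3L), layer_relu()            # unit 5
    )
    head <- list(layer_maxpool2(), layer_flatten(),
                 layer_dense(flat, spec$n_classes))
    list(trunk = trunk, head = head)
  })
  # layer index of each conv unit's activation output within the trunk
  taps <- c(`1` = 2L, `2` = 4L, `3` = 7L, `4` = 9L, `5` = 12L)
  structure(list(spec = spec, trunk = built$trunk, head = built$head,
                 taps = taps, seed = as.integer(seed)),
            class = "adcgan_recognizer")
}

# Forward pass of the generator on a (H, W, 1, N) tensor.
gen_forward <- function(gen, x, keep = TRUE) {
  x <- as_tensor(x)
  d <- dim(x)
  div <- 2L^gen$spec$n_down
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop(sprintf("generator input %dx%d must be divisible by %d (pad to %dx%d)",
                 d[1], d[2], div, div * ceiling(d[1] / div), div * ceiling(d[2] / div)))
  if (d[3] != 1L) stop("generator expects a single-channel input")
  net_forward(gen$net, x, keep = keep)
}

disc_forward <- function(disc, x, keep = TRUE) net_forward(disc$net, as_tensor(x), keep = keep)

# Forward through the classifier trunk + head; returns logits and trunk outs.
recog_forward <- function(model, x, keep = TRUE) {
  tr <- net_forward(model$trunk, as_tensor(x), keep = keep)
  hd <- net_forward(model$head, tr$out, keep = keep)
  list(logits = hd$out, trunk = tr, head = hd)
}
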