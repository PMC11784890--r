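#' CARAFE configuration
#'
#' Hyperparameters of the content-aware reassembly upsampler: the channel
#' width the input is compressed to before kernel prediction, the kernel
#' encoder's own convolution size, the reassembly neighbourhood size, and the
#' upsampling factor. Defaults are the operator's canonical settings.
#'
#' @param compressed_ch channels of the compressed kernel-prediction input.
#' @param k_encoder odd convolution size of the kernel encoder.
#' @param k_up odd reassembly neighbourhood size.
#' @param scale integer upsampling factor (>= 2).
#' @export
carafe_config <- function(compressed_ch = 64L, k_encoder = 3L, k_up = 5L,
                          scale = 2L) {
  if (compressed_ch <= 0) stop("compressed_ch must be positive")
  if (k_encoder %% 2 != 1 || k_up %% 2 != 1)
    stop("encoder and reassembly kernels must be odd-sized")
  if (scale < 2) stop("upsampling scale must be a positive integer >= 2")
  list(compressed_ch = compressed_ch, k_encoder = k_encoder, k_up = k_up,
       scale = as.integer(scale))
}

#' Content-aware reassembly (CARAFE) upsampler
#'
#' Predicts, from the input content, a softmax-normalized `k_up x k_up`
#' reassembly kernel for each output location and mixes the corresponding
#' source neighbourhood with it: a 1x1 compressor, a kernel-encoder
#' convolution emitting `scale^2 * k_up^2` logits per source cell, pixel
#' shuffling to output resolution, channel softmax, then reassembly. Every
#' output value is a convex combination of source values (border
#' neighbourhoods replicate the edge), so constant inputs are reproduced
#' exactly and output values stay within the source neighbourhood's range.
#'
#' @param channels input channel count (unchanged by the operator).
#' @param cfg a [carafe_config()].
#' @return a CARAFE module; apply with [carafe_upsample()].
#' @export
carafe_layer <- function(channels, cfg = carafe_config()) {
  new_module("carafe",
    compressor = conv_layer(channels, cfg$compressed_ch, 1L, act = FALSE),
    encoder = conv_layer(cfg$compressed_ch, cfg$scale^2 * cfg$k_up^2,
                         cfg$k_encoder, act = FALSE, bn = FALSE, bias = TRUE),
    cfg = cfg, channels = channels)
}

fwd.carafe <- function(m, x, training = FALSE, ...) {
  logits <- fwd(m$encoder, fwd(m$compressor, x, training), training)
  kern <- ad_softmax_c(ad_pixel_shuffle(logits, m$cfg$scale))
  ad_carafe_reassemble(x, kern, m$cfg$scale, m$cfg$k_up)
}

#' @rdname carafe_layer
#' @param x numeric feature map, dim `(channels, H, W, batch)`.
#' @param layer a module built by `carafe_layer()`.
#' @param mode forward mode as in [module_forward()].
#' @return array of dim `(channels, scale*H, scale*W, batch)`.
#' @export
carafe_upsample <- function(x, layer, mode = "eval") {
  stopifnot(inherits(layer, "carafe"), dim(x)[1] == layer$channels)
  module_forward(layer, x, mode)
}

#' Channel-enhancement module (FEM / FSM)
#'
#' Evaluates per-channel importance by average-pooling the feature map along
#' the height and width directions, passing the concatenated directional
#' descriptors through a shared two-layer bottleneck (reduction `ratio`), and
#' squashing the pooled logits into a per-channel gate in (0, 1). The gated
#' channels are added back residually (`x * (1 + gate)`) and a final 1x1
#' convolution screens the channels. Spatial shape is preserved.
#'
#' @param channels input (= output) channel count.
#' @param ratio bottleneck reduction ratio.
#' @return an FEM module; apply with [fem_enhance()].
#' @export
fem_layer <- function(channels, ratio = 4L) {
  cr <- max(1L, channels %/% ratio)
  new_module("fem",
    w1 = ad_param(matrix(stats::rnorm(cr * channels, sd = sqrt(2 / channels)),
                         cr, channels)),
    b1 = ad_param(numeric(cr)),
    w2 = ad_param(matrix(stats::rnorm(channels * cr, sd = sqrt(2 / cr)),
                         channels, cr)),
    b2 = ad_param(numeric(channels)),
    screen = conv_layer(channels, channels, 1L),
    channels = channels, ratio = ratio)
}

fwd.fem <- function(m, x, training = FALSE, ...) {
  fwd(m$screen, ad_fem_gate(x, m$w1, m$b1, m$w2, m$b2), training)
}

#' @rdname fem_layer
#' @param x numeric feature map `(channels, H, W, batch)`.
#' @param layer a module built by `fem_layer()`.
#' @param mode forward mode as in [module_forward()].
#' @export
fem_enhance <- function(x, layer, mode = "eval") {
  stopifnot(inherits(layer, "fem"), dim(x)[1] == layer$channels)
  d <- dim(x)
  if (d[2] == 0 || d[3] == 0) stop("fem: empty feature map")
  module_forward(layer, x, mode)
}

#' 2D sine-cosine positional embedding
#'
#' Deterministic transformer position coding on an `h x w` grid: the channel
#' dimension splits into four quarters -- sine and cosine of the x position,
#' then sine and cosine of the y position -- at geometrically spaced
#' frequencies. Token order is x-fastest (`t = (y-1)*w + x`), matching the
#' package's feature-map flattening.
#'
#' @param h,w grid size.
#' @param dim embedding width, divisible by 4.
#' @param temperature frequency base.
#' @return an `(h*w) x dim` matrix with all entries in `[-1, 1]`.
#' @export
sincos_pos_embed_2d <- function(h, w, dim, temperature = 10000) {
  if (dim %% 4 != 0) stop("embedding dim must be divisible by 4")
  q <- dim %/% 4L
  omega <- 1 / temperature^((seq_len(q) - 1) / q)
  xs <- rep(seq_len(w) - 1, times = h)
  ys <- rep(seq_len(h) - 1, each = w)
  xo <- outer(xs, omega)
  yo <- outer(ys, omega)
  cbind(sin(xo), cos(xo), sin(yo), cos(yo))
}
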