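#' Spatial output side of a convolution or pooling layer
#'
#' For a square `H_in x H_in` input, a `k x k` receptive field, padding `P`
#' and stride `S`, the output side is
#' `floor((H_in - k + 2 P) / S) + 1`. Integer (floor) division applies to
#' convolution and pooling alike; the width is taken equal to the height
#' (square convention).
#'
#' @param H_in Input side length (positive integer).
#' @param k Receptive-field side (positive integer).
#' @param P Zero-padding (non-negative integer).
#' @param S Stride (positive integer).
#' @return The output side length, a positive integer.
#' @export
#' @examples
#' output_size(63, 3, 0, 2) # 31
#' output_size(15, 3, 0, 2) # 7
#' output_size(6, 3, 1, 1)  # 6
output_size <- function(H_in, k, P, S) {
  stopifnot(H_in >= 1, k >= 1, P >= 0, S >= 1)
  if (H_in + 2 * P < k) {
    stop("receptive field (k = ", k, ") larger than padded input (",
         H_in, " + 2*", P, ")", call. = FALSE)
  }
  as.integer((H_in - k + 2 * P) %/% S + 1)
}

#' Construct one layer specification
#'
#' @param kind One of `input`, `convolution`, `pooling`, `normalization`,
#'   `fully_connected`, `dropout`, `relu`, `softmax`, `loss`.
#' @param k,S,P Receptive-field side, stride and padding (convolution and
#'   pooling layers).
#' @param C_out Output channel count (convolution and fully-connected
#'   layers; for fully-connected layers this is the output width).
#' @param rate Dropout fraction in `(0, 1)` (dropout layers).
#' @param note Free-text annotation (e.g. provenance of assumed values).
#' @return A one-row tibble.
#' @export
layer_spec <- function(kind, k = NA_integer_, S = NA_integer_,
                       P = NA_integer_, C_out = NA_integer_,
                       rate = NA_real_, note = NA_character_) {
  kinds <- c("input", "convolution", "pooling", "normalization",
             "fully_connected", "dropout", "relu", "softmax", "loss")
  kind <- match.arg(kind, kinds)
  if (kind %in% c("convolution", "pooling")) {
    stopifnot(k >= 1, S >= 1, P >= 0)
  }
  if (kind %in% c("convolution", "fully_connected")) stopifnot(C_out >= 1)
  if (kind == "dropout") stopifnot(rate > 0, rate < 1)
  tibble::tibble(kind = kind, k = as.integer(k), S = as.integer(S),
                 P = as.integer(P), C_out = as.integer(C_out),
                 rate = as.numeric(rate), note = as.character(note))
}

#' Construct an architecture descriptor
#'
#' An ordered stack of layer specifications plus the input geometry. The
#' first layer must be `input` and the stack must end `softmax`, `loss`.
#'
#' @param layers A tibble of stacked [layer_spec()] rows.
#' @param input_size Square input side n_0.
#' @param input_channels Input channel count c_0 (1 for grayscale).
#' @param n_labels Output dimension L.
#' @return An object of class `architecture`.
#' @export
architecture <- function(layers, input_size, input_channels = 1L, n_labels) {
  stopifnot(nrow(layers) >= 3)
  if (layers$kind[1] != "input") {
    stop("first layer must be `input`", call. = FALSE)
  }
  nl <- nrow(layers)
  if (layers$kind[nl - 1] != "softmax" || layers$kind[nl] != "loss") {
    stop("architecture must end with softmax then loss", call. = FALSE)
  }
  fc <- which(layers$kind == "fully_connected")
  if (length(fc) > 0 && layers$C_out[fc[length(fc)]] != n_labels) {
    stop("final fully-connected width must equal n_labels", call. = FALSE)
  }
  structure(
    list(layers = layers,
         input_size = as.integer(input_size),
         input_channels = as.integer(input_channels),
         n_labels = as.integer(n_labels)),
    class = "architecture"
  )
}

#' @export
print.architecture <- function(x, ...) {
  cat("<architecture> input ", x$input_size, "x", x$input_size, "x",
      x$input_channels, " -> ", x$n_labels, " labels, ",
      nrow(x$layers), " layers\n", sep = "")
  print(trace_shapes(x), n = Inf)
  invisible(x)
}

#' Trace feature-map shapes through an architecture
#'
#' Applies the output-size formula layer by layer, starting from the input
#' geometry. Width always equals height (square convention). Errors name
#' the first layer whose receptive field no longer fits its input.
#'
#' @param arch An [architecture()].
#' @return A tibble with one row per layer: `layer`, `kind`, `H_out`,
#'   `W_out`, `C_out`.
#' @export
trace_shapes <- function(arch) {
  H <- arch$input_size
  C <- arch$input_channels
  n <- nrow(arch$layers)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    l <- arch$layers[i, ]
    if (l$kind == "input") {
      # geometry given by the descriptor
    } else if (l$kind %in% c("convolution", "pooling")) {
      H <- tryCatch(output_size(H, l$k, l$P, l$S), error = function(e)
        stop("layer ", i, " (", l$kind, "): ", conditionMessage(e),
             call. = FALSE))
      if (l$kind == "convolution") C <- l$C_out
    } else if (l$kind == "fully_connected") {
      H <- 1L
      C <- l$C_out
    }
    rows[[i]] <- tibble::tibble(layer = i, kind = l$kind, H_out = H,
                                W_out = H, C_out = C)
  }
  dplyr::bind_rows(rows)
}

# The AlexNet-style layer pattern used throughout: five convolutions with
# interleaved max pooling and cross-channel normalization, then two wide
# fully-connected layers with dropout and a final classifier. Kernel sizes
# of the dimension-preserving middle convolutions (5, 3, 3, 3 with matching
# padding) and the first convolution's padding of 2 are assumptions carried
# in the layer notes: only the channel counts and the 63/31/15/7 chain are
# pinned externally.
build_layer_stack <- function(n_labels, width_factor = 1) {
  ch <- function(c) max(8L, as.integer(ceiling(c * width_factor)))
  dplyr::bind_rows(
    layer_spec("input"),
    layer_spec("convolution", k = 11, S = 4, P = 2, C_out = ch(96),
               note = "padding 2 inferred from the printed 63x63x96 output"),
    layer_spec("relu"),
    layer_spec("pooling", k = 3, S = 2, P = 0),
    layer_spec("normalization"),
    layer_spec("convolution", k = 5, S = 1, P = 2, C_out = ch(256),
               note = "dimension-preserving; kernel 5 assumed (AlexNet)"),
    layer_spec("relu"),
    layer_spec("pooling", k = 3, S = 2, P = 0),
    layer_spec("normalization"),
    layer_spec("convolution", k = 3, S = 1, P = 1, C_out = ch(384),
               note = "dimension-preserving; kernel 3 assumed (AlexNet)"),
    layer_spec("relu"),
    layer_spec("convolution", k = 3, S = 1, P = 1, C_out = ch(384),
               note = "dimension-preserving; kernel 3 assumed (AlexNet)"),
    layer_spec("relu"),
    layer_spec("convolution", k = 3, S = 1, P = 1, C_out = ch(256),
               note = "dimension-preserving; kernel 3 assumed (AlexNet)"),
    layer_spec("relu"),
    layer_spec("pooling", k = 3, S = 2, P = 0),
    layer_spec("fully_connected", C_out = ch(4096)),
    layer_spec("relu"),
    layer_spec("dropout", rate = 0.5),
    layer_spec("fully_connected", C_out = ch(4096)),
    layer_spec("relu"),
    layer_spec("dropout", rate = 0.5),
    layer_spec("fully_connected", C_out = n_labels),
    layer_spec("softmax"),
    layer_spec("loss")
  )
}

#' The reference 12-layer classification network
#'
#' The full-scale network: grayscale 256x256 input; 11x11 stride-4
#' convolution to 63x63x96; 3x3 stride-2 max poolings driving the
#' 63 -> 31 -> 15 -> 7 spatial chain with cross-channel normalization;
#' three dimension-preserving convolutions (384, 384, 256 channels); two
#' 4096-wide fully-connected layers with dropout; and a 57-way softmax
#' classifier head.
#'
#' @return An [architecture()].
#' @export
reference_architecture <- function() {
  architecture(build_layer_stack(57L, 1), input_size = 256L,
               input_channels = 1L, n_labels = 57L)
}

#' A scaled-down variant of the reference network
#'
#' Same layer pattern as [reference_architecture()] with every channel count
#' and fully-connected width multiplied by `width_factor` (rounded up,
#' floored at 8) and the classifier head sized to `n_labels`. The shape
#' trace is validated; inputs too small for the pooling chain raise an
#' error.
#'
#' @param input_size Square input side (>= 32).
#' @param n_labels Output dimension (>= 2).
#' @param width_factor Channel scaling in `(0, 1]`.
#' @return An [architecture()].
#' @export
scaled_architecture <- function(input_size, n_labels, width_factor = 1) {
  stopifnot(input_size >= 32, n_labels >= 2,
            width_factor > 0, width_factor <= 1)
  arch <- architecture(build_layer_stack(as.integer(n_labels), width_factor),
                       input_size = as.integer(input_size),
                       input_channels = 1L, n_labels = as.integer(n_labels))
  trace_shapes(arch)  # errors if the chain collapses
  arch
}

#' Serialize an architecture to JSON
#' @param arch An [architecture()].
#' @param path Optional file to write to.
#' @return The JSON string, invisibly when `path` is given.
#' @export
arch_to_json <- function(arch, path = NULL) {
  doc <- jsonlite::toJSON(
    list(input_size = arch$input_size,
         input_channels = arch$input_channels,
         n_labels = arch$n_labels,
         layers = arch$layers),
    dataframe = "rows", auto_unbox = TRUE, pretty = TRUE, na = "null"
  )
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Read an architecture from JSON
#' @param json A JSON string or file path produced by [arch_to_json()].
#' @return An [architecture()].
#' @export
arch_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  layers <- tibble::as_tibble(doc$layers)
  for (col in c("k", "S", "P", "C_out")) {
    if (is.null(layers[[col]])) layers[[col]] <- NA_integer_
    layers[[col]] <- as.integer(layers[[col]])
  }
  if (is.null(layers$rate)) layers$rate <- NA_real_
  if (is.null(layers$note)) layers$note <- NA_character_
  architecture(layers, doc$input_size, doc$input_channels, doc$n_labels)
}
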