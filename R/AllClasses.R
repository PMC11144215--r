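#' SlideImage: an in-memory whole-slide image at a stated base magnification
#'
#' Wraps an 8-bit RGB raster (stored as a `height x width x 3` array of
#' doubles on the `k/255` grid) together with its identifier and base
#' magnification. Lower magnifications are synthesized on demand by
#' area-averaged downsampling (see [slidePixels()]), emulating the pyramid
#' levels of production slide formats.
#'
#' @slot pixels `height x width x 3` numeric array in `[0, 1]`.
#' @slot slideId character scalar.
#' @slot baseMagnification one of `"10x"`, `"20x"`, `"40x"`.
#' @export
setClass("SlideImage",
  representation(pixels = "array", slideId = "character",
                 baseMagnification = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3] != 3L)
      msg <- c(msg, "pixels must be a height x width x 3 array")
    if (any(!is.finite(object@pixels)) ||
        min(object@pixels) < 0 || max(object@pixels) > 1)
      msg <- c(msg, "pixel values must be finite and in [0, 1]")
    if (!object@baseMagnification %in% c("10x", "20x", "40x"))
      msg <- c(msg, "baseMagnification must be one of '10x', '20x', '40x'")
    if (length(msg)) msg else TRUE
  })

#' FeatureBag: the multiple-instance unit of prediction
#'
#' An `N x 512` matrix of tile embeddings with an aligned table of tile
#' references (row `i` of `features` embeds `tiles[i, ]`).
#'
#' @slot features `N x 512` numeric matrix, all finite.
#' @slot tiles data.frame with columns `slide_id`, `x`, `y`, `size`.
#' @export
setClass("FeatureBag",
  representation(features = "matrix", tiles = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@features) < 1L) msg <- c(msg, "bag must hold >= 1 tile")
    if (ncol(object@features) != 512L)
      msg <- c(msg, "features must have 512 columns")
    if (any(!is.finite(object@features)))
      msg <- c(msg, "features must be finite")
    if (nrow(object@tiles) != nrow(object@features))
      msg <- c(msg, "tiles must align with feature rows")
    if (!all(c("x", "y", "size") %in% names(object@tiles)))
      msg <- c(msg, "tiles needs columns x, y, size")
    if (length(msg)) msg else TRUE
  })

#' SlidePrediction: slide-level likelihood with tile attention weights
#'
#' @slot likelihood biomarker-positive probability in `[0, 1]`.
#' @slot attentionWeights non-negative weights summing to 1, one per tile.
#' @slot tiles data.frame aligned with `attentionWeights`.
#' @export
setClass("SlidePrediction",
  representation(likelihood = "numeric", attentionWeights = "numeric",
                 tiles = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (length(object@likelihood) != 1L || !is.finite(object@likelihood) ||
        object@likelihood < 0 || object@likelihood > 1)
      msg <- c(msg, "likelihood must be a single value in [0, 1]")
    w <- object@attentionWeights
    if (any(w < 0)) msg <- c(msg, "attention weights must be non-negative")
    if (abs(sum(w) - 1) > 1e-6)
      msg <- c(msg, "attention weights must sum to 1 (tol 1e-6)")
    if (nrow(object@tiles) != length(w))
      msg <- c(msg, "tiles must align with attention weights")
    if (length(msg)) msg else TRUE
  })

#' MILModel: attention network, classifier head and frozen backbone
#'
#' @slot backbone list describing the tile -> 512-vector feature extractor.
#' @slot params list with attention matrix `V`, attention vector `w`,
#'   head weights `W` (2 x 512) and bias `b` (length 2).
#' @slot featureStats list with per-dimension `center`/`scale` used to
#'   standardize bags before pooling.
#' @slot config list of training hyperparameters (see [milConfig()]).
#' @slot threshold operating threshold shipped with the model (may be `NA`
#'   before model selection).
#' @export
setClass("MILModel",
  representation(backbone = "list", params = "list", featureStats = "list",
                 config = "list", threshold = "numeric"),
  validity = function(object) {
    p <- object@params
    msg <- character()
    if (!all(c("V", "w", "W", "b") %in% names(p)))
      msg <- c(msg, "params needs V, w, W, b")
    else {
      if (ncol(p$V) != 512L) msg <- c(msg, "V must be hidden_dim x 512")
      if (length(p$w) != nrow(p$V)) msg <- c(msg, "w must match V's rows")
      if (!all(dim(p$W) == c(2L, 512L))) msg <- c(msg, "W must be 2 x 512")
      if (length(p$b) != 2L) msg <- c(msg, "b must have length 2")
      if (any(!is.finite(c(p$V, p$w, p$W, p$b))))
        msg <- c(msg, "parameters must be finite")
    }
    if (length(msg)) msg else TRUE
  })

#' DeviceResult: outcome of one device run on one slide
#'
#' Either `status = "ok"` with a likelihood, binary call, optional tier and
#' the number of tiles used, or `status = "error"` with one of the device's
#' fixed error messages.
#'
#' @slot slideId character scalar.
#' @slot status `"ok"` or `"error"`.
#' @slot errorMessage the error string, or `NA_character_` when ok.
#' @slot likelihood numeric in `[0, 1]` or `NA`.
#' @slot call `"FGFR+"`, `"FGFR-"` or `NA`.
#' @slot tier `"Low"`, `"Mid"`, `"High"` or `NA`.
#' @slot nTilesUsed integer count of tiles entering the prediction.
#' @slot timings named numeric vector of per-stage wall times (seconds).
#' @export
setClass("DeviceResult",
  representation(slideId = "character", status = "character",
                 errorMessage = "character", likelihood = "numeric",
                 call = "character", tier = "character",
                 nTilesUsed = "integer", timings = "numeric"),
  prototype(slideId = NA_character_, status = "error",
            errorMessage = NA_character_, likelihood = NA_real_,
            call = NA_character_, tier = NA_character_,
            nTilesUsed = 0L, timings = numeric()),
  validity = function(object) {
    msg <- character()
    if (!object@status %in% c("ok", "error"))
      msg <- c(msg, "status must be 'ok' or 'error'")
    if (object@status == "error" && is.na(object@errorMessage))
      msg <- c(msg, "error status requires an error message")
    if (object@status == "ok" && !is.na(object@errorMessage))
      msg <- c(msg, "ok status must not carry an error message")
    if (object@status == "ok" && object@nTilesUsed < 1L)
      msg <- c(msg, "ok status requires >= 1 tile used")
    if (length(msg)) msg else TRUE
  })
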