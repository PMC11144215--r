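#' Slide dimensions at a requested magnification
#'
#' @param x a [SlideImage-class].
#' @param ... further arguments for methods.
#' @return integer vector `c(width_px, height_px)`.
#' @export
setGeneric("slideDims", function(x, ...) standardGeneric("slideDims"))

#' Slide pixel raster at a requested magnification
#'
#' @param x a [SlideImage-class].
#' @param magnification one of `"10x"`, `"20x"`, `"40x"`.
#' @param ... further arguments for methods.
#' @return `height x width x 3` numeric array in `[0, 1]`.
#' @export
setGeneric("slidePixels",
           function(x, magnification = "10x", ...) standardGeneric("slidePixels"))

#' @rdname SlideImage-class
#' @param x a [SlideImage-class].
#' @export
setGeneric("slideId", function(x) standardGeneric("slideId"))

#' @rdname SlideImage-class
#' @export
setGeneric("baseMagnification",
           function(x) standardGeneric("baseMagnification"))

#' Number of tiles in a bag or prediction
#' @param x a [FeatureBag-class] or [SlidePrediction-class].
#' @export
setGeneric("nTiles", function(x) standardGeneric("nTiles"))

#' @rdname FeatureBag-class
#' @param x a [FeatureBag-class].
#' @export
setGeneric("bagFeatures", function(x) standardGeneric("bagFeatures"))

#' Tile reference table of a bag or prediction
#' @param x a [FeatureBag-class] or [SlidePrediction-class].
#' @export
setGeneric("tileRefs", function(x) standardGeneric("tileRefs"))

#' @rdname SlidePrediction-class
#' @param x a [SlidePrediction-class].
#' @export
setGeneric("likelihood", function(x) standardGeneric("likelihood"))

#' @rdname SlidePrediction-class
#' @export
setGeneric("attentionWeights",
           function(x) standardGeneric("attentionWeights"))

setMethod("slideDims", "SlideImage", function(x, magnification = NULL) {
  d <- dim(x@pixels)
  if (is.null(magnification) || magnification == x@baseMagnification)
    return(c(width_px = d[2], height_px = d[1]))
  f <- magFactor(x@baseMagnification) / magFactor(magnification)
  c(width_px = floor(d[2] / f), height_px = floor(d[1] / f))
})

setMethod("slidePixels", "SlideImage", function(x, magnification = "10x", ...) {
  if (magnification == x@baseMagnification) return(x@pixels)
  f <- magFactor(x@baseMagnification) / magFactor(magnification)
  if (f < 1)
    stop("magnification ", magnification, " exceeds base level ",
         x@baseMagnification)
  downsampleArea(x@pixels, as.integer(f))
})

setMethod("slideId", "SlideImage", function(x) x@slideId)
setMethod("baseMagnification", "SlideImage", function(x) x@baseMagnification)

setMethod("show", "SlideImage", function(object) {
  d <- dim(object@pixels)
  cat("SlideImage '", object@slideId, "': ", d[2], " x ", d[1],
      " px at ", object@baseMagnification, "\n", sep = "")
})

setMethod("nTiles", "FeatureBag", function(x) nrow(x@features))
setMethod("nTiles", "SlidePrediction", function(x) length(x@attentionWeights))
setMethod("bagFeatures", "FeatureBag", function(x) x@features)
setMethod("tileRefs", "FeatureBag", function(x) x@tiles)
setMethod("tileRefs", "SlidePrediction", function(x) x@tiles)
setMethod("likelihood", "SlidePrediction", function(x) x@likelihood)
setMethod("attentionWeights", "SlidePrediction", function(x) x@attentionWeights)

setMethod("show", "FeatureBag", function(object) {
  cat("FeatureBag:", nrow(object@features), "tiles x",
      ncol(object@features), "features\n")
})

setMethod("show", "SlidePrediction", function(object) {
  cat("SlidePrediction: likelihood ", round(object@likelihood, 4),
      " over ", length(object@attentionWeights), " tiles\n", sep = "")
})

setMethod("show", "MILModel", function(object) {
  cat("MILModel: attention hidden_dim ", nrow(object@params$V),
      ", backbone '", object@backbone$name, "', threshold ",
      object@threshold, "\n", sep = "")
})

setMethod("show", "DeviceResult", function(object) {
  if (object@status == "ok")
    cat("DeviceResult[", object@slideId, "]: ok, likelihood ",
        round(object@likelihood, 4), ", call ", object@call,
        if (!is.na(object@tier)) paste0(", tier ", object@tier) else "",
        ", tiles ", object@nTilesUsed, "\n", sep = "")
  else
    cat("DeviceResult[", object@slideId, "]: error: ",
        object@errorMessage, "\n", sep = "")
})

magFactor <- function(m) switch(m, "10x" = 1, "20x" = 2, "40x" = 4,
                                stop("unknown magnification: ", m))

## Area-averaged integer-factor downsampling of an H x W x 3 array.
downsampleArea <- function(px, f) {
  if (f == 1L) return(px)
  d <- dim(px)
  h <- (d[1] %/% f) * f
  w <- (d[2] %/% f) * f
  out <- array(0, c(h %/% f, w %/% f, 3))
  for (ch in 1:3) {
    m <- px[seq_len(h), seq_len(w), ch]
    m <- colMeans(array(m, c(f, h %/% f, w)))       # average row blocks
    m <- colMeans(array(t(m), c(f, w %/% f, h %/% f)))
    out[, , ch] <- t(m)
  }
  out
}
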