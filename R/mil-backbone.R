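## Tile feature extraction.
##
## The backbone contract is any map from a 224 x 224 RGB tile to a
## 512-vector. The default backbone is frozen: a handcrafted morphology +
## color descriptor (connected purple-blob statistics, HSV and channel
## moments, edge density) followed by a seeded random Gaussian projection
## to 512 dimensions. Freezing the backbone and training only the
## attention network and classifier head on the resulting bags is the
## precomputed-embedding variant of attention MIL; it mirrors the
## transfer-learning role the pretrained convolutional trunk plays at
## production scale while keeping the whole loop fast and deterministic
## on one CPU.

#' Construct a tile feature backbone
#'
#' @param name `"morphology"` (the default frozen descriptor backbone).
#' @param seed seed for the fixed random projection.
#' @param pool integer downsampling factor applied to the tile before
#'   descriptor computation (default 4: 224 -> 56).
#' @return a list with fields `name`, `dim` (512) and internals; pass to
#'   [extractFeatures()].
#' @export
milBackbone <- function(name = "morphology", seed = 202L, pool = 4L) {
  if (name != "morphology") stop("unknown backbone: ", name)
  ndesc <- 26L
  P <- withSeed(seed, matrix(rnorm(512L * ndesc), 512L, ndesc)) /
    sqrt(ndesc)
  list(name = name, dim = 512L, ndesc = ndesc, P = P, pool = as.integer(pool))
}

## 26-number descriptor of one tile (array in [0,1]).
tileDescriptor <- function(tile, pool = 4L) {
  if (pool > 1L) tile <- downsampleArea(tile, pool)
  r <- tile[, , 1]; g <- tile[, , 2]; b <- tile[, , 3]
  hsv <- rgbToHsv(as.vector(r), as.vector(g), as.vector(b))
  blob <- matrix(hsv$h >= 230 & hsv$h <= 310 & hsv$s > 0.3 & hsv$v < 0.7,
                 nrow(tile))
  areas <- if (any(blob)) {
    lab <- EBImage::bwlabel(blob)
    tabulate(lab[lab > 0])
  } else integer(0)
  nb <- length(areas)
  tot <- sum(areas)
  if (nb == 0L) tot <- 0L
  npx <- length(r)
  gx <- abs(r[, -1] - r[, -ncol(r)])
  gy <- abs(r[-1, ] - r[-nrow(r), ])
  c(log1p(nb),
    tot / npx,
    if (nb) max(areas) / npx else 0,
    if (nb) max(areas) / tot else 0,           # compactness share
    if (nb) log1p(mean(areas)) else 0,
    if (nb > 1) sd(areas) / mean(areas) else 0,
    mean(r), mean(g), mean(b), sd(r), sd(g), sd(b),
    mean(sin(hsv$h * pi / 180)), mean(cos(hsv$h * pi / 180)),
    mean(hsv$s), sd(hsv$s), mean(hsv$v), sd(hsv$v),
    as.numeric(stats::quantile(hsv$v, c(0.1, 0.5, 0.9))),
    mean(gx), mean(gy),
    mean(hsv$s > 0.3), mean(hsv$v < 0.5),
    mean(blob))
}

#' Extract an N x 512 feature bag from tiles
#'
#' @param tiles list of `224 x 224 x 3` arrays (or any equal-size RGB
#'   tiles).
#' @param backbone a [milBackbone()].
#' @param tile_refs optional data.frame of tile references aligned with
#'   `tiles` (columns `x`, `y`, `size`); a default grid index is used
#'   when absent.
#' @return a [FeatureBag-class].
#' @export
extractFeatures <- function(tiles, backbone = milBackbone(),
                            tile_refs = NULL) {
  if (length(tiles) == 0L)
    stop("empty tile list: no tiles to embed")
  desc <- vapply(tiles, tileDescriptor, numeric(backbone$ndesc),
                 pool = backbone$pool)
  feats <- t(backbone$P %*% desc)      # N x 512
  if (is.null(tile_refs))
    tile_refs <- data.frame(slide_id = NA_character_,
                            x = seq_along(tiles) - 1L, y = 0L,
                            size = dim(tiles[[1]])[1])
  new("FeatureBag", features = feats, tiles = tile_refs)
}

#' Bags for every slide of a manifest
#'
#' Reads each slide, runs tile QC, keeps passing tiles and embeds them.
#' Slides with no passing tiles are skipped with a warning.
#'
#' @param manifest data.frame with `slide_id`, `file_path`, `label`.
#' @param backbone a [milBackbone()].
#' @param threshold QC pass threshold (default 0.75).
#' @return list with `bags` (list of [FeatureBag-class]), `labels`
#'   (character vector aligned with `bags`) and `skipped` (slide ids).
#' @export
bagsFromManifest <- function(manifest, backbone = milBackbone(),
                             threshold = 0.75) {
  bags <- list(); labels <- character(); skipped <- character()
  for (i in seq_len(nrow(manifest))) {
    slide <- readSlide(manifest$file_path[i])
    rec <- scoreTiles(slide)
    kept <- tryCatch(filterTiles(rec, threshold),
                     histoscreen_qc_failure = function(e) NULL)
    if (is.null(kept)) {
      warning("slide ", manifest$slide_id[i],
              " skipped: no tiles passed QC", call. = FALSE)
      skipped <- c(skipped, manifest$slide_id[i])
      next
    }
    px <- slidePixels(slide, "10x")
    tiles <- lapply(seq_len(nrow(kept)), function(j)
      px[kept$y[j] + seq_len(TILE_SIZE), kept$x[j] + seq_len(TILE_SIZE), ,
         drop = FALSE])
    refs <- data.frame(slide_id = manifest$slide_id[i], x = kept$x,
                       y = kept$y, size = TILE_SIZE)
    bags[[length(bags) + 1L]] <- extractFeatures(tiles, backbone, refs)
    labels <- c(labels, manifest$label[i])
  }
  list(bags = bags, labels = labels, skipped = skipped)
}
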