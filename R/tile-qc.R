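## Tile-level quality control: slide reading, thumbnail, pen/background
## masks, tile grid, quality factors, the QC score and the score filter.
##
## The pen and gray rules, the hue arc behind color_factor and the
## saturation_factor definition are reconstructions of the open-source
## helper-function semantics the device builds on; the exact production
## constants are not public, so these choices are documented here and in
## the methods vignette and are not claimed to be bit-compatible with any
## deployed system. All constants live in `qcConfig()`.

## Device error strings (fixed contract; note the en dash).
ERR_TISSUE_SITE <- "Non-qualifying tissue site."
ERR_DISEASE_STAGE <- "Non-qualifying disease stage."
ERR_MISSING_FILE <- "Unsupported or missing image file."
ERR_CORRUPT_FILE <- "Corrupted image file."
ERR_MAGNIFICATION <- "Required magnification unavailable."
ERR_QC_FAILURE <- "QC Failure – Insufficient tissue tiles."

#' Fixed strings returned by the device on rejected inputs
#'
#' @return named character vector of the six device error messages.
#' @export
deviceErrorMessages <- function() {
  c(tissue_site = ERR_TISSUE_SITE, disease_stage = ERR_DISEASE_STAGE,
    missing_file = ERR_MISSING_FILE, corrupt_file = ERR_CORRUPT_FILE,
    magnification = ERR_MAGNIFICATION, qc_failure = ERR_QC_FAILURE)
}

#' Quality-control configuration constants
#'
#' One block holding every reconstructed QC constant: the gray tolerance,
#' the relational pen-color rules, the purple-pink hue arc, the
#' quantity-factor bins and the pass threshold.
#'
#' @return a list of constants used by the QC operators.
#' @export
qcConfig <- function() {
  list(
    gray_tolerance = 15,          # max pairwise channel difference, 0-255
    hue_arc = c(250, 350),        # purple-pink H&E band, degrees
    color_scale = 22.5,           # degrees of hue distance per factor unit
    score_threshold = 0.75,
    quantity_bins = c(none = 0, scant = 0.1, partial = 0.2, full = 1),
    ## relational pen rules on the 0-255 scale: each row fires when
    ## r OP r_thr & g OP g_thr & b OP b_thr with the ops fixed per color
    red_pen = rbind(c(150, 80, 90), c(110, 20, 30), c(185, 65, 105),
                    c(195, 85, 125), c(220, 115, 145), c(125, 40, 70),
                    c(200, 120, 150), c(100, 50, 65)),
    green_pen = rbind(c(150, 160, 140), c(70, 110, 110), c(45, 115, 100),
                      c(30, 75, 60), c(195, 220, 210), c(170, 210, 200),
                      c(50, 60, 40), c(100, 110, 105), c(30, 50, 35)),
    blue_pen = rbind(c(60, 120, 190), c(120, 170, 200), c(175, 210, 230),
                     c(145, 180, 210), c(37, 95, 160), c(30, 65, 130),
                     c(130, 155, 180), c(90, 60, 120), c(60, 34, 115))
  )
}

#' Read a slide image from disk
#'
#' Reads an 8-bit RGB TIFF (or PNG) raster into a [SlideImage-class].
#' Error messages follow the device contract: a missing path or
#' unsupported extension yields "Unsupported or missing image file.", an
#' unreadable/truncated file "Corrupted image file.", and a slide whose
#' level inventory cannot supply 10x "Required magnification unavailable."
#'
#' @param path file path (`.tif`/`.tiff`/`.png`).
#' @param base_magnification magnification of the stored raster
#'   (`"10x"`, `"20x"`, `"40x"`). Synthetic slides are written at 10x.
#' @param allow_resample if TRUE (default), 20x/40x rasters are
#'   area-average downsampled to provide the 10x level; if FALSE a
#'   non-10x slide raises the magnification error.
#' @return a [SlideImage-class].
#' @export
readSlide <- function(path, base_magnification = "10x",
                      allow_resample = TRUE) {
  if (length(path) != 1L || is.na(path) || !nzchar(path) ||
      !file.exists(path))
    stop(ERR_MISSING_FILE, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("tif", "tiff", "png"))
    stop(ERR_MISSING_FILE, call. = FALSE)
  px <- tryCatch({
    if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  }, error = function(e) stop(ERR_CORRUPT_FILE, call. = FALSE))
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  if (!base_magnification %in% c("10x", "20x", "40x"))
    stop(ERR_MAGNIFICATION, call. = FALSE)
  if (base_magnification != "10x" && !allow_resample)
    stop(ERR_MAGNIFICATION, call. = FALSE)
  slide <- new("SlideImage", pixels = px,
               slideId = tools::file_path_sans_ext(basename(path)),
               baseMagnification = base_magnification)
  if (base_magnification != "10x") {
    px10 <- slidePixels(slide, "10x")
    slide <- new("SlideImage", pixels = px10,
                 slideId = slide@slideId, baseMagnification = "10x")
  }
  slide
}

#' Low-resolution thumbnail by block averaging
#'
#' @param slide a [SlideImage-class] or `H x W x 3` array.
#' @param scale_divisor integer >= 1; output dimensions are
#'   `ceiling(original / scale_divisor)` (partial edge blocks averaged
#'   over their actual extent, preserving aspect ratio).
#' @return `ceil(H/d) x ceil(W/d) x 3` numeric array.
#' @export
computeThumbnail <- function(slide, scale_divisor = 32L) {
  px <- if (is(slide, "SlideImage")) slide@pixels else slide
  d <- as.integer(scale_divisor)
  if (d < 1L) stop("scale_divisor must be >= 1")
  if (d == 1L) return(px)
  dims <- dim(px)
  gr <- ceiling(seq_len(dims[1]) / d)
  gc <- ceiling(seq_len(dims[2]) / d)
  nr <- max(gr); nc <- max(gc)
  out <- array(0, c(nr, nc, 3))
  crow <- tabulate(gr, nr); ccol <- tabulate(gc, nc)
  for (ch in 1:3) {
    m <- rowsum(px[, , ch], gr, reorder = TRUE)
    m <- t(rowsum(t(m), gc, reorder = TRUE))
    out[, , ch] <- m / outer(crow, ccol)
  }
  out
}

#' Pen-mark and background binary masks
#'
#' The pen mask fires where any relational red/green/blue pen rule holds
#' (e.g. green pen: green channel high while red is low, over several
#' threshold pairs); the background mask fires where all pairwise channel
#' differences are within the gray tolerance. Both operators are
#' deterministic and idempotent.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param config constants from [qcConfig()].
#' @return list with logical matrices `pen_mask`, `background_mask`.
#' @export
penAndBackgroundMasks <- function(image, config = qcConfig()) {
  r <- image[, , 1] * 255; g <- image[, , 2] * 255; b <- image[, , 3] * 255
  pen <- matrix(FALSE, nrow(r), ncol(r))
  for (i in seq_len(nrow(config$red_pen))) {
    t <- config$red_pen[i, ]
    pen <- pen | (r > t[1] & g < t[2] & b < t[3])
  }
  for (i in seq_len(nrow(config$green_pen))) {
    t <- config$green_pen[i, ]
    pen <- pen | (r < t[1] & g > t[2] & b < t[3])
  }
  for (i in seq_len(nrow(config$blue_pen))) {
    t <- config$blue_pen[i, ]
    pen <- pen | (r < t[1] & g < t[2] & b > t[3])
  }
  tol <- config$gray_tolerance
  bg <- abs(r - g) <= tol & abs(g - b) <= tol & abs(r - b) <= tol
  list(pen_mask = pen, background_mask = bg)
}

#' Non-overlapping tile grid locations
#'
#' Row-major grid of `tile_size` squares; partial edge tiles are dropped.
#' Coordinates are 0-based pixel offsets at the 10x reference scale.
#'
#' @param width_px,height_px slide dimensions.
#' @param tile_size tile side in pixels (default 224).
#' @return data.frame with columns `x`, `y`, `size` (possibly 0 rows).
#' @export
tileLocations <- function(width_px, height_px, tile_size = TILE_SIZE) {
  stopifnot(tile_size >= 1)
  nx <- width_px %/% tile_size
  ny <- height_px %/% tile_size
  if (nx < 1 || ny < 1)
    return(data.frame(x = integer(), y = integer(), size = integer()))
  data.frame(x = rep((seq_len(nx) - 1L) * tile_size, ny),
             y = rep((seq_len(ny) - 1L) * tile_size, each = nx),
             size = as.integer(tile_size))
}

#' Per-tile quality factors
#'
#' `tissue_percent` is 100 x the fraction of tile pixels that are neither
#' pen nor background (pen pixels are excluded from tissue before
#' binning). `quantity_factor` bins tissue_percent: 0 -> 0.0, (0,10) ->
#' 0.1, [10,80) -> 0.2, [80,100] -> 1.0. `color_factor` measures how
#' close tissue hues sit to the purple-pink H&E arc (larger is closer);
#' `saturation_factor` is the mean of HSV saturation and value over
#' tissue pixels (washed-out tiles score low). Both are 0 when the tile
#' has no tissue.
#'
#' @param tile `s x s x 3` array in `[0, 1]`.
#' @param pen_mask,background_mask logical matrices covering the tile.
#' @param config constants from [qcConfig()].
#' @return list with `tissue_percent`, `quantity_factor`, `color_factor`,
#'   `saturation_factor`.
#' @export
tileQualityFactors <- function(tile, pen_mask, background_mask,
                               config = qcConfig()) {
  stopifnot(all(dim(pen_mask) == dim(tile)[1:2]),
            all(dim(background_mask) == dim(tile)[1:2]))
  tissue <- !(pen_mask | background_mask)
  tissue_percent <- 100 * mean(tissue)
  bins <- config$quantity_bins
  quantity_factor <- if (tissue_percent == 0) bins[["none"]]
    else if (tissue_percent < 10) bins[["scant"]]
    else if (tissue_percent < 80) bins[["partial"]]
    else bins[["full"]]
  if (!any(tissue))
    return(list(tissue_percent = 0, quantity_factor = bins[["none"]],
                color_factor = 0, saturation_factor = 0))
  r <- tile[, , 1][tissue]; g <- tile[, , 2][tissue]; b <- tile[, , 3][tissue]
  hsv <- rgbToHsv(r, g, b)
  d <- hueArcDistance(hsv$h, config$hue_arc)
  color_factor <- max(0, (90 - mean(d)) / config$color_scale)
  saturation_factor <- max(0, mean((hsv$s + hsv$v) / 2))
  list(tissue_percent = tissue_percent, quantity_factor = quantity_factor,
       color_factor = color_factor, saturation_factor = saturation_factor)
}

## Circular distance (degrees) from hues to the closed arc [a1, a2].
hueArcDistance <- function(h, arc) {
  inside <- h >= arc[1] & h <= arc[2]
  d1 <- pmin(abs(h - arc[1]), 360 - abs(h - arc[1]))
  d2 <- pmin(abs(h - arc[2]), 360 - abs(h - arc[2]))
  ifelse(inside, 0, pmin(d1, d2))
}

#' Tile QC score
#'
#' Evaluates
#' `score = 1 - 10 / (10 + tissue_percent^2 * ln(1 + color_factor *
#' saturation_factor * quantity_factor) / 100)`
#' with the natural logarithm. The score lies in `[0, 1)` and is monotone
#' non-decreasing in each argument; it is 0 whenever `tissue_percent` is
#' 0 or the factor product is 0.
#'
#' @param tissue_percent in `[0, 100]`.
#' @param color_factor,saturation_factor,quantity_factor non-negative.
#' @return score in `[0, 1)`.
#' @examples
#' qcScore(100, exp(1) - 1, 1, 1)  # 1 - 10/110
#' @export
qcScore <- function(tissue_percent, color_factor, saturation_factor,
                    quantity_factor) {
  if (any(tissue_percent < 0 | tissue_percent > 100))
    stop("tissue_percent must lie in [0, 100]")
  if (any(color_factor < 0) || any(saturation_factor < 0) ||
      any(quantity_factor < 0))
    stop("quality factors must be non-negative")
  x <- tissue_percent^2 *
    log(1 + color_factor * saturation_factor * quantity_factor) / 100
  1 - 10 / (10 + x)
}

#' Score every tile of a slide
#'
#' Computes masks at thumbnail scale (divisor `thumb_divisor`),
#' nearest-neighbor upsamples them to tile coordinates, then evaluates
#' the quality factors and QC score for each grid tile.
#'
#' @param slide a [SlideImage-class].
#' @param tile_size tile side (default 224).
#' @param thumb_divisor thumbnail divisor for mask computation
#'   (default 32).
#' @param config constants from [qcConfig()].
#' @return data.frame (one row per tile): `slide_id`, `x`, `y`,
#'   `tissue_percent`, `quantity_factor`, `color_factor`,
#'   `saturation_factor`, `score`, `passed`.
#' @export
scoreTiles <- function(slide, tile_size = TILE_SIZE, thumb_divisor = 32L,
                       config = qcConfig()) {
  px <- slidePixels(slide, "10x")
  thumb <- computeThumbnail(px, thumb_divisor)
  masks <- penAndBackgroundMasks(thumb, config)
  ## nearest-neighbor upsample back to full resolution
  ri <- ceiling(seq_len(dim(px)[1]) / thumb_divisor)
  ci <- ceiling(seq_len(dim(px)[2]) / thumb_divisor)
  pen <- masks$pen_mask[ri, ci, drop = FALSE]
  bg <- masks$background_mask[ri, ci, drop = FALSE]
  locs <- tileLocations(dim(px)[2], dim(px)[1], tile_size)
  if (nrow(locs) == 0L)
    return(cbind(data.frame(slide_id = character()), locs[, 1:2],
                 tissue_percent = numeric(), quantity_factor = numeric(),
                 color_factor = numeric(), saturation_factor = numeric(),
                 score = numeric(), passed = logical()))
  out <- vector("list", nrow(locs))
  for (i in seq_len(nrow(locs))) {
    rr <- locs$y[i] + seq_len(tile_size)
    cc <- locs$x[i] + seq_len(tile_size)
    f <- tileQualityFactors(px[rr, cc, , drop = FALSE],
                            pen[rr, cc, drop = FALSE],
                            bg[rr, cc, drop = FALSE], config)
    out[[i]] <- data.frame(slide_id = slideId(slide), x = locs$x[i],
                           y = locs$y[i],
                           tissue_percent = f$tissue_percent,
                           quantity_factor = f$quantity_factor,
                           color_factor = f$color_factor,
                           saturation_factor = f$saturation_factor)
  }
  rec <- do.call(rbind, out)
  rec$score <- qcScore(rec$tissue_percent, rec$color_factor,
                       rec$saturation_factor, rec$quantity_factor)
  rec$passed <- rec$score > config$score_threshold
  rec
}

#' Keep tiles whose QC score strictly exceeds the threshold
#'
#' Preserves input order. If no tile survives, signals a classed
#' condition (`histoscreen_qc_failure`) whose message is the device's
#' exact QC-failure string.
#'
#' @param records data.frame from [scoreTiles()] (needs a `score`
#'   column).
#' @param threshold pass threshold (default 0.75, strict `>`).
#' @return the kept rows of `records`.
#' @export
filterTiles <- function(records, threshold = 0.75) {
  kept <- records[records$score > threshold, , drop = FALSE]
  if (nrow(kept) < 1L)
    stop(structure(class = c("histoscreen_qc_failure", "error", "condition"),
                   list(message = ERR_QC_FAILURE, call = NULL)))
  kept
}
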