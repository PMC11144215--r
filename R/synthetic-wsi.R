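## Synthetic H&E-like slide generation.
##
## Tiles are 224 x 224 RGB rasters at a nominal 10x reference scale.
## Tissue hues are drawn in HSV around the hematoxylin-purple and
## eosin-pink centers so the QC color/saturation factors respond as on
## real H&E: purple nuclei/nests H ~ 265-295 deg (S .45-.70, V .35-.60),
## pink stroma H ~ 330-350 deg (S .25-.45, V .75-.90).

TILE_SIZE <- 224L

#' Synthetic slide specification
#'
#' Describes one synthetic H&E-like slide: its label, pixel dimensions at
#' the 10x reference scale, the fraction of tissue tiles carrying the
#' class morphology, artifact rates and the RNG seed. Identical spec +
#' seed yields byte-identical output.
#'
#' @param slide_id character identifier.
#' @param label `"positive"` or `"negative"`.
#' @param width_px,height_px slide dimensions in pixels (>= 224).
#' @param signal_fraction fraction of tissue tiles rendered with the
#'   class morphology on positive slides, in `[0, 1]`.
#' @param pen_fraction,blur_fraction,background_fraction artifact rates,
#'   each in `[0, 1]` (`background_fraction` is the fraction of all tiles;
#'   pen/blur are fractions of tissue tiles).
#' @param seed integer RNG seed.
#' @return a `"SyntheticSlideSpec"` list.
#' @examples
#' sp <- syntheticSlideSpec("s1", "positive", 672, 672, seed = 1)
#' @export
syntheticSlideSpec <- function(slide_id, label = c("negative", "positive"),
                               width_px = 896L, height_px = 896L,
                               signal_fraction = 0.5, pen_fraction = 0,
                               blur_fraction = 0, background_fraction = 0.25,
                               seed = 1L) {
  label <- match.arg(label)
  fr <- c(signal_fraction, pen_fraction, blur_fraction, background_fraction)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (width_px < TILE_SIZE || height_px < TILE_SIZE)
    stop("slide dimensions must be at least one tile (", TILE_SIZE, " px)")
  structure(list(slide_id = slide_id, label = label,
                 width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 signal_fraction = signal_fraction,
                 pen_fraction = pen_fraction, blur_fraction = blur_fraction,
                 background_fraction = background_fraction,
                 seed = as.integer(seed)),
            class = "SyntheticSlideSpec")
}

#' Generate one synthetic 224x224 H&E-like tile
#'
#' Five texture kinds are available: `solid_nest` (few large compact
#' purple blob clusters on pink stroma, the positive-class morphology),
#' `dispersed` (many small scattered purple blobs, the negative-class
#' morphology), `background` (near-uniform light gray), `pen_mark`
#' (tissue overdrawn with a saturated red, green or blue stroke) and
#' `blurred_tissue` (tissue convolved with a wide Gaussian kernel).
#'
#' @param kind one of `"solid_nest"`, `"dispersed"`, `"background"`,
#'   `"pen_mark"`, `"blurred_tissue"`.
#' @param seed integer seed; identical (kind, seed) gives identical pixels.
#' @return `224 x 224 x 3` numeric array on the 8-bit grid `k/255`.
#' @examples
#' t1 <- generateTileTexture("solid_nest", seed = 1)
#' @export
generateTileTexture <- function(kind, seed = 1L) {
  kinds <- c("solid_nest", "dispersed", "background", "pen_mark",
             "blurred_tissue")
  if (length(kind) != 1L || !kind %in% kinds)
    stop("unknown tile kind: ", paste(kind, collapse = ","),
         " (expected one of ", paste(kinds, collapse = ", "), ")")
  withSeed(seed, {
    n <- TILE_SIZE
    tile <- switch(kind,
      background = {
        g <- matrix(0.92 + 0.01 * matrix(rnorm(n * n), n), n)
        array(rep(g, 3), c(n, n, 3))  # equal channels: gray by construction
      },
      solid_nest = drawTissue(n, n_blobs = sample(3:5, 1),
                              radius_range = c(34, 55)),
      dispersed = drawTissue(n, n_blobs = sample(90:140, 1),
                             radius_range = c(3, 7)),
      pen_mark = drawPen(drawTissue(n, n_blobs = sample(90:140, 1),
                                    radius_range = c(3, 7))),
      blurred_tissue = {
        t0 <- drawTissue(n, n_blobs = sample(90:140, 1),
                         radius_range = c(3, 7))
        img <- EBImage::Image(aperm(t0, c(2, 1, 3)), colormode = "Color")
        b <- EBImage::gblur(img, sigma = 8)
        aperm(EBImage::imageData(b), c(2, 1, 3))
      })
    quantize8(tile)
  })
}

## Pink eosin stroma with purple hematoxylin blobs; n x n x 3 in [0,1].
drawTissue <- function(n, n_blobs, radius_range) {
  hs <- rgbGridHsv(n)
  ## stroma: pink
  h <- matrix(runif(1, 330, 350) + 3 * matrix(rnorm(n * n), n), n)
  s <- matrix(runif(1, 0.28, 0.42) + 0.03 * matrix(rnorm(n * n), n), n)
  v <- matrix(runif(1, 0.78, 0.88) + 0.03 * matrix(rnorm(n * n), n), n)
  ## blobs: purple, slightly irregular disks
  xs <- runif(n_blobs, 1, n); ys <- runif(n_blobs, 1, n)
  rad <- runif(n_blobs, radius_range[1], radius_range[2])
  inside <- matrix(FALSE, n, n)
  for (i in seq_len(n_blobs)) {
    ## work inside the blob's bounding box only
    r2 <- ceiling(rad[i] * 1.15)
    rows <- max(1, floor(ys[i]) - r2):min(n, ceiling(ys[i]) + r2)
    cols <- max(1, floor(xs[i]) - r2):min(n, ceiling(xs[i]) + r2)
    cy <- matrix(rows, length(rows), length(cols))
    cx <- matrix(cols, length(rows), length(cols), byrow = TRUE)
    wob <- 1 + 0.15 * sin(atan2(cy - ys[i], cx - xs[i]) * sample(3:6, 1))
    hit <- (cx - xs[i])^2 + (cy - ys[i])^2 < (rad[i] * wob)^2
    inside[rows, cols] <- inside[rows, cols] | hit
  }
  h[inside] <- runif(1, 268, 292) + 4 * rnorm(sum(inside))
  s[inside] <- runif(1, 0.5, 0.65) + 0.04 * rnorm(sum(inside))
  v[inside] <- runif(1, 0.4, 0.55) + 0.04 * rnorm(sum(inside))
  rgb <- hsvToRgb(as.vector(h), pmin(pmax(as.vector(s), 0), 1),
                  pmin(pmax(as.vector(v), 0), 1))
  array(c(rgb$r, rgb$g, rgb$b), c(n, n, 3))
}

rgbGridHsv <- function(n) {
  cx <- matrix(rep(seq_len(n), each = n), n)   # column index
  cy <- matrix(rep(seq_len(n), n), n)          # row index
  list(cx = cx, cy = cy)
}

## Overdraw 2-3 thick saturated pen strokes (red / green / blue).
drawPen <- function(tile) {
  n <- nrow(tile)
  pens <- list(red = c(220, 40, 50) / 255,
               green = c(40, 200, 80) / 255,
               blue = c(40, 60, 220) / 255)
  col <- pens[[sample(3, 1)]]
  hs <- rgbGridHsv(n)
  n_strokes <- sample(2:3, 1)
  for (k in seq_len(n_strokes)) {
    x0 <- runif(1, 1, n); y0 <- runif(1, 1, n)
    ang <- runif(1, 0, pi)
    width <- runif(1, 5, 8)
    ## distance from the stroke's center line
    d <- abs(cos(ang) * (hs$cy - y0) - sin(ang) * (hs$cx - x0))
    hit <- d < width
    for (ch in 1:3) {
      m <- tile[, , ch]
      m[hit] <- col[ch]
      tile[, , ch] <- m
    }
  }
  tile
}

#' Generate a synthetic slide and its tile-level truth map
#'
#' Assembles a mosaic of 224-px tiles per the slide specification.
#' Background tiles fill
#' `background_fraction` of the grid; among the remaining tissue tiles,
#' positive slides carry `signal_fraction` of tiles as `solid_nest`
#' morphology (negative slides render all tissue as `dispersed`), and
#' pen/blur artifacts overwrite `pen_fraction` / `blur_fraction` of the
#' non-signal tissue tiles. Tile counts are exact after rounding.
#'
#' @param spec a [syntheticSlideSpec()].
#' @return list with `image` (`height x width x 3` array), `truth`
#'   (data.frame with `x`, `y`, `kind`, `is_signal`) and `spec`.
#' @examples
#' sl <- generateSlide(syntheticSlideSpec("s1", "positive", 448, 448, seed = 1))
#' @export
generateSlide <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSlideSpec"))
  nx <- spec$width_px %/% TILE_SIZE
  ny <- spec$height_px %/% TILE_SIZE
  if (nx < 1L || ny < 1L) stop("slide smaller than one tile")
  n_tiles <- nx * ny
  kinds <- withSeed(spec$seed, {
    n_bg <- round(spec$background_fraction * n_tiles)
    ord <- sample.int(n_tiles)
    kind <- rep("dispersed", n_tiles)
    bg_idx <- ord[seq_len(n_bg)]
    kind[bg_idx] <- "background"
    tissue_idx <- ord[setdiff(seq_len(n_tiles), seq_len(n_bg))]
    n_tissue <- length(tissue_idx)
    n_sig <- if (spec$label == "positive")
      round(spec$signal_fraction * n_tissue) else 0L
    sig_idx <- utils::head(tissue_idx, n_sig)
    kind[sig_idx] <- "solid_nest"
    rest <- setdiff(tissue_idx, sig_idx)
    n_pen <- min(round(spec$pen_fraction * n_tissue), length(rest))
    pen_idx <- utils::head(rest, n_pen)
    kind[pen_idx] <- "pen_mark"
    rest <- setdiff(rest, pen_idx)
    n_blur <- min(round(spec$blur_fraction * n_tissue), length(rest))
    kind[utils::head(rest, n_blur)] <- "blurred_tissue"
    kind
  })
  img <- array(0, c(ny * TILE_SIZE, nx * TILE_SIZE, 3))
  xs <- rep((seq_len(nx) - 1L) * TILE_SIZE, each = ny)
  ys <- rep((seq_len(ny) - 1L) * TILE_SIZE, nx)
  for (i in seq_len(n_tiles)) {
    tl <- generateTileTexture(kinds[i], seed = mixSeed(spec$seed, i))
    img[ys[i] + seq_len(TILE_SIZE), xs[i] + seq_len(TILE_SIZE), ] <- tl
  }
  truth <- data.frame(slide_id = spec$slide_id, x = xs, y = ys,
                      kind = kinds,
                      is_signal = kinds == "solid_nest",
                      stringsAsFactors = FALSE)
  list(image = img, truth = truth, spec = spec)
}

#' Write a synthetic slide to disk as an 8-bit RGB TIFF
#'
#' @param slide output of [generateSlide()].
#' @param dir output directory (created if absent).
#' @return invisibly, paths of the written TIFF and truth CSV.
#' @export
writeSlide <- function(slide, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  tif <- file.path(dir, paste0(slide$spec$slide_id, ".tif"))
  csv <- file.path(dir, paste0(slide$spec$slide_id, "_truth.csv"))
  tiff::writeTIFF(slide$image, tif, bits.per.sample = 8L)
  write.csv(slide$truth, csv, row.names = FALSE)
  invisible(c(image = tif, truth = csv))
}

#' Generate a labeled synthetic cohort with exact prevalence
#'
#' Writes `n_slides` slides plus a manifest CSV. Exactly
#' `round(n_slides * prevalence)` slides are positive (deterministic
#' stratified count, not Bernoulli draws); positive/negative positions in
#' the manifest are a seeded permutation. Per-slide seeds are derived by
#' hashing `(seed, slide_index)`.
#'
#' @param n_slides number of slides (>= 1).
#' @param prevalence fraction of positive slides in `[0, 1]`.
#' @param template a [syntheticSlideSpec()] supplying dimensions, signal
#'   fraction and artifact rates (its `slide_id`, `label`, `seed` are
#'   overridden per slide).
#' @param seed cohort seed.
#' @param dir output directory; slides are written here as TIFF.
#' @param cohort_name cohort label recorded in the manifest.
#' @param tissue_site,disease_stage metadata recorded per slide.
#' @return the manifest data.frame (also written to `manifest.csv` in
#'   `dir`) with columns `slide_id`, `file_path`, `tissue_site`,
#'   `disease_stage`, `label`, `cohort_name`.
#' @export
generateCohort <- function(n_slides, prevalence, template, seed, dir,
                           cohort_name = "synthetic",
                           tissue_site = "Bladder",
                           disease_stage = "MIBC") {
  stopifnot(n_slides >= 1, prevalence >= 0, prevalence <= 1)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  n_pos <- round(n_slides * prevalence)
  labels <- withSeed(seed, {
    lab <- rep("negative", n_slides)
    lab[sample.int(n_slides, n_pos)] <- "positive"
    lab
  })
  rows <- vector("list", n_slides)
  for (i in seq_len(n_slides)) {
    sp <- template
    sp$slide_id <- sprintf("%s_%03d", cohort_name, i)
    sp$label <- labels[i]
    sp$seed <- mixSeed(seed, i)
    paths <- writeSlide(generateSlide(sp), dir)
    rows[[i]] <- data.frame(slide_id = sp$slide_id,
                            file_path = unname(paths["image"]),
                            tissue_site = tissue_site,
                            disease_stage = disease_stage,
                            label = labels[i], cohort_name = cohort_name,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Blob-compactness statistic of a tile
#'
#' The generator's own morphology statistic: the fraction of all
#' purple-blob area belonging to the largest connected blob. Compact
#' solid-nest tiles score high; dispersed tiles score low. Used to verify
#' that the planted class signal is detectable.
#'
#' @param tile `224 x 224 x 3` array in `[0, 1]`.
#' @return numeric in `[0, 1]` (0 when no blob pixels are found).
#' @export
tileCompactness <- function(tile) {
  hsv <- rgbToHsv(as.vector(tile[, , 1]), as.vector(tile[, , 2]),
                  as.vector(tile[, , 3]))
  blob <- matrix(hsv$h >= 230 & hsv$h <= 310 & hsv$s > 0.3 & hsv$v < 0.7,
                 nrow(tile))
  if (!any(blob)) return(0)
  lab <- EBImage::bwlabel(blob)
  areas <- tabulate(lab[lab > 0])
  max(areas) / sum(areas)
}
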