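## End-to-end device orchestration: metadata gates, read checks, QC,
## inference, thresholding and the 3-tier assignment, with the fixed
## error-message contract.

#' Metadata qualification check
#'
#' The tissue site must normalize to "Bladder" and the disease stage to
#' "MIBC" (whitespace-trimmed, case-insensitive by default); the site is
#' checked before the stage. With `strict = TRUE` the comparison is the
#' literal string equality.
#'
#' @param tissue_site,disease_stage character scalars.
#' @param strict literal comparison instead of normalized (default
#'   FALSE).
#' @return `TRUE` on pass; otherwise the exact error string
#'   (`"Non-qualifying tissue site."` or
#'   `"Non-qualifying disease stage."`).
#' @export
checkMetadata <- function(tissue_site, disease_stage, strict = FALSE) {
  norm <- function(x) if (strict) x else tolower(trimws(x))
  if (!identical(norm(tissue_site), norm("Bladder")))
    return(ERR_TISSUE_SITE)
  if (!identical(norm(disease_stage), norm("MIBC")))
    return(ERR_DISEASE_STAGE)
  TRUE
}

#' Binarize a slide likelihood
#'
#' @param likelihood in `[0, 1]`.
#' @param threshold in `[0, 1]`; the boundary is inclusive: the call is
#'   `"FGFR+"` iff `likelihood >= threshold`.
#' @return `"FGFR+"` or `"FGFR-"`.
#' @export
binarizeLikelihood <- function(likelihood, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  ifelse(likelihood >= threshold, "FGFR+", "FGFR-")
}

#' 3-tier thresholds
#'
#' @param low_cut high-sensitivity operating threshold.
#' @param high_cut high-specificity operating threshold; must exceed
#'   `low_cut`.
#' @return list of class `"TierThresholds"`.
#' @export
tierThresholds <- function(low_cut, high_cut) {
  if (!(low_cut >= 0 && low_cut < high_cut && high_cut <= 1))
    stop("need 0 <= low_cut < high_cut <= 1")
  structure(list(low_cut = low_cut, high_cut = high_cut),
            class = "TierThresholds")
}

#' Assign the likelihood tier
#'
#' `Low` iff `likelihood < low_cut`; `High` iff
#' `likelihood >= high_cut` (boundary inclusive); `Mid` otherwise. The
#' three tiers partition `[0, 1]` and the tier is monotone in the
#' likelihood.
#'
#' @param likelihood in `[0, 1]`.
#' @param tiers a [tierThresholds()].
#' @return `"Low"`, `"Mid"` or `"High"`.
#' @export
assignTier <- function(likelihood, tiers) {
  ifelse(likelihood < tiers$low_cut, "Low",
         ifelse(likelihood >= tiers$high_cut, "High", "Mid"))
}

#' Run the full prescreening device on one slide
#'
#' Executes metadata check, slide read, masks, tile grid, QC scoring,
#' the score > threshold filter, feature extraction, attention pooling,
#' likelihood and binarization (plus tiering when thresholds are
#' supplied). The six fixed error messages propagate verbatim into the
#' result; any other failure raises a regular R error.
#'
#' @param wsi_path slide file path.
#' @param tissue_site,disease_stage slide metadata.
#' @param model a trained [MILModel-class].
#' @param threshold operating threshold; defaults to the model's stored
#'   threshold.
#' @param tiers optional [tierThresholds()].
#' @param base_magnification stored raster magnification.
#' @param allow_resample see [readSlide()].
#' @param strict_metadata literal metadata comparison.
#' @return a [DeviceResult-class].
#' @export
runDevice <- function(wsi_path, tissue_site, disease_stage, model,
                      threshold = NULL, tiers = NULL,
                      base_magnification = "10x", allow_resample = FALSE,
                      strict_metadata = FALSE) {
  slide_id <- if (length(wsi_path) == 1L && !is.na(wsi_path) &&
                  nzchar(wsi_path))
    tools::file_path_sans_ext(basename(wsi_path)) else NA_character_
  if (is.null(threshold)) threshold <- model@threshold
  if (is.na(threshold)) threshold <- 0.5
  fail <- function(msg) new("DeviceResult", slideId = slide_id,
                            status = "error", errorMessage = msg)
  md <- checkMetadata(tissue_site, disease_stage, strict = strict_metadata)
  if (!isTRUE(md)) return(fail(md))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  slide <- tryCatch(readSlide(wsi_path, base_magnification, allow_resample),
                    error = function(e) e)
  if (inherits(slide, "error")) {
    msg <- conditionMessage(slide)
    if (msg %in% deviceErrorMessages()) return(fail(msg))
    stop(slide)
  }
  timings["read"] <- tic() - t0; t0 <- tic()
  rec <- scoreTiles(slide, tile_size = model@config$tile_size)
  kept <- tryCatch(filterTiles(rec),
                   histoscreen_qc_failure = function(e) NULL)
  if (is.null(kept)) return(fail(ERR_QC_FAILURE))
  timings["qc"] <- tic() - t0; t0 <- tic()
  px <- slidePixels(slide, "10x")
  ts <- model@config$tile_size
  tiles <- lapply(seq_len(nrow(kept)), function(j)
    px[kept$y[j] + seq_len(ts), kept$x[j] + seq_len(ts), , drop = FALSE])
  refs <- data.frame(slide_id = slideId(slide), x = kept$x, y = kept$y,
                     size = ts)
  bag <- extractFeatures(tiles, model@backbone, refs)
  timings["features"] <- tic() - t0; t0 <- tic()
  pred <- predictSlide(bag, model)
  timings["inference"] <- tic() - t0
  new("DeviceResult", slideId = slide_id, status = "ok",
      errorMessage = NA_character_, likelihood = likelihood(pred),
      call = binarizeLikelihood(likelihood(pred), threshold),
      tier = if (!is.null(tiers))
        assignTier(likelihood(pred), tiers) else NA_character_,
      nTilesUsed = nTiles(pred), timings = timings)
}

#' Run the device over a cohort manifest
#'
#' @param manifest data.frame with `slide_id`, `file_path`,
#'   `tissue_site`, `disease_stage`.
#' @param model a trained [MILModel-class].
#' @param ... passed to [runDevice()].
#' @return list of [DeviceResult-class], one per manifest row.
#' @export
runDeviceBatch <- function(manifest, model, ...) {
  lapply(seq_len(nrow(manifest)), function(i)
    runDevice(manifest$file_path[i], manifest$tissue_site[i],
              manifest$disease_stage[i], model, ...))
}

#' Convert a DeviceResult to a plain list (JSON-ready)
#'
#' @param result a [DeviceResult-class].
#' @return named list with the result schema fields.
#' @export
deviceResultRecord <- function(result) {
  list(slide_id = result@slideId, status = result@status,
       error_message = result@errorMessage,
       likelihood = result@likelihood, call = result@call,
       tier = result@tier, n_tiles_used = result@nTilesUsed)
}
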