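## Training of the attention-MIL classifier on frozen feature bags, with
## hand-derived gradients, plus cross-validation splitting and model
## selection by PPV at the sensitivity target.

#' Inverse-frequency class weights
#'
#' `weight_c` is proportional to `1 / count_c`, normalized so the mean
#' weight is 1.
#'
#' @param labels character vector of `"positive"` / `"negative"`.
#' @return named numeric vector `c(negative = ..., positive = ...)`.
#' @export
classWeights <- function(labels) {
  cls <- c("negative", "positive")
  counts <- c(sum(labels == "negative"), sum(labels == "positive"))
  if (any(counts == 0))
    stop("both classes must be present to compute class weights")
  w <- 1 / counts
  w <- w / mean(w)
  setNames(w, cls)
}

#' Stratified hold-out and cross-validation split
#'
#' Within every (label x cohort) stratum, `round(holdout_fraction * n)`
#' slides go to the hold-out partition and the rest are dealt round-robin
#' into `n_folds` folds, so every partition preserves the class and
#' cohort mix to within one slide. A stratum smaller than `n_folds`
#' triggers a warning (its slides still receive fold labels).
#'
#' @param manifest data.frame with `slide_id`, `label`, `cohort_name`.
#' @param holdout_fraction default 0.15.
#' @param n_folds default 5.
#' @param seed RNG seed.
#' @return data.frame `slide_id`, `label`, `cohort_name`, `partition`
#'   (`"holdout"`/`"train"`), `fold` (integer, `NA` on hold-out rows).
#' @export
stratifiedSplits <- function(manifest, holdout_fraction = 0.15,
                             n_folds = 5L, seed = 1L) {
  stopifnot(holdout_fraction >= 0, holdout_fraction < 1, n_folds >= 1)
  out <- manifest[, c("slide_id", "label", "cohort_name")]
  out$partition <- "train"
  out$fold <- NA_integer_
  strata <- split(seq_len(nrow(out)),
                  paste(out$label, out$cohort_name, sep = "\r"))
  withSeed(seed, for (idx in strata) {
    n <- length(idx)
    if (n < n_folds)
      warning("stratum with ", n, " slides is smaller than n_folds = ",
              n_folds, call. = FALSE)
    idx <- idx[sample.int(n)]
    n_h <- round(holdout_fraction * n)
    hold <- idx[seq_len(n_h)]
    out$partition[hold] <- "holdout"
    rest <- idx[setdiff(seq_len(n), seq_len(n_h))]
    if (length(rest))
      out$fold[rest] <- rep(seq_len(n_folds), length.out = length(rest))
  })
  out
}

## One forward/backward pass for a single bag; returns loss and grads.
milStep <- function(H, y, params, cw, dropout, dropmask) {
  Tm <- tanh(H %*% t(params$V))
  s <- drop(Tm %*% params$w)
  a <- softmax1(s)
  z <- drop(crossprod(H, a))
  keep <- 1 - dropout
  zt <- z * dropmask / keep
  logits <- drop(params$W %*% zt + params$b)
  p <- softmax1(logits)
  wy <- cw[[y]]
  yi <- if (y == "positive") 2L else 1L
  loss <- -wy * log(max(p[yi], 1e-12))
  dl <- wy * p; dl[yi] <- dl[yi] - wy
  gW <- dl %o% zt
  gb <- dl
  dz <- drop(crossprod(params$W, dl)) * dropmask / keep
  da <- drop(H %*% dz)
  ds <- a * (da - sum(a * da))
  gw <- drop(crossprod(Tm, ds))
  dpre <- (ds %o% params$w) * (1 - Tm^2)
  gV <- crossprod(dpre, H)   # hidden x 512
  list(loss = loss, gV = gV, gw = gw, gW = gW, gb = gb,
       likelihood = p[2])
}

#' Train the attention-MIL classifier on feature bags
#'
#' Optimizes the class-weighted cross-entropy over slide bags by plain
#' stochastic gradient descent with weight decay, one slide-bag per
#' optimization step, dropout on the bag embedding, and all randomness
#' drawn from `config$seed`. Features are standardized with statistics
#' computed on the training bags and stored in the model. When
#' validation bags are supplied the parameters with the best validation
#' loss are kept (checkpointing); otherwise the final parameters are
#' returned.
#'
#' @param bags list of [FeatureBag-class] (training slides).
#' @param labels character vector (`"positive"`/`"negative"`) aligned
#'   with `bags`.
#' @param config a [milConfig()].
#' @param backbone the [milBackbone()] the bags were extracted with
#'   (stored in the model).
#' @param val_bags,val_labels optional validation bags for
#'   checkpointing.
#' @return list with `model` (a [MILModel-class]) and `log` (data.frame
#'   with per-epoch mean training loss and, when available, validation
#'   loss).
#' @export
trainMIL <- function(bags, labels, config = milConfig(),
                     backbone = milBackbone(), val_bags = NULL,
                     val_labels = NULL) {
  stopifnot(length(bags) == length(labels), length(bags) >= 2)
  if (length(unique(labels)) < 2)
    stop("need at least one slide per class")
  cw <- classWeights(labels)
  allH <- do.call(rbind, lapply(bags, bagFeatures))
  fstats <- list(center = colMeans(allH),
                 scale = pmax(apply(allH, 2, sd), 1e-8))
  Hs <- lapply(bags, function(b) standardizeBag(bagFeatures(b), fstats))
  Hv <- if (!is.null(val_bags))
    lapply(val_bags, function(b) standardizeBag(bagFeatures(b), fstats))
  params <- initMILParams(config$hidden_dim, config$seed)
  lr <- config$learning_rate; wd <- config$weight_decay
  n <- length(bags)
  log_rows <- vector("list", config$epochs)
  best <- list(loss = Inf, params = params)
  withSeed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(n)
      for (i in seq_along(ord)) {
        j <- ord[i]
        dropmask <- if (config$dropout > 0)
          as.numeric(runif(512L) >= config$dropout) else rep(1, 512L)
        st <- milStep(Hs[[j]], labels[j], params, cw, config$dropout,
                      dropmask)
        losses[i] <- st$loss
        params$V <- params$V - lr * (st$gV + wd * params$V)
        params$w <- params$w - lr * (st$gw + wd * params$w)
        params$W <- params$W - lr * (st$gW + wd * params$W)
        params$b <- params$b - lr * st$gb
      }
      vloss <- NA_real_
      if (!is.null(val_bags)) {
        vloss <- mean(vapply(seq_along(Hv), function(j) {
          st <- milStep(Hv[[j]], val_labels[j], params, cw, 0, rep(1, 512L))
          st$loss
        }, numeric(1)))
        if (vloss < best$loss) best <- list(loss = vloss, params = params)
      }
      log_rows[[ep]] <- data.frame(epoch = ep, train_loss = mean(losses),
                                   val_loss = vloss)
    }
  })
  final <- if (!is.null(val_bags) && is.finite(best$loss)) best$params
           else params
  model <- new("MILModel", backbone = backbone, params = final,
               featureStats = fstats, config = unclass(config),
               threshold = NA_real_)
  list(model = model, log = do.call(rbind, log_rows))
}

#' PPV at a sensitivity target for one score set
#'
#' Sets the threshold to the largest value achieving sensitivity at or
#' above the target (calls are positive when `score >= threshold`) and
#' computes the PPV there. If no threshold reaches the target the
#' maximal-sensitivity threshold is used and the result is flagged.
#'
#' @param scores numeric likelihoods.
#' @param labels `"positive"` / `"negative"` (or 1/0) truth.
#' @param target_sensitivity default 0.9.
#' @return list `threshold`, `sensitivity`, `specificity`, `ppv`,
#'   `flagged`.
#' @export
ppvAtSensitivity <- function(scores, labels, target_sensitivity = 0.9) {
  y <- as.integer(labels %in% c("positive", 1, TRUE))
  if (sum(y) == 0) stop("no positive samples")
  cand <- sort(unique(scores))
  stats_at <- function(t) {
    pred <- scores >= t
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    fn <- sum(!pred & y == 1); tn <- sum(!pred & y == 0)
    c(sens = tp / (tp + fn),
      spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  }
  st <- t(vapply(cand, stats_at, numeric(3)))
  ok <- which(st[, "sens"] >= target_sensitivity)
  flagged <- length(ok) == 0
  pick <- if (flagged) which.max(st[, "sens"]) else max(ok)
  list(threshold = cand[pick], sensitivity = unname(st[pick, "sens"]),
       specificity = unname(st[pick, "spec"]),
       ppv = unname(st[pick, "ppv"]), flagged = flagged)
}

#' Select the best model by PPV at the sensitivity target
#'
#' Each candidate carries cross-validation scores and truth labels. For
#' each, the threshold is the largest achieving sensitivity at or above
#' the target, PPV is computed there, and the candidate with the highest
#' PPV wins; ties break toward higher specificity, then lower candidate
#' index. The winning threshold is stored on the returned model when the
#' candidate's `model` is a [MILModel-class].
#'
#' @param candidates list of lists with fields `model`, `scores`,
#'   `labels`.
#' @param target_sensitivity default 0.9.
#' @return list `model`, `index`, `threshold`, `ppv`, `sensitivity`,
#'   `specificity`, `flagged`.
#' @export
selectModel <- function(candidates, target_sensitivity = 0.9) {
  stopifnot(length(candidates) >= 1)
  evals <- lapply(candidates, function(cd)
    ppvAtSensitivity(cd$scores, cd$labels, target_sensitivity))
  ppv <- vapply(evals, `[[`, numeric(1), "ppv")
  spec <- vapply(evals, `[[`, numeric(1), "specificity")
  ord <- order(-ppv, -spec, seq_along(evals))
  i <- ord[1]
  model <- candidates[[i]]$model
  if (is(model, "MILModel")) model@threshold <- evals[[i]]$threshold
  c(list(model = model, index = i), evals[[i]])
}

#' Attention heatmap raster
#'
#' Fills every tile footprint with its attention weight normalized by
#' the maximum weight (so values lie in `[0, 1]`, the top tile at 1);
#' non-tile area stays 0. Optionally writes a single-channel PNG.
#'
#' @param prediction a [SlidePrediction-class].
#' @param width_px,height_px slide dimensions at 10x.
#' @param file optional PNG output path.
#' @param downscale integer divisor for the written raster (default 8).
#' @return numeric matrix `height_px x width_px` (invisibly when `file`
#'   is given).
#' @export
attentionHeatmap <- function(prediction, width_px, height_px, file = NULL,
                             downscale = 8L) {
  w <- attentionWeights(prediction) / max(attentionWeights(prediction))
  tiles <- tileRefs(prediction)
  map <- matrix(0, height_px, width_px)
  for (i in seq_len(nrow(tiles))) {
    rr <- tiles$y[i] + seq_len(tiles$size[i])
    cc <- tiles$x[i] + seq_len(tiles$size[i])
    map[rr, cc] <- w[i]
  }
  if (!is.null(file)) {
    small <- map[seq(1, height_px, by = downscale),
                 seq(1, width_px, by = downscale), drop = FALSE]
    png::writePNG(small, file)
    return(invisible(map))
  }
  map
}
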