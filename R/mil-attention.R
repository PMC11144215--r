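## Attention-based multiple-instance pooling and the slide classifier.
##
## For a bag of tile embeddings h_1..h_N the attention weights are
##   a_k = softmax_k( w' tanh(V h_k) )
## (plain, non-gated attention) and the bag embedding is z = sum_k a_k h_k.
## A two-logit softmax head on z yields the slide-level likelihood
## (positive-class probability). Gradients for training are derived by
## hand in mil-train.R; no autodiff library is involved.

#' Training configuration for the attention-MIL classifier
#'
#' Defaults mirror the production-scale recipe (224-px tiles at 10x,
#' learning rate 1e-5, weight decay 1e-4, dropout 0.5, class-weighted
#' cross-entropy); desk-scale runs on the frozen descriptor backbone
#' typically raise the learning rate (see the vignette).
#'
#' @param tile_size tile side in pixels.
#' @param magnification working magnification.
#' @param learning_rate,weight_decay positive rates.
#' @param dropout dropout probability on the bag embedding, in `[0, 1)`.
#' @param epochs training epochs.
#' @param hidden_dim attention hidden width (default 128).
#' @param seed single seed feeding all training randomness.
#' @param backbone_name backbone identifier.
#' @return list of class `"MILConfig"`.
#' @export
milConfig <- function(tile_size = 224L, magnification = "10x",
                      learning_rate = 1e-5, weight_decay = 1e-4,
                      dropout = 0.5, epochs = 20L, hidden_dim = 128L,
                      seed = 1L, backbone_name = "morphology") {
  if (learning_rate <= 0 || weight_decay <= 0)
    stop("learning_rate and weight_decay must be > 0")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  structure(list(tile_size = as.integer(tile_size),
                 magnification = magnification,
                 learning_rate = learning_rate,
                 weight_decay = weight_decay, dropout = dropout,
                 loss = "class-weighted cross-entropy",
                 epochs = as.integer(epochs),
                 hidden_dim = as.integer(hidden_dim),
                 seed = as.integer(seed), backbone_name = backbone_name),
            class = "MILConfig")
}

#' Attention pooling of a feature bag
#'
#' @param bag a [FeatureBag-class] or an `N x 512` matrix.
#' @param params list with `V` (`hidden_dim x 512`) and `w`
#'   (`hidden_dim`).
#' @return list with `embedding` (512-vector) and `weights` (N
#'   non-negative reals summing to 1).
#' @export
attentionPool <- function(bag, params) {
  H <- if (is(bag, "FeatureBag")) bag@features else bag
  if (ncol(H) != ncol(params$V))
    stop("feature dimension does not match attention parameters")
  Tm <- tanh(H %*% t(params$V))          # N x hidden
  s <- drop(Tm %*% params$w)             # N
  a <- softmax1(s)
  list(embedding = drop(crossprod(H, a)), weights = a)
}

softmax1 <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

#' Initialize attention + head parameters
#'
#' @param hidden_dim attention hidden width.
#' @param seed RNG seed.
#' @param input_dim embedding width (512).
#' @return list with `V`, `w`, `W`, `b`.
#' @export
initMILParams <- function(hidden_dim = 128L, seed = 1L, input_dim = 512L) {
  withSeed(seed, list(
    V = matrix(rnorm(hidden_dim * input_dim, sd = 0.1), hidden_dim),
    w = rnorm(hidden_dim, sd = 0.1),
    W = matrix(rnorm(2L * input_dim, sd = 0.01), 2L),
    b = c(0, 0)))
}

#' Slide-level prediction from a feature bag
#'
#' Standardizes the bag with the model's stored feature statistics,
#' attention-pools it and applies the two-logit softmax head. The
#' likelihood is the positive-class probability.
#'
#' @param bag a [FeatureBag-class].
#' @param model a [MILModel-class].
#' @return a [SlidePrediction-class].
#' @export
predictSlide <- function(bag, model) {
  H <- standardizeBag(bag@features, model@featureStats)
  pool <- attentionPool(H, model@params)
  logits <- drop(model@params$W %*% pool$embedding + model@params$b)
  p <- softmax1(logits)
  new("SlidePrediction", likelihood = p[2], attentionWeights = pool$weights,
      tiles = bag@tiles)
}

standardizeBag <- function(H, stats) {
  if (is.null(stats$center)) return(H)
  sweep(sweep(H, 2, stats$center, "-"), 2, stats$scale, "/")
}

#' Stain-direction color augmentation of a tile
#'
#' Decomposes the tile into optical-density contributions along fixed
#' hematoxylin / eosin / residual stain directions, applies a per-stain
#' random scale `1 + U(-magnitude, magnitude)` and shift
#' `U(-magnitude, magnitude)`, and reconstructs. Geometry is unchanged;
#' magnitude 0 returns exact copies.
#'
#' @param tile `s x s x 3` array in `[0, 1]`.
#' @param k number of variants.
#' @param magnitude perturbation magnitude (default 0.05).
#' @param seed RNG seed.
#' @return list of `k` tiles.
#' @export
stainAugmentations <- function(tile, k = 1L, magnitude = 0.05, seed = 1L) {
  stopifnot(k >= 1, magnitude >= 0)
  if (magnitude == 0) return(replicate(k, tile, simplify = FALSE))
  M <- rbind(h = c(0.650, 0.704, 0.286),
             e = c(0.072, 0.990, 0.105),
             d = c(0.268, 0.570, 0.776))
  M <- M / sqrt(rowSums(M^2))
  Minv <- solve(M)
  d <- dim(tile)
  I <- pmax(matrix(tile, ncol = 3), 1 / 255)
  OD <- -log10(I)
  C <- OD %*% Minv
  withSeed(seed, lapply(seq_len(k), function(i) {
    alpha <- 1 + runif(3, -magnitude, magnitude)
    beta <- runif(3, -magnitude, magnitude)
    ODp <- sweep(sweep(C, 2, alpha, "*"), 2, beta, "+") %*% M
    out <- 10^(-ODp)
    quantize8(array(out, d))
  }))
}
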