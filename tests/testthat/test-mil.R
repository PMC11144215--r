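test_that("attention weights are a proper, permutation-equivariant softmax", {
  params <- initMILParams(hidden_dim = 32, seed = 3)
  for (s in 1:200) {
    bag <- matrix(rnorm(7 * 512), 7, 512)
    pool <- attentionPool(bag, params)
    expect_true(all(pool$weights >= 0))
    expect_lt(abs(sum(pool$weights) - 1), 1e-6)
  }
  bag <- matrix(rnorm(9 * 512), 9, 512)
  pool <- attentionPool(bag, params)
  perm <- sample(9)
  pperm <- attentionPool(bag[perm, ], params)
  expect_equal(pperm$weights, pool$weights[perm], tolerance = 1e-12)
  expect_equal(pperm$embedding, pool$embedding, tolerance = 1e-12)
  ## singleton bag
  expect_equal(attentionPool(matrix(rnorm(512), 1), params)$weights, 1)
  ## identical rows -> uniform weights
  u <- matrix(rep(rnorm(512), 4), 4, byrow = TRUE)
  expect_equal(attentionPool(u, params)$weights, rep(0.25, 4))
})

test_that("slide likelihood is invariant to bag duplication", {
  params <- initMILParams(hidden_dim = 16, seed = 5)
  model <- new("MILModel", backbone = list(name = "none"), params = params,
               featureStats = list(), config = unclass(milConfig()),
               threshold = 0.5)
  bag <- randomBag(6, seed = 11)
  dup <- new("FeatureBag",
             features = bag@features[rep(1:6, each = 2), ],
             tiles = bag@tiles[rep(1:6, each = 2), ])
  p1 <- predictSlide(bag, model)
  p2 <- predictSlide(dup, model)
  expect_lt(abs(likelihood(p1) - likelihood(p2)), 1e-6)
  expect_gte(likelihood(p1), 0); expect_lte(likelihood(p1), 1)
  ## zeroed classifier head gives equal logits, likelihood 1/2
  params0 <- params; params0$W[] <- 0; params0$b[] <- 0
  model0 <- new("MILModel", backbone = list(name = "none"),
                params = params0, featureStats = list(),
                config = unclass(milConfig()), threshold = 0.5)
  expect_equal(likelihood(predictSlide(bag, model0)), 0.5)
})

test_that("feature extraction is deterministic and discriminative", {
  bb <- milBackbone()
  tiles <- list(generateTileTexture("solid_nest", 1),
                generateTileTexture("dispersed", 2))
  bag <- extractFeatures(tiles, bb)
  expect_s4_class(bag, "FeatureBag")
  expect_equal(dim(bagFeatures(bag)), c(2L, 512L))
  expect_identical(bagFeatures(extractFeatures(tiles, bb)),
                   bagFeatures(bag))
  ## single tile -> 1 x 512
  expect_equal(dim(bagFeatures(extractFeatures(tiles[1], bb))), c(1L, 512L))
  ## constant-color vs textured tile embed differently
  flat <- array(0.5, c(224, 224, 3))
  b2 <- extractFeatures(list(flat, tiles[[2]]), bb)
  expect_gt(sqrt(sum((bagFeatures(b2)[1, ] - bagFeatures(b2)[2, ])^2)), 0)
  expect_error(extractFeatures(list(), bb), "empty tile list")
})

test_that("stain augmentation perturbs color but not geometry", {
  tile <- generateTileTexture("dispersed", 9)
  ## magnitude 0 -> exact copies
  z <- stainAugmentations(tile, k = 3, magnitude = 0, seed = 2)
  expect_length(z, 3)
  expect_identical(z[[1]], tile); expect_identical(z[[3]], tile)
  ## deterministic under a fixed seed
  a <- stainAugmentations(tile, 3, 0.05, seed = 2)
  b <- stainAugmentations(tile, 3, 0.05, seed = 2)
  expect_identical(a, b)
  ## variants keep dimensions, move channel means
  expect_equal(dim(a[[1]]), dim(tile))
  means <- vapply(a, function(t) mean(t[, , 1]), numeric(1))
  expect_true(any(abs(means - mean(tile[, , 1])) > 1e-4))
})

test_that("class weights are inverse-frequency with mean one", {
  w <- classWeights(c(rep("positive", 10), rep("negative", 10)))
  expect_equal(unname(w), c(1, 1))
  w <- classWeights(c(rep("positive", 12), rep("negative", 88)))
  expect_equal(unname(w["positive"] / w["negative"]), 88 / 12)
  expect_equal(mean(w), 1)
  expect_error(classWeights(rep("positive", 5)), "both classes")
})

test_that("stratified splits preserve strata and partition the manifest", {
  man <- data.frame(
    slide_id = sprintf("s%03d", 1:100),
    label = rep(c("positive", "negative"), c(12, 88)),
    cohort_name = rep(c("A", "B"), 50))
  sp <- stratifiedSplits(man, holdout_fraction = 0.15, n_folds = 5,
                         seed = 1)
  hold <- sp[sp$partition == "holdout", ]
  expect_equal(sum(hold$label == "positive"), 2)  # round(12 * 0.15)
  expect_true(abs(nrow(hold) - 15) <= 1)
  ## per-stratum deviation from the target fraction is at most one slide
  for (st in split(sp, paste(sp$label, sp$cohort_name))) {
    expect_lte(abs(sum(st$partition == "holdout") - 0.15 * nrow(st)), 1)
  }
  ## folds are disjoint and cover all training slides
  train <- sp[sp$partition == "train", ]
  expect_true(all(!is.na(train$fold)))
  expect_true(all(is.na(sp$fold[sp$partition == "holdout"])))
  expect_equal(sort(unique(train$fold)), 1:5)
  ## fold sizes within each stratum are balanced to one slide
  for (st in split(train, paste(train$label, train$cohort_name))) {
    cnt <- tabulate(st$fold, 5)
    expect_lte(diff(range(cnt)), 1)
  }
  ## determinism
  expect_identical(sp, stratifiedSplits(man, 0.15, 5, seed = 1))
  ## single stratum (3 positive/A slides) smaller than n_folds
  expect_warning(stratifiedSplits(man[c(1, 3, 5), ], 0, 5, seed = 1),
                 "stratum")
})

test_that("PPV at the sensitivity target matches exhaustive search", {
  bruteForce <- function(scores, labels, target) {
    y <- labels == "positive"
    best <- NULL
    for (t in sort(unique(scores))) {
      pred <- scores >= t
      sens <- sum(pred & y) / sum(y)
      if (sens >= target) {
        ppv <- if (any(pred)) sum(pred & y) / sum(pred) else NA
        if (is.null(best) || t > best$t) best <- list(t = t, ppv = ppv)
      }
    }
    best
  }
  ## enumerated 6-sample toy
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.2)
  labels <- c("positive", "negative", "positive", "positive", "negative",
              "negative")
  got <- ppvAtSensitivity(scores, labels, 0.9)
  bf <- bruteForce(scores, labels, 0.9)
  expect_equal(got$threshold, bf$t)
  expect_equal(got$ppv, bf$ppv)
  ## random instances with up to 20 validation samples
  set.seed(31)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    scores <- round(runif(n), 2)
    labels <- ifelse(runif(n) < 0.4, "positive", "negative")
    if (!any(labels == "positive")) labels[1] <- "positive"
    got <- ppvAtSensitivity(scores, labels, 0.9)
    bf <- bruteForce(scores, labels, 0.9)
    if (!is.null(bf)) {
      expect_equal(got$threshold, bf$t)
      expect_equal(got$ppv, bf$ppv)
      expect_false(got$flagged)
    } else {
      expect_true(got$flagged)
    }
  }
})

test_that("model selection ranks by PPV with the documented tie-breaks", {
  perfect <- list(model = "A", scores = c(0.9, 0.8, 0.2, 0.1),
                  labels = c("positive", "positive", "negative", "negative"))
  coin <- list(model = "B", scores = c(0.6, 0.4, 0.6, 0.4),
               labels = c("positive", "positive", "negative", "negative"))
  sel <- selectModel(list(coin, perfect))
  expect_equal(sel$model, "A")
  expect_equal(sel$ppv, 1)
  ## two identical candidates: first wins
  sel <- selectModel(list(perfect, perfect))
  expect_equal(sel$index, 1L)
})

test_that("training reduces the weighted loss and is seed-reproducible", {
  ## separable synthetic bags: positives carry a shifted tile cluster
  makeBag <- function(pos, seed) {
    set.seed(seed)
    f <- matrix(rnorm(8 * 512, sd = 0.5), 8, 512)
    if (pos) f[1:4, 1:64] <- f[1:4, 1:64] + 2
    new("FeatureBag", features = f,
        tiles = data.frame(slide_id = "t", x = 0:7, y = 0L, size = 224L))
  }
  bags <- lapply(1:10, function(i) makeBag(i <= 5, i))
  labels <- rep(c("positive", "negative"), each = 5)
  ## dropout disabled so the descent itself is what is being checked
  cfg <- milConfig(learning_rate = 0.05, epochs = 15, seed = 2,
                   dropout = 0)
  fit <- trainMIL(bags, labels, cfg)
  loss <- fit$log$train_loss
  ## non-increasing up to 10% jitter
  expect_true(all(diff(loss) <= 0.1 * head(loss, -1) + 1e-8))
  expect_lt(loss[length(loss)], loss[1])
  ## same seed, same trajectory
  fit2 <- trainMIL(bags, labels, cfg)
  expect_equal(fit$log$train_loss, fit2$log$train_loss)
  expect_equal(fit$model@params$V, fit2$model@params$V)
  expect_error(trainMIL(bags[1:5], labels[1:5], cfg), "per class")
})

test_that("attention heatmaps are max-normalized tile footprints", {
  mkpred <- function(w, xs) new("SlidePrediction", likelihood = 0.5,
    attentionWeights = w,
    tiles = data.frame(slide_id = "h", x = xs, y = 0L, size = 2L))
  ## single tile -> footprint 1.0
  m <- attentionHeatmap(mkpred(1, 0L), 4, 2)
  expect_equal(unique(as.vector(m[1:2, 1:2])), 1)
  expect_equal(unique(as.vector(m[, 3:4])), 0)
  ## weights [0.5, 0.25, 0.25] -> values [1, 0.5, 0.5]
  m <- attentionHeatmap(mkpred(c(0.5, 0.25, 0.25), c(0L, 2L, 4L)), 6, 2)
  expect_equal(m[1, 1], 1); expect_equal(m[1, 3], 0.5)
  expect_equal(m[1, 5], 0.5)
  ## uniform weights -> uniform map value 1
  m <- attentionHeatmap(mkpred(c(1, 1, 1) / 3, c(0L, 2L, 4L)), 6, 2)
  expect_equal(unique(as.vector(m)), 1)
})
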