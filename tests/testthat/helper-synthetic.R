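## Shared fixtures, built in code. Expensive objects are memoized per
## test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

## In-memory bag set: generates slides, runs QC, extracts features.
syntheticBagSet <- function(n_slides, prevalence, seed,
                            signal_fraction = 0.5, width = 896L,
                            background_fraction = 0.25) {
  backbone <- milBackbone()
  n_pos <- round(n_slides * prevalence)
  labels <- c(rep("positive", n_pos), rep("negative", n_slides - n_pos))
  bags <- vector("list", n_slides)
  truths <- vector("list", n_slides)
  for (i in seq_len(n_slides)) {
    sp <- syntheticSlideSpec(sprintf("bag%03d", i), labels[i], width, width,
                             signal_fraction = signal_fraction,
                             background_fraction = background_fraction,
                             seed = histoscreen:::mixSeed(seed, i))
    sl <- generateSlide(sp)
    slide <- new("SlideImage", pixels = sl$image, slideId = sp$slide_id,
                 baseMagnification = "10x")
    kept <- filterTiles(scoreTiles(slide))
    tiles <- lapply(seq_len(nrow(kept)), function(j)
      sl$image[kept$y[j] + 1:224, kept$x[j] + 1:224, , drop = FALSE])
    refs <- data.frame(slide_id = sp$slide_id, x = kept$x, y = kept$y,
                       size = 224L)
    bags[[i]] <- extractFeatures(tiles, backbone, refs)
    truths[[i]] <- sl$truth
  }
  list(bags = bags, labels = labels, truths = truths, backbone = backbone)
}

## Random (unstructured) feature bag for attention property tests.
randomBag <- function(n_tiles, seed) {
  set.seed(seed)
  new("FeatureBag",
      features = matrix(rnorm(n_tiles * 512), n_tiles, 512),
      tiles = data.frame(slide_id = "r", x = seq_len(n_tiles) - 1L,
                         y = 0L, size = 224L))
}

## Trained desk-scale model + its training cohort (memoized).
trainedFixture <- function() {
  memo("trained_model", function() {
    tr <- syntheticBagSet(14, 0.5, seed = 4001)
    cfg <- milConfig(learning_rate = 0.05, epochs = 25, seed = 7)
    fit <- trainMIL(tr$bags, tr$labels, cfg)
    list(fit = fit, train = tr)
  })
}

## On-disk deployment batch: 22 tissue slides + 2 all-background slides.
deploymentFixture <- function() {
  memo("deployment_batch", function() {
    dir <- file.path(tempdir(), "histoscreen-deploy")
    if (!dir.exists(dir)) dir.create(dir)
    rows <- vector("list", 24)
    for (i in 1:24) {
      bg <- if (i <= 2) 1.0 else 0.25
      lab <- if (i %% 4 == 0) "positive" else "negative"
      sp <- syntheticSlideSpec(sprintf("dep%02d", i), lab, 448, 448,
                               signal_fraction = 0.6,
                               background_fraction = bg,
                               seed = histoscreen:::mixSeed(9100, i))
      paths <- writeSlide(generateSlide(sp), dir)
      rows[[i]] <- data.frame(slide_id = sp$slide_id,
                              file_path = unname(paths["image"]),
                              tissue_site = "Bladder",
                              disease_stage = "MIBC", label = lab,
                              cohort_name = "deploy")
    }
    do.call(rbind, rows)
  })
}
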