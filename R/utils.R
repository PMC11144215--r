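#' @keywords internal
"_PACKAGE"

#' @import methods
#' @importFrom stats pbinom qbeta qnorm rnorm runif sd setNames wilcox.test
#' @importFrom utils read.csv write.csv head
NULL

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic seed mixing (Lehmer step, modulus 2^31 - 1) so per-slide /
## per-tile seeds derived from one cohort seed stay inside R's integer range.
mixSeed <- function(seed, index) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m)
  s <- (s * 48271 + as.numeric(index) + 1) %% m
  s <- (s * 48271 + 11) %% m
  as.integer(s)
}

## Vectorized RGB (in [0,1]) -> HSV; hue in degrees [0, 360).
rgbToHsv <- function(r, g, b) {
  v <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- v - mn
  s <- ifelse(v > 0, d / v, 0)
  h <- numeric(length(r))
  nz <- d > 0
  rr <- r[nz]; gg <- g[nz]; bb <- b[nz]; dd <- d[nz]; vv <- v[nz]
  hh <- numeric(sum(nz))
  i <- vv == rr
  hh[i] <- ((gg[i] - bb[i]) / dd[i]) %% 6
  i <- vv == gg & vv != rr
  hh[i] <- (bb[i] - rr[i]) / dd[i] + 2
  i <- vv == bb & vv != rr & vv != gg
  hh[i] <- (rr[i] - gg[i]) / dd[i] + 4
  h[nz] <- (hh * 60) %% 360
  list(h = h, s = s, v = v)
}

## HSV -> RGB in [0,1], vectorized; h in degrees.
hsvToRgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  for (k in 0:5) {
    idx <- i == k
    if (!any(idx)) next
    ch <- switch(as.character(k),
      "0" = list(v, t, p), "1" = list(q, v, p), "2" = list(p, v, t),
      "3" = list(p, q, v), "4" = list(t, p, v), "5" = list(v, p, q))
    r[idx] <- ch[[1]][idx]; g[idx] <- ch[[2]][idx]; b[idx] <- ch[[3]][idx]
  }
  list(r = r, g = g, b = b)
}

## Quantize [0,1] doubles to the 8-bit grid k/255 (lossless TIFF round trip).
quantize8 <- function(x) round(pmin(pmax(x, 0), 1) * 255) / 255

isBinaryLabel <- function(x) all(x %in% c(0L, 1L, 0, 1, TRUE, FALSE))
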