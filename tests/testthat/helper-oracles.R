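# Shared fixtures and independent oracles.

# small EPIK-like configuration: 24 lines, one-fourth keyhole, 3 interleaves
tinyEpik <- function(pe = 24L, trMS = 1000) {
  sequenceParams("EPIK", matrixPE = pe, echoSpacingMS = 1, teMS = 15,
                 trMS = trMS, keyholeFraction = 0.25, nInterleaves = 3L,
                 t2starMS = 40)
}

tinyEpi <- function(pe = 16L, trMS = 1000) {
  sequenceParams("EPI", matrixPE = pe, echoSpacingMS = 1, teMS = 12,
                 trMS = trMS, t2starMS = 40)
}

# direct-summation PSF oracle: |sum_j w_j exp(2*pi*i*(j - N/2)*x)|,
# peak-normalized; independent of the package's FFT path
naivePsf <- function(w, x) {
  n <- length(w)
  j <- seq_len(n) - 1
  v <- vapply(x, function(xx) Mod(sum(w * exp(2i * pi * (j - n / 2) * xx))),
              numeric(1))
  v / Mod(sum(w))
}

# brute-force half-max width of a function evaluated on a very fine grid
bruteFwhm <- function(f, halfRange = 0.5, nGrid = 2e5) {
  x <- seq(-halfRange, halfRange, length.out = nGrid)
  y <- f(x)
  y <- y / max(y)
  i0 <- which.max(y)
  ir <- i0
  while (y[ir] >= 0.5) ir <- ir + 1
  il <- i0
  while (y[il] >= 0.5) il <- il - 1
  interp <- function(a, b) x[a] + (0.5 - y[a]) * (x[b] - x[a]) / (y[b] - y[a])
  interp(ir - 1, ir) - interp(il + 1, il)
}

# closed-form Dirichlet kernel (uniform-weight PSF magnitude)
dirichletKernel <- function(n) {
  function(x) {
    v <- abs(sin(n * pi * x) / (n * sin(pi * x)))
    v[abs(sin(pi * x)) < 1e-15] <- 1
    v
  }
}

# direct-summation DFT row oracle for a 2-D image, DC-centred convention
naiveKspaceRow <- function(img, line) {
  n <- nrow(img)
  m <- ncol(img)
  ky <- line - n %/% 2
  kx <- (seq_len(m) - 1) - m %/% 2
  row <- complex(m)
  for (u in seq_len(m)) {
    s <- 0i
    for (r in seq_len(n)) for (c in seq_len(m)) {
      y <- (r - 1) - n %/% 2
      x <- (c - 1) - m %/% 2
      s <- s + img[r, c] * exp(-2i * pi * (ky * y / n + kx[u] * x / m))
    }
    row[u] <- s
  }
  row
}

# random valid EPIK-like parameterization
randomValidParams <- function() {
  repeat {
    ni <- sample(2:4, 1)
    khFracDen <- sample(c(2L, 3L, 4L, 6L), 1)
    pe <- khFracDen * ni * sample(2:6, 1)
    kh <- pe %/% khFracDen
    if ((pe - kh) %% ni == 0 && pe %% 2L == 0L) {
      return(sequenceParams("EPIK", matrixPE = pe,
                            echoSpacingMS = stats::runif(1, 0.3, 1.5),
                            teMS = stats::runif(1, 20, 40),
                            keyholeFraction = kh / pe, nInterleaves = ni))
    }
  }
}
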