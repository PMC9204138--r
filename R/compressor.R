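# Autoencoder feature compression for the collinear diffusion metrics.

#' Compressor configuration
#'
#' A compact fully-connected autoencoder trained with the Adam optimizer on
#' mean squared reconstruction error. With `hidden = integer(0)` (the
#' default) both encoder and decoder are single linear layers, whose optimum
#' spans the leading principal subspace of the standardized features; tanh
#' hidden layers can be added for a nonlinear code.
#'
#' @param latentDim size of the code (1..6; default 3 of the 6 metrics).
#' @param hidden integer vector of hidden layer sizes (mirrored in the
#'   decoder); `integer(0)` for a purely linear autoencoder.
#' @param epochs full-batch Adam steps.
#' @param lr Adam learning rate.
#' @param seed RNG seed for weight initialization (overridden by pipeline
#'   substreams where applicable).
#' @return A config list for [fitCompressor()].
#' @export
compressorConfig <- function(latentDim = 3L, hidden = integer(0),
                             epochs = 300L, lr = 0.02, seed = 1L) {
  stopifnot(latentDim >= 1, latentDim <= 6, epochs >= 1, lr > 0)
  list(latentDim = as.integer(latentDim), hidden = as.integer(hidden),
       epochs = as.integer(epochs), lr = lr, seed = as.integer(seed))
}

.mlpInit <- function(sizes, acts, seed) {
  withSeed(seed, lapply(seq_len(length(sizes) - 1), function(i) {
    fanIn <- sizes[i]
    list(W = matrix(stats::rnorm(fanIn * sizes[i + 1], sd = sqrt(1 / fanIn)),
                    fanIn, sizes[i + 1]),
         b = rep(0, sizes[i + 1]), act = acts[i])
  }))
}

.mlpForward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1)
  acts[[1]] <- X
  for (i in seq_along(layers)) {
    L <- layers[[i]]
    a <- sweep(acts[[i]] %*% L$W, 2, L$b, "+")
    if (L$act == "tanh") a <- tanh(a)
    acts[[i + 1]] <- a
  }
  acts
}

#' Fit the autoencoder compressor
#'
#' Features are standardized with the training data's mean and sd (stored
#' in the compressor and reapplied at encode time, so no statistics leak
#' from test data). Training is deterministic for a given seed.
#'
#' @param X numeric matrix of training features (rows = blocks, columns =
#'   the 6 metrics); all finite, at least `latentDim` rows.
#' @param config from [compressorConfig()].
#' @param seed optional seed overriding `config$seed`.
#' @return A [Compressor-class].
#' @export
fitCompressor <- function(X, config = compressorConfig(), seed = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite features")
  if (nrow(X) < config$latentDim)
    stop("need at least latentDim training rows")
  seed <- seed %||% config$seed
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  p <- ncol(X)
  sizes <- c(p, config$hidden, config$latentDim, rev(config$hidden), p)
  nl <- length(sizes) - 1
  acts <- rep("linear", nl)
  if (length(config$hidden)) {
    hid <- c(seq_along(config$hidden),                    # encoder hiddens
             nl - rev(seq_along(config$hidden)))          # decoder hiddens
    acts[hid] <- "tanh"
  }
  layers <- .mlpInit(sizes, acts, seed)
  nEnc <- length(config$hidden) + 1L

  # Adam state
  mW <- lapply(layers, function(L) L$W * 0); vW <- mW
  mB <- lapply(layers, function(L) L$b * 0); vB <- mB
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  n <- nrow(Xs)
  loss <- NA_real_
  for (ep in seq_len(config$epochs)) {
    fw <- .mlpForward(layers, Xs)
    Yhat <- fw[[length(fw)]]
    diff <- Yhat - Xs
    loss <- mean(diff^2)
    grad <- 2 * diff / length(diff)
    for (i in rev(seq_along(layers))) {
      L <- layers[[i]]
      if (L$act == "tanh") grad <- grad * (1 - fw[[i + 1]]^2)
      gW <- crossprod(fw[[i]], grad)
      gB <- colSums(grad)
      grad <- grad %*% t(L$W)
      mW[[i]] <- b1 * mW[[i]] + (1 - b1) * gW
      vW[[i]] <- b2 * vW[[i]] + (1 - b2) * gW^2
      mB[[i]] <- b1 * mB[[i]] + (1 - b1) * gB
      vB[[i]] <- b2 * vB[[i]] + (1 - b2) * gB^2
      corr1 <- 1 - b1^ep; corr2 <- 1 - b2^ep
      layers[[i]]$W <- L$W - config$lr * (mW[[i]] / corr1) /
        (sqrt(vW[[i]] / corr2) + epsA)
      layers[[i]]$b <- L$b - config$lr * (mB[[i]] / corr1) /
        (sqrt(vB[[i]] / corr2) + epsA)
    }
  }
  new("Compressor", layers = layers, nEncoderLayers = nEnc, center = ctr,
      scale = scl, latentDim = config$latentDim, finalLoss = loss)
}

#' @rdname Compressor-class
#' @param x a `Compressor`.
setMethod("encode", "Compressor", function(x, newdata) {
  newdata <- as.matrix(newdata)
  Xs <- sweep(sweep(newdata, 2, x@center), 2, x@scale, "/")
  fw <- .mlpForward(x@layers[seq_len(x@nEncoderLayers)], Xs)
  fw[[length(fw)]]
})

#' Reconstruct features through the full autoencoder
#'
#' @param compressor a [Compressor-class].
#' @param newdata feature matrix.
#' @return Reconstruction on the original feature scale.
#' @export
reconstruct <- function(compressor, newdata) {
  newdata <- as.matrix(newdata)
  Xs <- sweep(sweep(newdata, 2, compressor@center), 2, compressor@scale, "/")
  fw <- .mlpForward(compressor@layers, Xs)
  Yh <- fw[[length(fw)]]
  sweep(sweep(Yh, 2, compressor@scale, "*"), 2, compressor@center, "+")
}
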