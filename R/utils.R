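# Internal numeric utilities: seeding, smoothing, interpolation, hashing.

.MOD31 <- 2147483647

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All stochastic stages of the package draw their randomness from named
#' substreams of one master seed, so that a whole analysis is a pure function
#' of that seed while individual stages remain independently reproducible.
#'
#' @param master integer master seed.
#' @param name character stream label (e.g. `"fold3-regressor"`).
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
seedFrom <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  h <- abs(as.numeric(master)) %% .MOD31
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% .MOD31
  as.integer(h)
}

# Evaluate expr under a given seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Row-normalized truncated Gaussian convolution matrix (edge-renormalized).
gaussianKernelMatrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(3 * sigma)
  d <- outer(seq_len(n), seq_len(n), "-")
  K <- exp(-d^2 / (2 * sigma^2))
  K[abs(d) > r] <- 0
  K / rowSums(K)
}

smoothAlong <- function(x, K, along) {
  d <- dim(x)
  perm <- c(along, setdiff(1:3, along))
  xp <- aperm(x, perm)
  xp <- array(K %*% matrix(xp, nrow = d[along]), dim = d[perm])
  aperm(xp, order(perm))
}

# Separable 3D Gaussian smoothing with edge renormalization.
gaussianSmooth3d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  for (ax in 1:3) x <- smoothAlong(x, gaussianKernelMatrix(d[ax], sigma), ax)
  x
}

# Trilinear sampling of a 3D array at fractional 1-based coordinates,
# clamped to the array bounds (replicate-edge behaviour).
trilinearSample <- function(vol, xi, yi, zi) {
  d <- dim(vol)
  xi <- pmin(pmax(xi, 1), d[1])
  yi <- pmin(pmax(yi, 1), d[2])
  zi <- pmin(pmax(zi, 1), d[3])
  x0 <- pmin(floor(xi), d[1] - 1L); x1 <- x0 + 1
  y0 <- pmin(floor(yi), d[2] - 1L); y1 <- y0 + 1
  z0 <- pmin(floor(zi), d[3] - 1L); z1 <- z0 + 1
  if (d[1] == 1L) { x0 <- x1 <- rep(1, length(xi)) }
  if (d[2] == 1L) { y0 <- y1 <- rep(1, length(yi)) }
  if (d[3] == 1L) { z0 <- z1 <- rep(1, length(zi)) }
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  at <- function(i, j, k) vol[cbind(i, j, k)]
  v000 <- at(x0, y0, z0); v100 <- at(x1, y0, z0)
  v010 <- at(x0, y1, z0); v110 <- at(x1, y1, z0)
  v001 <- at(x0, y0, z1); v101 <- at(x1, y0, z1)
  v011 <- at(x0, y1, z1); v111 <- at(x1, y1, z1)
  v00 <- v000 * (1 - fx) + v100 * fx
  v10 <- v010 * (1 - fx) + v110 * fx
  v01 <- v001 * (1 - fx) + v101 * fx
  v11 <- v011 * (1 - fx) + v111 * fx
  v0 <- v00 * (1 - fy) + v10 * fy
  v1 <- v01 * (1 - fy) + v11 * fy
  v0 * (1 - fz) + v1 * fz
}

# Small deterministic content hash (polynomial over the serialized object),
# used for provenance sidecars only.
contentHash <- function(obj) {
  raw <- as.integer(serialize(obj, NULL, version = 2))
  h <- 5381
  for (b in raw) h <- (h * 33 + b) %% .MOD31
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.METRICS <- c("AD", "ADC", "FA", "RD", "NDI", "ODI")
.CELLTYPES <- c("Cells", "Neurons", "Glia",
                "Oligodendrocytes", "Astrocytes", "Microglia")
.BASETYPES <- c("Neurons", "Oligodendrocytes", "Astrocytes", "Microglia")
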