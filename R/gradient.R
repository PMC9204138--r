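#' Construct a gradient scheme
#'
#' @param bvals numeric b-values in s/mm^2, one per DWI volume.
#' @param bvecs 3 x n matrix (or n x 3, transposed automatically) of gradient
#'   directions; b > 0 columns must be unit vectors.
#' @return A [GradientScheme-class] object.
#' @export
gradientScheme <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  new("GradientScheme", bvals = as.numeric(bvals), bvecs = bvecs)
}

#' Approximately uniform gradient directions by electrostatic repulsion
#'
#' Places `n` points on the unit sphere and relaxes them under an
#' antipodally-symmetric Coulomb repulsion (each point repels both every
#' other point and its antipode), the standard construction for DWI
#' direction tables. Deterministic for a given `seed`.
#'
#' @param n number of directions.
#' @param iters relaxation iterations.
#' @param seed RNG seed for the initial configuration.
#' @return 3 x n matrix of unit vectors.
#' @export
repulsionDirections <- function(n, iters = 300, seed = 42L) {
  v <- withSeed(seed, matrix(stats::rnorm(3 * n), 3, n))
  v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
  step <- 0.05
  for (it in seq_len(iters)) {
    f <- matrix(0, 3, n)
    for (i in seq_len(n)) {
      d1 <- v[, i] - v          # repulsion from the other points
      d2 <- v[, i] + v          # ... and from their antipodes
      r1 <- colSums(d1^2); r2 <- colSums(d2^2)
      r1[i] <- Inf              # skip self
      f[, i] <- d1 %*% (1 / (r1^1.5)) + d2 %*% (1 / pmax(r2, 1e-9)^1.5)
    }
    v <- v + step * f
    v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
    step <- step * 0.97
  }
  v
}

#' Default two-shell acquisition scheme
#'
#' Two b = 0 volumes, 20 directions at b = 1,000 s/mm^2 and 52 directions at
#' b = 3,000 s/mm^2 (74 volumes), with direction tables built by
#' electrostatic repulsion.
#'
#' @return A [GradientScheme-class] with 74 entries.
#' @export
defaultGradientScheme <- function() {
  g1 <- repulsionDirections(20, seed = 20L)
  g2 <- repulsionDirections(52, seed = 52L)
  gradientScheme(
    bvals = c(0, 0, rep(1000, 20), rep(3000, 52)),
    bvecs = cbind(matrix(0, 3, 2), g1, g2))
}

#' Read / write FSL-style bval and bvec files
#'
#' `readGradientScheme` reads a pair of whitespace-separated text files
#' (bvals on one line; bvecs as three lines of x, y, z components);
#' `writeGradientScheme` writes them.
#'
#' @param bvalFile,bvecFile file paths.
#' @param scheme a [GradientScheme-class].
#' @param prefix output path prefix; writes `<prefix>.bval` and `<prefix>.bvec`.
#' @return A [GradientScheme-class]; the writer returns the two paths invisibly.
#' @export
readGradientScheme <- function(bvalFile, bvecFile) {
  bvals <- scan(bvalFile, quiet = TRUE)
  bvecs <- as.matrix(utils::read.table(bvecFile))
  dimnames(bvecs) <- NULL
  gradientScheme(bvals, bvecs)
}

#' @rdname readGradientScheme
#' @export
writeGradientScheme <- function(scheme, prefix) {
  bval <- paste0(prefix, ".bval")
  bvec <- paste0(prefix, ".bvec")
  writeLines(paste(format(scheme@bvals, trim = TRUE), collapse = " "), bval)
  writeLines(apply(scheme@bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec)
  invisible(c(bval, bvec))
}
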