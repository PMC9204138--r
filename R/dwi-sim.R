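# Tensor forward signal model and Rician noise.

# Normalize tensor input to an n x 6 component matrix (Dxx,Dyy,Dzz,Dxy,Dxz,Dyz)
# plus the original spatial dims (or NA).
.asTensorComps <- function(tensors) {
  if (is.matrix(tensors) && nrow(tensors) == 3L && ncol(tensors) == 3L) {
    if (max(abs(tensors - t(tensors))) > 1e-8)
      stop("diffusion tensor must be symmetric")
    comps <- matrix(c(tensors[1, 1], tensors[2, 2], tensors[3, 3],
                      tensors[1, 2], tensors[1, 3], tensors[2, 3]), 1, 6)
    return(list(comps = comps, sdim = NA_integer_))
  }
  if (is.matrix(tensors) && ncol(tensors) == 6L)
    return(list(comps = tensors, sdim = NA_integer_))
  d <- dim(tensors)
  if (length(d) == 4L && d[4] == 6L)
    return(list(comps = matrix(tensors, prod(d[1:3]), 6), sdim = as.integer(d[1:3])))
  stop("tensors must be a 3x3 matrix, an n x 6 matrix, or a 4D array with 6 components")
}

# Design rows of the quadratic form g' D g for component order above.
.quadDesign <- function(bvecs) {
  gx <- bvecs[1, ]; gy <- bvecs[2, ]; gz <- bvecs[3, ]
  cbind(gx^2, gy^2, gz^2, 2 * gx * gy, 2 * gx * gz, 2 * gy * gz)
}

#' Simulate diffusion-weighted signals from a tensor field
#'
#' The noiseless signal of scheme entry i is the monoexponential tensor
#' model `S_i = s0 * exp(-b_i * g_i' D g_i)` with b converted from s/mm^2 to
#' ms/um^2 so that D is in um^2/ms. Optional Rician noise is the magnitude
#' of a complex Gaussian perturbation of the noiseless signal.
#'
#' @param tensors a symmetric 3 x 3 matrix (one voxel), an n x 6 component
#'   matrix (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) or a 4D array with 6 components
#'   in the 4th dimension; units um^2/ms.
#' @param scheme a [GradientScheme-class].
#' @param s0 positive baseline (b = 0) signal.
#' @param noiseSd Rician noise level in signal units (0 = noiseless).
#' @param seed RNG seed for the noise draw.
#' @return Signal array: n_voxels x n_volumes matrix, or a 4D array if
#'   `tensors` was 4D.
#' @export
#' @examples
#' sch <- gradientScheme(c(0, 1000), cbind(c(0, 0, 0), c(1, 0, 0)))
#' simulateDWI(diag(c(1.5, 0.3, 0.3)), sch, s0 = 100)  # 100, 100*exp(-1.5)
simulateDWI <- function(tensors, scheme, s0 = 1, noiseSd = 0, seed = 1L) {
  stopifnot(is(scheme, "GradientScheme"), s0 > 0, noiseSd >= 0)
  tf <- .asTensorComps(tensors)
  bms <- scheme@bvals * 1e-3               # s/mm^2 -> ms/um^2
  A <- .quadDesign(scheme@bvecs) * bms     # rows scaled by b
  S <- s0 * exp(-tf$comps %*% t(A))
  dimnames(S) <- NULL
  if (noiseSd > 0) {
    S <- withSeed(seed, {
      e1 <- matrix(stats::rnorm(length(S), sd = noiseSd), nrow(S))
      e2 <- matrix(stats::rnorm(length(S), sd = noiseSd), nrow(S))
      sqrt((S + e1)^2 + e2^2)
    })
  }
  if (!anyNA(tf$sdim)) S <- array(S, dim = c(tf$sdim, ncol(S)))
  S
}
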