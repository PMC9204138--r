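# Weighted least squares tensor fit and tensor-derived scalar maps.

#' Fit the diffusion tensor by weighted least squares with reweighting
#'
#' Per voxel, solves the log-linear tensor model `log S = log s0 -
#' b g' D g` by weighted least squares with weights equal to the squared
#' observed signals, then repeats `reweightIters` times with weights equal
#' to the squared predicted signals from the previous pass (iterated WLS).
#' Nonpositive signals are clipped to `signalFloor` times the voxel's mean
#' b0 signal before taking logs.
#'
#' @param dwi signal data: n_voxels x n_volumes matrix or a 4D array whose
#'   4th dimension matches the scheme.
#' @param scheme a [GradientScheme-class] with >= 7 entries including at
#'   least one b = 0 entry and at least one b > 0 entry.
#' @param reweightIters number of reweighted passes after the initial
#'   signal-weighted fit (default 1).
#' @param signalFloor relative clipping floor for nonpositive signals.
#' @return A [TensorVolume-class]; diffusivities in um^2/ms.
#' @export
fitTensorWLS <- function(dwi, scheme, reweightIters = 1L, signalFloor = 1e-6) {
  stopifnot(is(scheme, "GradientScheme"))
  nvol <- length(scheme@bvals)
  sdim <- NA_integer_
  if (is.array(dwi) && length(dim(dwi)) == 4L) {
    sdim <- as.integer(dim(dwi)[1:3])
    dwi <- matrix(dwi, prod(sdim), dim(dwi)[4])
  }
  dwi <- as.matrix(dwi)
  if (ncol(dwi) != nvol) stop("signal volumes do not match the gradient scheme")
  if (nvol < 7L) stop("at least 7 scheme entries are required to fit 7 unknowns")
  isB0 <- scheme@bvals == 0
  if (!any(isB0)) stop("the scheme must include at least one b = 0 entry")
  if (all(isB0)) stop("an all-b0 scheme carries no diffusion information")

  bms <- scheme@bvals * 1e-3
  X <- cbind(1, -.quadDesign(scheme@bvecs) * bms)   # log s0 + 6 tensor terms
  nvox <- nrow(dwi)
  beta <- matrix(NA_real_, nvox, 7)
  for (v in seq_len(nvox)) {
    s <- dwi[v, ]
    s0ref <- mean(s[isB0])
    if (!is.finite(s0ref) || s0ref <= 0) s0ref <- max(s, 1e-12)
    s <- pmax(s, signalFloor * s0ref)
    y <- log(s)
    w <- s^2
    b <- tryCatch(
      solve(crossprod(X * sqrt(w)), crossprod(X * w, y)),
      error = function(e) rep(NA_real_, 7))
    for (it in seq_len(reweightIters)) {
      if (anyNA(b)) break
      w <- exp(2 * as.vector(X %*% b))
      b2 <- tryCatch(
        solve(crossprod(X * sqrt(w)), crossprod(X * w, y)),
        error = function(e) NULL)
      if (!is.null(b2)) b <- b2
    }
    beta[v, ] <- b
  }
  new("TensorVolume", comps = beta[, 2:7, drop = FALSE], logS0 = beta[, 1],
      spatialDim = sdim)
}

#' Tensor-derived scalar maps
#'
#' Per voxel, from the tensor eigenvalues in descending order
#' (lambda1 >= lambda2 >= lambda3): mean apparent diffusion coefficient
#' ADC = (l1+l2+l3)/3, axial diffusivity AD = l1 (the principal
#' eigenvalue), radial diffusivity RD = (l2+l3)/2 (mean of the two
#' non-principal eigenvalues), and fractional anisotropy
#' FA = sqrt(1/2) * sqrt((l1-l2)^2+(l2-l3)^2+(l3-l1)^2) / sqrt(l1^2+l2^2+l3^2),
#' with FA of the zero tensor defined as 0. Eigenvalues are not clamped:
#' voxels with any negative eigenvalue are flagged in the QC mask (clamping
#' would silently bias FA), and only at such degenerate voxels is FA capped
#' into \[0, 1\].
#'
#' @param tensors a [TensorVolume-class].
#' @return `list(metrics = MetricVolumeSet with AD, ADC, FA, RD, qc =
#'   logical QC flag per voxel (TRUE = degenerate fit))`. The maps are 3D
#'   arrays when the fit came from a 4D volume, else vectors stored as
#'   n x 1 x 1 arrays.
#' @export
tensorScalars <- function(tensors) {
  stopifnot(is(tensors, "TensorVolume"))
  comps <- tensors@comps
  nvox <- nrow(comps)
  out <- matrix(NA_real_, nvox, 4,
                dimnames = list(NULL, c("AD", "ADC", "FA", "RD")))
  qc <- logical(nvox)
  for (v in seq_len(nvox)) {
    cv <- comps[v, ]
    if (anyNA(cv)) { qc[v] <- TRUE; next }
    D <- matrix(c(cv[1], cv[4], cv[5],
                  cv[4], cv[2], cv[6],
                  cv[5], cv[6], cv[3]), 3, 3)
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    qc[v] <- any(ev < 0)
    adc <- mean(ev)
    num <- sqrt((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 + (ev[3] - ev[1])^2)
    den <- sqrt(2 * sum(ev^2))
    fa <- if (den == 0) 0 else num / den
    if (qc[v]) fa <- min(max(fa, 0), 1)
    out[v, ] <- c(ev[1], adc, fa, (ev[2] + ev[3]) / 2)
  }
  sdim <- tensors@spatialDim
  shape <- if (anyNA(sdim)) c(nvox, 1L, 1L) else sdim
  mets <- lapply(colnames(out), function(m) array(out[, m], dim = shape))
  names(mets) <- colnames(out)
  qcArr <- array(qc, dim = shape)
  list(metrics = new("MetricVolumeSet", metrics = mets), qc = qcArr)
}
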