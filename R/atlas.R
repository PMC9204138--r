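#' Describe a cuboid region for [makeAtlas()]
#'
#' @param lower,upper integer 3-vectors of inclusive voxel index bounds.
#' @param mirror logical; if `TRUE` the cuboid is duplicated, mirrored across
#'   the mid-plane of the first array dimension, under the same label
#'   (hemisphere-symmetric region).
#' @return A layout element for [makeAtlas()].
#' @export
cuboidRegion <- function(lower, upper, mirror = FALSE) {
  stopifnot(length(lower) == 3L, length(upper) == 3L, all(upper >= lower))
  list(type = "cuboid", lower = as.integer(lower), upper = as.integer(upper),
       mirror = isTRUE(mirror))
}

#' Build a region-label atlas from a named layout
#'
#' Constructs an integer label volume (0 = background) from named cuboid
#' regions. Regions must be disjoint; mirrored layouts produce
#' left/right-symmetric regions across the mid-plane of dimension 1.
#'
#' @param shape integer 3-vector of grid dimensions.
#' @param layout named list of [cuboidRegion()] elements; names become region
#'   names, labels are assigned 1, 2, ... in list order.
#' @param voxelSize isotropic voxel edge in mm (default 0.125, a typical
#'   high-field ex vivo mouse acquisition).
#' @return A [RegionAtlas-class].
#' @export
#' @examples
#' atlas <- makeAtlas(c(60, 30, 30), list(
#'   A = cuboidRegion(c(3, 3, 3), c(22, 22, 22)),
#'   B = cuboidRegion(c(33, 3, 3), c(52, 22, 22))))
#' regionNames(atlas)
makeAtlas <- function(shape, layout, voxelSize = 0.125) {
  stopifnot(length(shape) == 3L, all(shape >= 1), length(layout) >= 1,
            !is.null(names(layout)), all(nzchar(names(layout))))
  labels <- array(0L, dim = as.integer(shape))
  owner <- array("", dim = as.integer(shape))
  fill <- function(lab, name, lo, hi) {
    if (any(hi > shape) || any(lo < 1))
      stop("region '", name, "' extends outside the grid")
    sl <- labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    if (any(sl != 0L) && any(sl != lab)) {
      other <- unique(owner[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
      other <- setdiff(other, c("", name))
      stop("regions '", other[1], "' and '", name, "' overlap")
    }
    labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <<- lab
    owner[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <<- name
  }
  for (k in seq_along(layout)) {
    reg <- layout[[k]]
    nm <- names(layout)[k]
    stopifnot(identical(reg$type, "cuboid"))
    fill(k, nm, reg$lower, reg$upper)
    if (reg$mirror) {
      lo <- reg$lower; hi <- reg$upper
      mlo <- c(shape[1] + 1L - hi[1], lo[2:3])
      mhi <- c(shape[1] + 1L - lo[1], hi[2:3])
      fill(k, nm, mlo, mhi)
    }
  }
  nms <- names(layout)
  names(nms) <- as.character(seq_along(layout))
  new("RegionAtlas", labels = labels, regionNames = nms,
      voxelSize = voxelSize)
}

# Logical mask of one or more regions, by label or name.
regionMask <- function(atlas, region) {
  labs <- .resolveRegion(atlas, region)
  array(atlas@labels %in% labs, dim = dim(atlas@labels))
}

.resolveRegion <- function(atlas, region) {
  if (is.numeric(region)) {
    labs <- as.integer(region)
  } else {
    labs <- as.integer(names(atlas@regionNames)[match(region, atlas@regionNames)])
  }
  if (any(is.na(labs)) || !all(labs %in% as.integer(names(atlas@regionNames))))
    stop("unknown region: ", paste(region, collapse = ", "))
  labs
}

# Mask of one hemisphere (split across the mid-plane of dimension 1).
hemisphereMask <- function(atlas, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  d <- dim(atlas@labels)
  mid <- d[1] / 2
  xi <- slice.index(atlas@labels, 1)
  if (hemisphere == "left") xi <= mid else xi > mid
}
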