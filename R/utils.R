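# Internal array / morphology helpers shared by the segmentation and
# phantom modules. All masks are plain logical 3-D arrays; grid metadata
# (voxel_size_mm, affine) travels as attributes.

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# voxel edge lengths in mm for an array carrying grid metadata
voxel_size_of <- function(x) {
  vs <- attr(x, "voxel_size_mm")
  if (is.null(vs)) {
    aff <- attr(x, "affine")
    if (!is.null(aff)) vs <- sqrt(colSums(aff[1:3, 1:3]^2))
  }
  assert_that(!is.null(vs), "array carries no voxel-size or affine metadata")
  as.numeric(vs)
}

# voxel volume in mm^3, from the affine determinant when available
voxel_volume_of <- function(x) {
  aff <- attr(x, "affine")
  if (!is.null(aff)) return(abs(det(aff[1:3, 1:3])))
  prod(voxel_size_of(x))
}

default_affine <- function(dim, voxel_size_mm) {
  aff <- diag(4)
  aff[1, 1] <- voxel_size_mm[1]
  aff[2, 2] <- voxel_size_mm[2]
  aff[3, 3] <- voxel_size_mm[3]
  # grid centred on the world origin (RAS)
  aff[1:3, 4] <- -voxel_size_mm * (dim - 1) / 2
  aff
}

set_grid <- function(x, voxel_size_mm, affine = NULL) {
  attr(x, "voxel_size_mm") <- as.numeric(voxel_size_mm)
  attr(x, "affine") <- affine %||% default_affine(dim(x)[1:3], voxel_size_mm)
  x
}

copy_grid <- function(x, from) {
  attr(x, "voxel_size_mm") <- attr(from, "voxel_size_mm")
  attr(x, "affine") <- attr(from, "affine")
  x
}

# Otsu's between-class-variance threshold on a histogram of `values`
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(values, br, rightmost.closed = TRUE), n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- h / sum(h)
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  mu <- cm[n_bins]
  between <- (mu * cw - cm)^2 / (cw * (1 - cw))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# integer voxel offsets within a physical ball of radius_mm
ball_offsets <- function(radius_mm, voxel_size_mm) {
  assert_that(radius_mm > 0, "radius_mm must be > 0")
  nmax <- floor(radius_mm / voxel_size_mm)
  g <- expand.grid(dx = -nmax[1]:nmax[1], dy = -nmax[2]:nmax[2], dz = -nmax[3]:nmax[3])
  d2 <- (g$dx * voxel_size_mm[1])^2 + (g$dy * voxel_size_mm[2])^2 +
    (g$dz * voxel_size_mm[3])^2
  as.matrix(g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE])
}

# 26-neighbourhood (one voxel in every direction)
unit_offsets <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), , drop = FALSE])
}

shift_logical <- function(m, d) {
  dm <- dim(m)
  out <- array(FALSE, dm)
  t1 <- max(1, 1 + d[1]):min(dm[1], dm[1] + d[1])
  t2 <- max(1, 1 + d[2]):min(dm[2], dm[2] + d[2])
  t3 <- max(1, 1 + d[3]):min(dm[3], dm[3] + d[3])
  if (length(t1) < 1 || length(t2) < 1 || length(t3) < 1) return(out)
  out[t1, t2, t3] <- m[t1 - d[1], t2 - d[2], t3 - d[3]]
  out
}

dilate_mask <- function(mask, offsets) {
  out <- mask
  for (i in seq_len(nrow(offsets))) {
    d <- offsets[i, ]
    if (all(d == 0)) next
    out <- out | shift_logical(mask, d)
  }
  out
}

# erosion as the complement of a dilation; voxels beyond the volume edge
# are treated as foreground so that structures touching the edge are not
# eaten by the border
erode_mask <- function(mask, offsets) {
  !dilate_mask(!mask, offsets)
}

#' Label connected components of a binary mask
#'
#' Breadth-first connected-component labelling of a logical 3-D array.
#'
#' @param mask Logical 3-D array (or matrix, treated as a single slice).
#' @param connectivity 6, 18 or 26 (face, face+edge, full neighbourhood).
#' @return Integer array of the same shape; 0 outside the mask, components
#'   numbered from 1. The number of components is attached as attribute
#'   `n_components`.
#' @export
label_components <- function(mask, connectivity = 26L) {
  dm <- dim(mask)
  if (length(dm) == 2) dm <- c(dm, 1L)
  assert_that(length(dm) == 3, "mask must be a 2-D or 3-D array")
  lab <- cc_label_cpp(as.logical(mask), as.integer(dm), as.integer(connectivity))
  n <- attr(lab, "n_components")
  lab <- array(lab, dim(mask))
  attr(lab, "n_components") <- n
  lab
}

# fill in-plane holes of `mask` slice by slice (4-connectivity on the
# complement; complement components not touching the slice border are holes)
fill_holes_slicewise <- function(mask) {
  dm <- dim(mask)
  out <- mask
  for (k in seq_len(dm[3])) {
    sl <- mask[, , k]
    comp <- label_components(!sl, connectivity = 6L)
    border <- unique(c(comp[1, ], comp[dm[1], ], comp[, 1], comp[, dm[2]]))
    hole <- comp > 0 & !(comp %in% border)
    out[, , k] <- sl | hole
  }
  out
}

# Dice overlap between two logical masks
dice_coefficient <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}
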