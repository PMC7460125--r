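# Tissue separation from the T1-weighted volume: body masking, intensity
# clustering into dark / mid / bright populations, and connectivity-based
# assignment of the anatomical classes (subcutaneous fat, muscle,
# intramuscular fat, cortical bone, marrow).

#' Wrap an integer array as a label volume
#'
#' @param labels Integer 3-D array with values from [tissue_codes()],
#'   carrying grid metadata (see internals of [make_thigh_geometry()]).
#' @return The array with class `label_volume` and the label dictionary
#'   attached.
#' @export
as_label_volume <- function(labels) {
  codes <- tissue_codes()
  present <- unique(as.integer(labels))
  assert_that(all(present %in% codes),
              "labels contain codes outside the tissue dictionary")
  attr(labels, "label_dict") <- codes
  class(labels) <- c("label_volume", class(labels))
  labels
}

#' Extract the body mask from a T1-weighted volume
#'
#' Otsu threshold on the intensity histogram, retention of the two largest
#' 26-connected components (the two legs), then slice-wise hole filling so
#' that dark cortical bone and enclosed marrow are part of the body.
#'
#' @param t1w Numeric 3-D array.
#' @return Logical array of the same shape.
#' @export
body_mask <- function(t1w) {
  thr <- otsu_threshold(as.numeric(t1w))
  fg <- t1w > thr
  comp <- label_components(fg, connectivity = 26L)
  n <- attr(comp, "n_components")
  if (n == 0) stop("no foreground found above the Otsu threshold", call. = FALSE)
  sizes <- tabulate(comp[comp > 0], n)
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(2L, n))]
  fill_holes_slicewise(array(comp %in% keep, dim(t1w)))
}

#' Cluster voxel intensities into ordered populations
#'
#' One-dimensional k-means over the masked voxel intensities. Centroids
#' are initialised at the exact optimum of the binned (512-bin histogram)
#' 1-D k-means problem, found by dynamic programming, and polished with
#' Lloyd iterations on the raw intensities; the procedure is deterministic
#' and independent of the seed. Clusters are relabelled in increasing
#' order of centroid intensity (1 = darkest).
#'
#' @param t1w Numeric 3-D array of finite intensities.
#' @param k Number of clusters, >= 2.
#' @param mask Logical array of voxels to cluster; defaults to
#'   [body_mask()] of the input (background is never clustered).
#' @param seed Unused; accepted so that seeded callers keep a uniform
#'   interface. The algorithm is deterministic.
#' @return Integer array: 0 outside the mask, 1..k ordered by centroid.
#'   Centroids are attached as attribute `centers`.
#' @export
cluster_intensities <- function(t1w, k = 3L, mask = NULL, seed = NULL) {
  assert_that(k >= 2, "k must be >= 2")
  assert_that(all(is.finite(t1w)), "volume must be finite")
  mask <- mask %||% body_mask(t1w)
  v <- as.numeric(t1w[mask])
  if (length(unique(v)) < k)
    stop("fewer distinct intensities than clusters", call. = FALSE)
  centers <- kmeans_1d_centers(v, k)
  fit <- suppressWarnings(
    kmeans(matrix(v, ncol = 1), centers = matrix(centers, ncol = 1),
           iter.max = 100L, algorithm = "Lloyd"))
  ord <- order(fit$centers[, 1])
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  out <- array(0L, dim(t1w))
  out[mask] <- relabel[fit$cluster]
  out <- copy_grid(out, t1w)
  attr(out, "centers") <- sort(fit$centers[, 1])
  out
}

# exact weighted 1-D k-means on a histogram via dynamic programming;
# returns the k segment means in increasing order
kmeans_1d_centers <- function(v, k, n_bins = 512L) {
  u <- sort(unique(v))
  if (length(u) <= n_bins) {
    x <- u
    w <- tabulate(match(v, u), length(u))
  } else {
    br <- seq(min(v), max(v), length.out = n_bins + 1L)
    idx <- findInterval(v, br, rightmost.closed = TRUE)
    w <- tabulate(idx, n_bins)
    x <- vapply(seq_len(n_bins), function(i) (br[i] + br[i + 1]) / 2, numeric(1))
    x <- x[w > 0]; w <- w[w > 0]
  }
  nb <- length(x)
  cw0 <- c(0, cumsum(w)); cwx0 <- c(0, cumsum(w * x)); cwx20 <- c(0, cumsum(w * x^2))
  seg_cost <- function(i, j) {
    # vectorised over i for a fixed j
    sw <- cw0[j + 1] - cw0[i]
    swx <- cwx0[j + 1] - cwx0[i]
    pmax(0, (cwx20[j + 1] - cwx20[i]) - swx^2 / sw)
  }
  dp <- matrix(Inf, k, nb)
  back <- matrix(0L, k, nb)
  dp[1, ] <- seg_cost(1, seq_len(nb))
  if (k > 1) for (m in 2:k) {
    for (j in m:nb) {
      i <- m:j
      val <- dp[m - 1, i - 1] + seg_cost(i, j)
      bi <- which.min(val)
      dp[m, j] <- val[bi]
      back[m, j] <- i[bi]
    }
  }
  # recover segment boundaries and means
  bounds <- integer(k + 1); bounds[k + 1] <- nb
  j <- nb
  for (m in k:1) {
    i <- if (m == 1) 1L else back[m, j]
    bounds[m] <- i
    j <- i - 1L
  }
  vapply(seq_len(k), function(m) {
    i <- bounds[m]; jj <- bounds[m + 1] - (m < k)
    if (m == k) jj <- nb
    sum(w[i:jj] * x[i:jj]) / sum(w[i:jj])
  }, numeric(1))
}

#' Assign anatomical tissue classes from an intensity clustering
#'
#' Interprets the three ordered intensity clusters inside the body mask
#' anatomically via connectivity: bright voxels enclosed in-plane by the
#' dark shell become marrow and the shell cortical bone; bright
#' 26-connected components touching the background (or the volume edge)
#' become subcutaneous fat; remaining bright components, enclosed by
#' muscle, become intramuscular fat; mid-intensity voxels are muscle.
#'
#' @param clusters Integer array from [cluster_intensities()] with k = 3
#'   (0 = background, 1 = dark, 2 = mid, 3 = bright).
#' @return A `label_volume`.
#' @export
assign_tissues <- function(clusters) {
  assert_that(max(clusters) == 3 && min(clusters) == 0,
              "expected a 3-cluster map over a body mask")
  codes <- tissue_codes()
  dark <- clusters == 1L
  mid <- clusters == 2L
  bright <- clusters == 3L
  if (!any(mid)) stop("segmentation failure: no muscle-class voxels", call. = FALSE)

  # marrow: bright voxels inside in-plane holes of the dark (bone) shell
  dark_filled <- fill_holes_slicewise(dark)
  marrow <- bright & dark_filled & !dark

  rest <- bright & !marrow
  comp <- label_components(rest, connectivity = 26L)
  n <- attr(comp, "n_components")
  out <- array(codes[["background"]], dim(clusters))
  out[dark] <- codes[["cortical_bone"]]
  out[mid] <- codes[["muscle"]]
  out[marrow] <- codes[["marrow"]]
  if (n > 0) {
    bg <- clusters == 0L
    bg_touch <- dilate_mask(bg, unit_offsets())
    # contact with the body outer boundary: adjacency to background, or
    # the in-plane (x/y) volume faces; the axial faces merely truncate
    # the anatomy and are not an outer boundary
    dm <- dim(clusters)
    edge <- array(FALSE, dm)
    edge[c(1, dm[1]), , ] <- TRUE
    edge[, c(1, dm[2]), ] <- TRUE
    touching <- unique(comp[rest & (bg_touch | edge)])
    is_sub <- seq_len(n) %in% touching
    out[rest] <- ifelse(is_sub[comp[rest]],
                        codes[["subcutaneous_fat"]],
                        codes[["intramuscular_fat"]])
  }
  out <- copy_grid(out, clusters)
  as_label_volume(out)
}

#' Segment a T1-weighted volume into tissue classes
#'
#' Convenience wrapper: body mask, intensity clustering with k clusters,
#' anatomical assignment, and optional removal of small bright structures
#' (vessels, neurovascular bundle) below `min_structure_ml`.
#'
#' @param t1w Numeric 3-D array with grid metadata.
#' @param k Number of intensity clusters.
#' @param min_structure_ml Minimum intramuscular component volume retained
#'   as fat, in ml; smaller components are treated as excluded structures.
#' @param seed Passed through to [cluster_intensities()] (deterministic).
#' @return A `label_volume`.
#' @export
segment_thigh <- function(t1w, k = 3L, min_structure_ml = 0.5, seed = NULL) {
  cl <- cluster_intensities(t1w, k = k, seed = seed)
  labels <- assign_tissues(cl)
  exclude_small_structures(labels, min_structure_ml)
}

#' Remove small intramuscular structures from a segmentation
#'
#' Connected intramuscular-fat components smaller than `min_volume_ml`
#' are reassigned to muscle: small bright specks inside the muscle are
#' treated as vessels or neurovascular bundle rather than fat.
#'
#' @param labels A `label_volume`.
#' @param min_volume_ml Threshold in ml; 0 is the identity.
#' @return A `label_volume` with total intramuscular fat never increased.
#' @export
exclude_small_structures <- function(labels, min_volume_ml) {
  assert_that(min_volume_ml >= 0, "min_volume_ml must be >= 0")
  if (min_volume_ml == 0) return(labels)
  codes <- tissue_codes()
  imf <- labels == codes[["intramuscular_fat"]]
  if (!any(imf)) return(labels)
  comp <- label_components(imf, connectivity = 26L)
  n <- attr(comp, "n_components")
  sizes <- tabulate(comp[comp > 0], n)
  voxvol <- voxel_volume_of(labels)
  small <- which(sizes * voxvol < min_volume_ml * 1000)
  if (length(small)) {
    drop <- imf & array(comp %in% small, dim(labels))
    labels[drop] <- codes[["muscle"]]
  }
  labels
}

#' Morphological closing of the muscle mask
#'
#' Dilation followed by erosion of the muscle + intramuscular-fat mask
#' with a ball structuring element of the given physical radius. The
#' result is the muscle envelope used for macroscopic fatty infiltration:
#' it contains the muscle and the fat enclosed within it.
#'
#' @param labels A `label_volume` (or a logical mask with grid metadata).
#' @param radius_mm Ball radius in mm, > 0.
#' @return Logical envelope mask, a superset of the input mask.
#' @export
close_muscle_mask <- function(labels, radius_mm = 5) {
  assert_that(radius_mm > 0, "radius_mm must be > 0")
  if (is.logical(labels)) {
    mask <- labels
  } else {
    codes <- tissue_codes()
    mask <- labels == codes[["muscle"]] | labels == codes[["intramuscular_fat"]]
  }
  offs <- ball_offsets(radius_mm, voxel_size_of(labels))
  env <- erode_mask(dilate_mask(mask, offs), offs)
  copy_grid(env, labels)
}
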