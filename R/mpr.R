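# Minimal oblique multiplanar reformation (MPR) engine for voxel phantoms:
# trilinear sampling of an arbitrary reference plane and labelled-marker
# centroid recovery. Voxel-center convention: world = origin + (index-1)*spacing
# (R's 1-based indices); the world frame is interpreted as LPS millimetres.

#' Construct a voxel volume
#'
#' @param data 3D numeric array of voxel values.
#' @param spacing voxel size per axis, mm (length 3, all > 0).
#' @param origin world coordinate (mm) of the center of voxel (1,1,1).
#' @return object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L, all(dim(data) >= 1L))
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  origin <- as_point3(origin, "origin")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("Voxel volume %s, spacing (%g, %g, %g) mm, origin (%.2f, %.2f, %.2f)\n",
              paste(dim(x$data), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' World coordinate of the volume center
#' @param vol a `voxel_volume`.
#' @return length-3 numeric, mm.
#' @export
volume_center <- function(vol) {
  vol$origin + (dim(vol$data) - 1) / 2 * vol$spacing
}

#' Trilinear interpolation at world points
#'
#' @param vol a `voxel_volume`.
#' @param points n x 3 matrix of world coordinates (mm).
#' @param fill value returned for points outside the voxel-center grid.
#' @return numeric vector of n interpolated values. Values at exact voxel
#'   centers equal the stored values.
#' @export
trilinear_sample <- function(vol, points, fill = 0) {
  stopifnot(inherits(vol, "voxel_volume"))
  points <- matrix(as.numeric(points), ncol = 3)
  dims <- dim(vol$data)
  # continuous 1-based indices
  idx <- sweep(sweep(points, 2, vol$origin), 2, vol$spacing, "/") + 1
  out <- rep(as.numeric(fill), nrow(points))
  # tolerate floating-point jitter at the grid boundary (1e-9 voxels)
  eps <- 1e-9
  ok <- idx[, 1] >= 1 - eps & idx[, 1] <= dims[1] + eps &
        idx[, 2] >= 1 - eps & idx[, 2] <= dims[2] + eps &
        idx[, 3] >= 1 - eps & idx[, 3] <= dims[3] + eps
  if (!any(ok)) return(out)
  ix <- idx[ok, , drop = FALSE]
  ix <- pmin(pmax(ix, 1), matrix(dims, nrow(ix), 3, byrow = TRUE))
  # lower corner clamped so lo and lo+1 are valid (singleton axes collapse)
  lo <- pmax(pmin(floor(ix), matrix(dims - 1L, nrow(ix), 3, byrow = TRUE)), 1)
  fr <- pmin(pmax(ix - lo, 0), 1)
  acc <- numeric(nrow(ix))
  d12 <- dims[1] * dims[2]
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ii <- pmin(lo[, 1] + dx, dims[1])
    jj <- pmin(lo[, 2] + dy, dims[2])
    kk <- pmin(lo[, 3] + dz, dims[3])
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    lin <- ii + (jj - 1) * dims[1] + (kk - 1) * d12
    acc <- acc + w * vol$data[lin]
  }
  out[ok] <- acc
  out
}

#' Reformat an oblique plane through a volume
#'
#' Samples a square grid of world points lying on the reference plane,
#' centered at the projection of the volume center onto the plane, using
#' trilinear interpolation. The in-plane basis is `u` = the normalised
#' projection of world +x onto the plane (falling back to +y when the plane
#' is nearly orthogonal to +x) and `v = normal x u`.
#'
#' @param vol a `voxel_volume`.
#' @param plane a `reference_plane`.
#' @param spacing in-plane sample spacing, mm.
#' @param extent total side length of the sampled square, mm.
#' @param fill value for sample points outside the volume.
#' @return object of class `oblique_slice`: list with `data` (2D array),
#'   `u`, `v` (unit in-plane basis), `origin` (world coordinate of sample
#'   (1,1)), `center`, `spacing` and the source `plane`.
#' @export
reformat_plane <- function(vol, plane, spacing = 0.3, extent = 160, fill = 0) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(plane, "reference_plane"),
            spacing > 0)
  if (extent <= 0) stop("extent must cover a positive area", call. = FALSE)
  n <- plane$normal
  u <- c(1, 0, 0) - sum(n * c(1, 0, 0)) * n
  if (sqrt(sum(u^2)) < 1e-6) u <- c(0, 1, 0) - sum(n * c(0, 1, 0)) * n
  u <- u / sqrt(sum(u^2))
  v <- cross3(n, u)
  ctr <- volume_center(vol)
  ctr <- ctr - (sum(n * ctr) - plane$offset) * n   # project onto plane
  half <- floor(extent / (2 * spacing))
  offs <- (-half:half) * spacing
  grid <- expand.grid(su = offs, sv = offs)
  pts <- matrix(ctr, nrow(grid), 3, byrow = TRUE) +
    outer(grid$su, u) + outer(grid$sv, v)
  vals <- trilinear_sample(vol, pts, fill = fill)
  structure(list(data = matrix(vals, length(offs), length(offs)),
                 u = u, v = v,
                 origin = ctr + offs[1] * u + offs[1] * v,
                 center = ctr, spacing = spacing, plane = plane),
            class = "oblique_slice")
}

#' Locate labelled markers in a phantom volume
#'
#' @param vol a `voxel_volume` containing positive integer-labelled markers
#'   on a zero background (see [rasterize_to_volume()]). All voxels sharing
#'   a label are treated as one marker (connected components with equal
#'   labels merged).
#' @return data.frame `label`, `landmark_id` (from [landmark_label_map()],
#'   `NA` for unknown labels), `x`, `y`, `z`: the intensity-weighted centroid
#'   of each label's voxels in world mm, sorted by label.
#' @export
detect_marker_centroids <- function(vol) {
  stopifnot(inherits(vol, "voxel_volume"))
  pos <- which(vol$data > 0)
  if (!length(pos)) stop("volume contains no positive-labelled voxels", call. = FALSE)
  ijk <- arrayInd(pos, dim(vol$data))
  world <- sweep(sweep(ijk - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
  lab <- as.integer(round(vol$data[pos]))
  w <- as.numeric(vol$data[pos])
  labs <- sort(unique(lab))
  cent <- t(vapply(labs, function(l) {
    sel <- lab == l
    colSums(world[sel, , drop = FALSE] * w[sel]) / sum(w[sel])
  }, numeric(3)))
  map <- landmark_label_map()
  data.frame(label = labs,
             landmark_id = names(map)[match(labs, map)],
             x = cent[, 1], y = cent[, 2], z = cent[, 3],
             stringsAsFactors = FALSE)
}

#' Rebuild a landmark set from detected marker centroids
#'
#' @param centroids data.frame from [detect_marker_centroids()].
#' @param subject_id identifier for the reconstructed set.
#' @return a `landmark_set` containing the recognised landmarks.
#' @export
centroids_to_landmark_set <- function(centroids, subject_id = "detected") {
  keep <- !is.na(centroids$landmark_id)
  if (!any(keep)) stop("no recognised landmark labels among centroids", call. = FALSE)
  m <- as.matrix(centroids[keep, c("x", "y", "z")])
  rownames(m) <- centroids$landmark_id[keep]
  landmark_set(subject_id, m)
}

#' Write a voxel volume to NIfTI
#'
#' The affine encodes spacing and origin with identity direction; the world
#' frame is interpreted as LPS mm throughout this package.
#'
#' @param vol a `voxel_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  im <- RNifti::asNifti(vol$data + 0)   # force numeric storage
  RNifti::pixdim(im) <- vol$spacing
  af <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
  im <- RNifti::`sform<-`(im, structure(af, code = 2L))
  im <- RNifti::`qform<-`(im, structure(af, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a voxel volume from NIfTI
#'
#' Only identity-direction affines (diagonal spacing + translation) are
#' accepted; anything else is an error rather than silently reoriented.
#'
#' @param path NIfTI file path.
#' @return a `voxel_volume`.
#' @export
read_volume_nifti <- function(path) {
  im <- RNifti::readNifti(path)
  af <- unclass(RNifti::xform(im))[1:3, , drop = FALSE]
  rot <- af[, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-6 || any(diag(rot) <= 0)) {
    stop("only identity-direction NIfTI affines are supported", call. = FALSE)
  }
  arr <- as.array(im)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  voxel_volume(arr, spacing = diag(rot), origin = af[, 4])
}

#' Write an oblique slice as a one-voxel-thick NIfTI volume
#'
#' @param slice an `oblique_slice` from [reformat_plane()]. The slice is
#'   written on its own axis-aligned grid (u, v, normal), with the true
#'   in-plane spacing; the world offset is stored in the affine translation.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_slice_nifti <- function(slice, path) {
  stopifnot(inherits(slice, "oblique_slice"))
  arr <- array(slice$data, c(dim(slice$data), 1L))
  vol <- voxel_volume(arr, spacing = c(slice$spacing, slice$spacing, 1),
                      origin = slice$origin)
  write_volume_nifti(vol, path)
}
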