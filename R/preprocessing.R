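#' Minimum bounding cube of a segmentation mask
#'
#' Scans the nonzero voxels of the mask, takes the coordinate-wise minimum
#' and maximum along each axis (0-based, inclusive), and optionally expands
#' the resulting box symmetrically into a cube whose side equals the longest
#' extent. Expansion is clamped at the image border with the remainder
#' pushed to the opposite side, so the lesion center is preserved whenever
#' the cube fits inside the grid.
#'
#' @param mask A `SegmentationMask`.
#' @param make_cube Expand the tight box to an isotropic cube (default TRUE).
#' @return A `BoundingCube`: list with `min_index`, `max_index` (0-based,
#'   inclusive), `cube_side`, `grid_dim` and `ref_spacing` (mm, taken from
#'   the mask's reference grid, used to map the cube into other modalities'
#'   grids).
#' @export
compute_bounding_cube <- function(mask, make_cube = TRUE) {
  stopifnot(inherits(mask, "SegmentationMask"))
  nz <- which(mask$voxels != 0, arr.ind = TRUE)
  if (nrow(nz) == 0) stop("empty mask")
  mins <- apply(nz, 2, min) - 1L   # to 0-based
  maxs <- apply(nz, 2, max) - 1L
  dims <- dim(mask$voxels)
  extent <- maxs - mins + 1L
  side <- max(extent)
  if (make_cube) {
    for (a in 1:3) {
      pad <- side - extent[a]
      lo <- mins[a] - pad %/% 2L
      hi <- maxs[a] + (pad - pad %/% 2L)
      if (lo < 0L) { hi <- hi - lo; lo <- 0L }
      if (hi > dims[a] - 1L) {
        shift <- hi - (dims[a] - 1L)
        lo <- lo - shift; hi <- dims[a] - 1L
        if (lo < 0L) lo <- 0L  # cube larger than grid: crop will zero-pad
      }
      mins[a] <- lo; maxs[a] <- hi
    }
  }
  structure(list(min_index = as.integer(mins), max_index = as.integer(maxs),
                 cube_side = as.integer(side), grid_dim = as.integer(dims),
                 ref_spacing = mask$spacing),
            class = "BoundingCube")
}

# trilinear interpolation of vol at fractional 0-based coordinates;
# points outside the grid evaluate to 0 (zero padding)
.trilinear <- function(vol, xi, yi, zi) {
  d <- dim(vol)
  n <- length(xi)
  x0 <- floor(xi); y0 <- floor(yi); z0 <- floor(zi)
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  out <- numeric(n)
  # gather one corner with zero outside
  corner <- function(cx, cy, cz) {
    ix <- x0 + cx; iy <- y0 + cy; iz <- z0 + cz
    ok <- ix >= 0 & ix <= d[1] - 1 & iy >= 0 & iy <= d[2] - 1 &
          iz >= 0 & iz <= d[3] - 1
    v <- numeric(n)
    if (any(ok))
      v[ok] <- vol[cbind(ix[ok] + 1L, iy[ok] + 1L, iz[ok] + 1L)]
    v
  }
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) fx else 1 - fx) * (if (cy) fy else 1 - fy) *
         (if (cz) fz else 1 - fz)
    out <- out + w * corner(cx, cy, cz)
  }
  out
}

#' Crop a volume to a bounding cube and resample to a fixed side
#'
#' The cube, defined on the reference modality's grid, is mapped through
#' physical (mm) coordinates onto this volume's grid (all modalities are
#' assumed co-registered with a shared origin at voxel (0,0,0)), cropped
#' with zero padding outside the image bounds, and trilinearly resampled to
#' `target_side` voxels per axis.
#'
#' @param volume A `ModalityVolume`.
#' @param cube A `BoundingCube` from [compute_bounding_cube()].
#' @param target_side Output side length in voxels (default 64).
#' @return 3D numeric array of side `target_side`.
#' @export
crop_and_resample <- function(volume, cube, target_side = 64L) {
  stopifnot(inherits(volume, "ModalityVolume"), inherits(cube, "BoundingCube"))
  sp_ref <- cube$ref_spacing
  sp <- volume$spacing
  coords <- vector("list", 3)
  for (a in 1:3) {
    phys <- seq(cube$min_index[a] * sp_ref[a], cube$max_index[a] * sp_ref[a],
                length.out = target_side)
    coords[[a]] <- phys / sp[a]     # continuous 0-based index in this grid
  }
  d0 <- dim(volume$voxels)
  lo_idx <- vapply(coords, min, 0); hi_idx <- vapply(coords, max, 0)
  if (any(hi_idx < 0) || any(lo_idx > d0 - 1))
    stop("cube entirely outside the volume")
  grid <- expand.grid(x = coords[[1]], y = coords[[2]], z = coords[[3]])
  vals <- .trilinear(volume$voxels, grid$x, grid$y, grid$z)
  array(vals, dim = rep(as.integer(target_side), 3))
}

#' Min-max normalize a cropped cube to [0, 1]
#'
#' Applies `x = (X - X_min) / (X_max - X_min)` elementwise, where `X_min`
#' and `X_max` are the extreme intensities of the cube itself. A constant
#' cube (zero range) maps to all zeros with a warning.
#'
#' @param cube 3D numeric array.
#' @param modality Optional modality tag recorded on the result.
#' @return A `NormalizedCube`: list with `voxels` in \[0,1\],
#'   `source_modality`, `x_min`, `x_max`, `case_id`.
#' @param case_id Lesion identifier carried through to fusion.
#' @export
minmax_normalize <- function(cube, modality = NULL, case_id = "case") {
  stopifnot(is.array(cube), length(dim(cube)) == 3)
  x_min <- min(cube); x_max <- max(cube)
  if (x_max == x_min) {
    warning("constant cube: normalizing to all zeros")
    v <- array(0, dim = dim(cube))
  } else {
    v <- (cube - x_min) / (x_max - x_min)
  }
  structure(list(voxels = v, source_modality = modality,
                 x_min = x_min, x_max = x_max, case_id = case_id),
            class = "NormalizedCube")
}

# The 2D Sobel is applied separably (smooth along one axis, central
# difference along the other) on a reflect-padded (edge replicated) image;
# the factorization is algebraically identical to the 3x3 kernels and makes
# constant regions exactly zero in floating point.

#' 2D Sobel gradient of an image
#'
#' Correlates the image with the 3x3 horizontal and vertical Sobel kernels
#' `Gx = [[-1,0,1],[-2,0,2],[-1,0,1]]` and `Gy = [[1,2,1],[0,0,0],
#' [-1,-2,-1]]` (rows indexing the first array dimension), using
#' edge-replicating reflect padding, and returns the gradient magnitude
#' `G = sqrt(Gx^2 + Gy^2)` and quadrant-aware direction
#' `theta = atan2(Gy, Gx)`.
#'
#' @param image 2D numeric matrix, at least 3x3.
#' @return List with `gx`, `gy`, `magnitude`, `direction`.
#' @export
sobel_gradient_2d <- function(image) {
  if (!is.matrix(image) || any(dim(image) < 3))
    stop("image smaller than the 3x3 kernel")
  nr <- nrow(image); nc <- ncol(image)
  p <- image[c(1L, 1:nr, nr), c(1L, 1:nc, nc)]
  # Gx = [1 2 1]' (x) [-1 0 1]: smooth down rows, difference across columns
  sr <- p[1:nr, ] + 2 * p[2:(nr + 1L), ] + p[3:(nr + 2L), ]
  gx <- sr[, 3:(nc + 2L)] - sr[, 1:nc]
  # Gy = [1 0 -1]' (x) [1 2 1]: difference down rows, smooth across columns
  dr <- p[1:nr, ] - p[3:(nr + 2L), ]
  gy <- dr[, 1:nc] + 2 * dr[, 2:(nc + 1L)] + dr[, 3:(nc + 2L)]
  list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2),
       direction = atan2(gy, gx))
}

# 1D [-1,0,1] difference / [1,2,1] smoothing along one axis of a 3D array,
# with edge-replicating padding
.axis_filter <- function(x, axis, taps) {
  d <- dim(x)
  idx_lo <- function(i) pmax(i, 1L)
  idx_hi <- function(i, n) pmin(i, n)
  n <- d[axis]
  slice <- function(i) {
    i <- idx_hi(idx_lo(i), n)
    switch(axis, x[i, , , drop = FALSE], x[, i, , drop = FALSE],
           x[, , i, drop = FALSE])
  }
  out <- taps[1] * slice(0:(n - 1)) + taps[2] * slice(1:n) +
         taps[3] * slice(2:(n + 1))
  out
}

#' Sobel gradient-magnitude channel of a normalized cube
#'
#' `slicewise_2d` (default) applies the printed 2D operator independently to
#' each slice along the third axis; `full_3d` uses the separable 3D
#' extension (derivative `[-1,0,1]` along one axis, smoothing `[1,2,1]`
#' along the two others, magnitude over the three axis gradients). The
#' magnitude image is min-max renormalized to \[0,1\] unless
#' `renormalize = FALSE`.
#'
#' @param cube A `NormalizedCube` (any side length is accepted).
#' @param mode `"slicewise_2d"` or `"full_3d"`.
#' @param renormalize Rescale the magnitude to \[0,1\] (default TRUE).
#' @return A `GradientChannels` object: list with `magnitude`, `direction`
#'   (slicewise theta; `NULL` in 3D mode), `mode`, `source_modality`.
#' @export
sobel_channel <- function(cube, mode = c("slicewise_2d", "full_3d"),
                          renormalize = TRUE) {
  stopifnot(inherits(cube, "NormalizedCube"))
  mode <- match.arg(mode)
  x <- cube$voxels
  d <- dim(x)
  if (mode == "slicewise_2d") {
    mag <- array(0, d); theta <- array(0, d)
    for (k in seq_len(d[3])) {
      g <- sobel_gradient_2d(x[, , k])
      mag[, , k] <- g$magnitude
      theta[, , k] <- g$direction
    }
  } else {
    sm <- c(1, 2, 1); df <- c(-1, 0, 1)
    gx <- .axis_filter(.axis_filter(.axis_filter(x, 1, df), 2, sm), 3, sm)
    gy <- .axis_filter(.axis_filter(.axis_filter(x, 1, sm), 2, df), 3, sm)
    gz <- .axis_filter(.axis_filter(.axis_filter(x, 1, sm), 2, sm), 3, df)
    mag <- sqrt(gx^2 + gy^2 + gz^2)
    theta <- NULL
  }
  if (renormalize) {
    rng <- range(mag)
    mag <- if (rng[2] > rng[1]) (mag - rng[1]) / (rng[2] - rng[1])
           else array(0, d)
  }
  structure(list(magnitude = mag, direction = theta, mode = mode,
                 source_modality = cube$source_modality),
            class = "GradientChannels")
}

#' Fuse normalized modality cubes (plus Sobel channels) into a model input
#'
#' Stacks the cubes along the channel dimension in the given order; with
#' `include_sobel`, each modality's Sobel gradient-magnitude channel is
#' appended after all intensity channels, so the channel count is
#' `C = M * (1 + include_sobel)` (the four-modality fused model has C = 8).
#'
#' @param cubes Ordered list of `NormalizedCube`s of one case, equal sides.
#' @param include_sobel Append one Sobel channel per modality.
#' @param label Optional class label (`"benign"`/`"malignant"`).
#' @param sobel_mode Passed to [sobel_channel()].
#' @return A `ModelInputTensor`: list with `channels` (side^3 x C array laid
#'   out as `dim = c(side, side, side, C)`), `channel_labels`, `case_id`,
#'   `label`.
#' @export
fuse_channels <- function(cubes, include_sobel = TRUE, label = NA_character_,
                          sobel_mode = "slicewise_2d") {
  stopifnot(length(cubes) >= 1,
            all(vapply(cubes, inherits, TRUE, "NormalizedCube")))
  ids <- unique(vapply(cubes, function(c) c$case_id, ""))
  if (length(ids) != 1) stop("mixed case_ids: ", paste(ids, collapse = ", "))
  dims <- lapply(cubes, function(c) dim(c$voxels))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("shape mismatch between cubes")
  side <- dims[[1]][1]
  mods <- vapply(cubes, function(c) c$source_modality %||% "mod", "")
  M <- length(cubes)
  C <- M * (1L + as.integer(include_sobel))
  channels <- array(0, dim = c(dims[[1]], C))
  labels <- character(C)
  for (m in seq_len(M)) {
    channels[, , , m] <- cubes[[m]]$voxels
    labels[m] <- mods[m]
  }
  if (include_sobel) {
    for (m in seq_len(M)) {
      channels[, , , M + m] <- sobel_channel(cubes[[m]], sobel_mode)$magnitude
      labels[M + m] <- paste0(mods[m], "_sobel")
    }
  }
  structure(list(channels = channels, channel_labels = labels,
                 case_id = ids, label = label),
            class = "ModelInputTensor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preprocess one case end to end
#'
#' Bounding cube from the mask, per-modality crop + resample, min-max
#' normalization, optional Sobel channels, channel fusion.
#'
#' @param volumes Named list of `ModalityVolume`s (names = modality tags,
#'   order = fusion order).
#' @param mask The case's `SegmentationMask`.
#' @param target_side Cube side after resampling (default 64).
#' @param include_sobel Append Sobel channels (default TRUE).
#' @param label Class label carried onto the tensor.
#' @param sobel_mode Passed to [sobel_channel()].
#' @return List: `tensor` (a `ModelInputTensor`) and `sidecar` (cube
#'   coordinates and per-modality normalization min/max, for audit).
#' @export
preprocess_case <- function(volumes, mask, target_side = 64L,
                            include_sobel = TRUE, label = NA_character_,
                            sobel_mode = "slicewise_2d") {
  cube <- compute_bounding_cube(mask, make_cube = TRUE)
  ncubes <- vector("list", length(volumes))
  norm_rec <- list()
  for (m in seq_along(volumes)) {
    vol <- volumes[[m]]
    arr <- crop_and_resample(vol, cube, target_side)
    ncubes[[m]] <- minmax_normalize(arr, modality = vol$modality,
                                    case_id = vol$case_id)
    norm_rec[[vol$modality]] <- list(x_min = ncubes[[m]]$x_min,
                                     x_max = ncubes[[m]]$x_max)
  }
  tensor <- fuse_channels(ncubes, include_sobel = include_sobel,
                          label = label, sobel_mode = sobel_mode)
  sidecar <- list(case_id = mask$case_id,
                  cube = list(min_index = cube$min_index,
                              max_index = cube$max_index,
                              cube_side = cube$cube_side),
                  normalization = norm_rec,
                  target_side = as.integer(target_side),
                  channel_labels = tensor$channel_labels)
  list(tensor = tensor, sidecar = sidecar)
}
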