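## Simplified volume-based analysis arm: rasterise surface time series to a
## 3-mm grid, smooth in 3D, analyse per voxel, and project back to a surface.

#' Rasterise per-vertex time series into an isotropic voxel grid
#'
#' Each voxel holds the mean time series of the vertices falling inside it;
#' voxels containing no vertex are missing. A shared reference grid (from the
#' template's folded mesh) keeps all subjects in one volumetric space, the
#' analog of scanner-space normalisation.
#'
#' @param folded a `folded_mesh` giving vertex coordinates in mm.
#' @param bold vertices x time matrix (a single column gives a 3D map).
#' @param voxel_size isotropic voxel edge in mm (default 3).
#' @param grid optional reference grid (a previous `volume_grid`) whose
#'   origin and dimensions are reused.
#' @return object of class `volume_grid`: `data` (occupied voxels x time),
#'   `voxel_ijk` (occupied voxel integer coordinates), `dim`, `origin`,
#'   `voxel_size`, `vertex_assignment` (vertex -> occupied-voxel row),
#'   `n_per_voxel`.
#' @export
rasterize_surface_timeseries <- function(folded, bold, voxel_size = 3,
                                         grid = NULL) {
  stopifnot(inherits(folded, "folded_mesh"))
  bold <- as.matrix(bold)
  V <- folded$vertices
  if (nrow(bold) != nrow(V)) stop("`bold` must have one row per vertex", call. = FALSE)
  if (is.null(grid)) {
    origin <- floor(apply(V, 2, min) / voxel_size) * voxel_size - voxel_size
    dims <- ceiling((apply(V, 2, max) - origin) / voxel_size) + 2
  } else {
    origin <- grid$origin; dims <- grid$dim; voxel_size <- grid$voxel_size
  }
  ijk <- floor(sweep(V, 2, origin) / voxel_size) + 1
  if (any(ijk < 1) || any(sweep(ijk, 2, dims) > 0)) {
    stop("vertices fall outside the reference grid", call. = FALSE)
  }
  lin <- ijk[, 1] + dims[1] * (ijk[, 2] - 1) + dims[1] * dims[2] * (ijk[, 3] - 1)
  occ <- sort(unique(lin))
  row_of <- match(lin, occ)
  counts <- tabulate(row_of, length(occ))
  data <- unname(rowsum(bold, row_of)) / counts
  k <- occ - 1
  vox_ijk <- cbind(
    k %% dims[1] + 1,
    (k %/% dims[1]) %% dims[2] + 1,
    k %/% (dims[1] * dims[2]) + 1
  )
  structure(
    list(data = data, voxel_ijk = vox_ijk, dim = dims, origin = origin,
         voxel_size = voxel_size, vertex_assignment = row_of,
         n_per_voxel = counts),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d occupied voxels (%s grid, %g mm), %d column(s)\n",
              nrow(x$voxel_ijk), paste(x$dim, collapse = "x"), x$voxel_size,
              ncol(x$data)))
  invisible(x)
}

#' 3D Gaussian smoothing of a (sparse) volume grid
#'
#' Separable Gaussian with `sigma = fwhm / 2.3548`; voxels without data are
#' excluded and the kernel weights renormalised over observed voxels, so
#' values are not attenuated at the edge of the sampled shell.
#'
#' @param grid a `volume_grid`.
#' @param fwhm kernel full width at half maximum in mm (default 3; 0 is the
#'   identity).
#' @return the smoothed `volume_grid`.
#' @export
gaussian_smooth_3d <- function(grid, fwhm = 3) {
  stopifnot(inherits(grid, "volume_grid"))
  if (fwhm < 0) stop("`fwhm` must be non-negative", call. = FALSE)
  if (fwhm == 0) return(grid)
  sigma <- fwhm / 2.3548 / grid$voxel_size      # in voxel units
  half <- max(1L, ceiling(3 * sigma))
  offs <- -half:half
  ijk <- grid$voxel_ijk
  dims <- grid$dim
  lin <- ijk[, 1] + dims[1] * (ijk[, 2] - 1) + dims[1] * dims[2] * (ijk[, 3] - 1)
  lookup <- new.env(hash = TRUE)
  occ_index <- seq_len(nrow(ijk))
  key <- match(lin, lin)   # identity, lin is unique
  num <- matrix(0, nrow(ijk), ncol(grid$data))
  den <- numeric(nrow(ijk))
  for (dx in offs) for (dy in offs) for (dz in offs) {
    w <- exp(-(dx^2 + dy^2 + dz^2) / (2 * sigma^2))
    if (w < 1e-8) next
    ni <- ijk[, 1] + dx; nj <- ijk[, 2] + dy; nk <- ijk[, 3] + dz
    ok <- ni >= 1 & ni <= dims[1] & nj >= 1 & nj <= dims[2] & nk >= 1 & nk <= dims[3]
    nlin <- ni + dims[1] * (nj - 1) + dims[1] * dims[2] * (nk - 1)
    hit <- match(nlin, lin)          # neighbour's occupied-row, NA if empty
    use <- ok & !is.na(hit)
    if (!any(use)) next
    num[use, ] <- num[use, , drop = FALSE] + w * grid$data[hit[use], , drop = FALSE]
    den[use] <- den[use] + w
  }
  grid$data <- num / den
  grid
}

#' Sample a volumetric map onto a surface along vertex normals
#'
#' Averages trilinear samples taken at `n_depths` equidistant offsets from
#' -1 mm to +3 mm along each vertex normal. Sample points in voxels without
#' data are dropped (weight renormalisation); vertices whose samples all fall
#' in empty space get `NA`.
#'
#' @param grid a `volume_grid` holding one value column (e.g. a t map).
#' @param folded the `folded_mesh` to sample onto.
#' @param depths sampling offsets in mm (default 9 equidistant steps in
#'   -1..+3).
#' @param column which data column to sample (default 1).
#' @return per-vertex numeric vector (NA where no data was available).
#' @export
project_volume_map_to_surface <- function(grid, folded,
                                          depths = seq(-1, 3, length.out = 9),
                                          column = 1) {
  stopifnot(inherits(grid, "volume_grid"), inherits(folded, "folded_mesh"))
  vals <- grid$data[, column]
  dims <- grid$dim
  lin_of <- function(i, j, k) i + dims[1] * (j - 1) + dims[1] * dims[2] * (k - 1)
  occ_lin <- lin_of(grid$voxel_ijk[, 1], grid$voxel_ijk[, 2], grid$voxel_ijk[, 3])
  n <- nrow(folded$vertices)
  acc <- numeric(n)
  wacc <- numeric(n)
  for (d in depths) {
    P <- folded$vertices + d * folded$normals
    # continuous voxel coordinates (voxel centers at integer coordinates)
    cc <- sweep(P, 2, grid$origin) / grid$voxel_size + 0.5
    f0 <- floor(cc)
    fr <- cc - f0
    val <- numeric(n)
    wt <- numeric(n)
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      i <- f0[, 1] + cx; j <- f0[, 2] + cy; k <- f0[, 3] + cz
      w8 <- (if (cx == 1) fr[, 1] else 1 - fr[, 1]) *
            (if (cy == 1) fr[, 2] else 1 - fr[, 2]) *
            (if (cz == 1) fr[, 3] else 1 - fr[, 3])
      ok <- i >= 1 & i <= dims[1] & j >= 1 & j <= dims[2] & k >= 1 & k <= dims[3]
      hit <- rep(NA_integer_, n)
      hit[ok] <- match(lin_of(i[ok], j[ok], k[ok]), occ_lin)
      use <- !is.na(hit) & w8 > 0
      val[use] <- val[use] + w8[use] * vals[hit[use]]
      wt[use] <- wt[use] + w8[use]
    }
    has <- wt > 0
    acc[has] <- acc[has] + val[has] / wt[has]
    wacc[has] <- wacc[has] + 1
  }
  out <- rep(NA_real_, n)
  out[wacc > 0] <- acc[wacc > 0] / wacc[wacc > 0]
  out
}

#' Write a volume grid as a NIfTI-1 file
#'
#' @param grid a `volume_grid`.
#' @param path output file path (.nii).
#' @param column data column to write (default all, as a 4D volume).
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(grid, path, column = NULL) {
  dims <- grid$dim
  cols <- if (is.null(column)) seq_len(ncol(grid$data)) else column
  arr <- array(NA_real_, c(dims, length(cols)))
  lin <- grid$voxel_ijk[, 1] + dims[1] * (grid$voxel_ijk[, 2] - 1) +
    dims[1] * dims[2] * (grid$voxel_ijk[, 3] - 1)
  for (ci in seq_along(cols)) {
    slab <- array(NA_real_, dims)
    slab[lin] <- grid$data[, cols[ci]]
    arr[, , , ci] <- slab
  }
  if (length(cols) == 1) arr <- arr[, , , 1]
  img <- RNifti::asNifti(arr, pixdim = rep(grid$voxel_size, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume into a `volume_grid`
#'
#' @param path a NIfTI file written by [write_volume_nifti()].
#' @param origin grid origin in mm (stored separately in the run manifest).
#' @param voxel_size isotropic voxel size in mm.
#' @return a `volume_grid` of the non-missing voxels.
#' @export
read_volume_nifti <- function(path, origin = c(0, 0, 0), voxel_size = 3) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 3) dim(arr) <- c(dim(arr), 1)
  dims <- dim(arr)[1:3]
  first <- arr[, , , 1]
  occ <- which(!is.na(first))
  k <- occ - 1
  vox_ijk <- cbind(k %% dims[1] + 1, (k %/% dims[1]) %% dims[2] + 1,
                   k %/% (dims[1] * dims[2]) + 1)
  data <- sapply(seq_len(dim(arr)[4]), function(t) arr[, , , t][occ])
  structure(
    list(data = as.matrix(data), voxel_ijk = vox_ijk, dim = dims,
         origin = origin, voxel_size = voxel_size,
         vertex_assignment = NULL, n_per_voxel = NULL),
    class = "volume_grid"
  )
}
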