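## Synthetic phantoms: dilution well arrays and an elliptical brain.

## snap an (x, y) position onto the nearest voxel of a grid
nearestVoxel <- function(x, y, gridDim, voxelSize) {
  ix <- round(x / voxelSize + (gridDim[1] + 1) / 2)
  iy <- round(y / voxelSize + (gridDim[2] + 1) / 2)
  if (ix < 1 || ix > gridDim[1] || iy < 1 || iy > gridDim[2])
    stop(sprintf("well position (%.1f, %.1f) mm falls outside the grid", x, y))
  c(ix, iy)
}

#' Dilution-series well phantom
#'
#' Point-like wells (one voxel each) holding a geometric dilution series
#' `topMass * dilutionFactor^(k-1)`, k = 1..nWells -- the layout of the 250,
#' 125, 62.5, 31.25, 15.6 ng five-well array at defaults.
#'
#' @param topMass Fe mass of the first well (ng)
#' @param nWells number of wells (>= 1)
#' @param dilutionFactor mass ratio between consecutive wells (default 0.5)
#' @param wellPositions two-column matrix (or list of length-2 vectors) of
#'   in-plane well positions (mm); defaults to a ring of radius 9 mm
#'   (a single well is placed at the center)
#' @param voxelSize voxel edge (mm, default 3)
#' @param gridDim in-plane grid dimensions (default 9 x 9, covering a 27 mm
#'   square inside the 30 mm FOV)
#' @return a [TracerMap-class] with one slice at z = 0
#' @examples
#' wellMasses(250, 5, 0.5)  # 250 125 62.5 31.25 15.625
#' ph <- makeDilutionPhantom(250, 5)
#' sum(tracerGrid(ph) > 0)  # 5 wells
#' @export
makeDilutionPhantom <- function(topMass, nWells, dilutionFactor = 0.5,
                                wellPositions = NULL, voxelSize = 3,
                                gridDim = c(9, 9)) {
  stopifnot(nWells >= 1, topMass >= 0, dilutionFactor > 0)
  masses <- wellMasses(topMass, nWells, dilutionFactor)
  if (is.null(wellPositions)) {
    if (nWells == 1L) wellPositions <- matrix(c(0, 0), 1)
    else {
      th <- 2 * pi * (seq_len(nWells) - 1) / nWells
      wellPositions <- cbind(9 * cos(th), 9 * sin(th))
    }
  }
  if (is.list(wellPositions)) wellPositions <- do.call(rbind, wellPositions)
  stopifnot(nrow(wellPositions) == nWells)
  grid <- array(0, dim = c(gridDim[1], gridDim[2], 1L))
  for (k in seq_len(nWells)) {
    ij <- nearestVoxel(wellPositions[k, 1], wellPositions[k, 2],
                       gridDim, voxelSize)
    grid[ij[1], ij[2], 1L] <- grid[ij[1], ij[2], 1L] + masses[k]
  }
  TracerMap(grid, voxelSize = c(voxelSize, voxelSize, voxelSize))
}

#' @rdname makeDilutionPhantom
#' @details `wellMasses()` returns just the mass series; a first-step mass
#'   different from `topMass * dilutionFactor` (as in a 24 ug undiluted stock
#'   followed by a 2 ug first dilution) can be produced by passing the first
#'   diluted mass as `topMass` and prepending the stock.
#' @export
wellMasses <- function(topMass, nWells, dilutionFactor = 0.5)
  topMass * dilutionFactor^(seq_len(nWells) - 1)

#' Elliptical brain phantom
#'
#' A uniform elliptical parenchyma region at `parenchymaMass` ng per voxel
#' (the 210 ng resting-brain value at defaults) with optional large-vessel
#' hotspot voxels at `vesselFactor` times the parenchymal content (large
#' vessels carry roughly 20-fold the blood volume of parenchyma).
#'
#' @param parenchymaMass Fe per parenchyma voxel (ng), >= 0
#' @param vesselPositions two-column matrix (or list) of in-plane vessel
#'   voxel positions (mm); may be empty
#' @param vesselFactor vessel-to-parenchyma content ratio (default 20)
#' @param semiAxes ellipse semi-axes (mm), default c(8, 11)
#' @param voxelSize voxel edge (mm, default 3)
#' @param gridDim in-plane grid dimensions (default 9 x 9)
#' @return a [TracerMap-class] with one slice at z = 0
#' @examples
#' ph <- makeBrainPhantom(210)
#' max(tracerGrid(ph))  # 210
#' @export
makeBrainPhantom <- function(parenchymaMass = 210, vesselPositions = NULL,
                             vesselFactor = 20, semiAxes = c(8, 11),
                             voxelSize = 3, gridDim = c(9, 9)) {
  stopifnot(parenchymaMass >= 0, vesselFactor >= 0)
  grid <- array(0, dim = c(gridDim[1], gridDim[2], 1L))
  cx <- (seq_len(gridDim[1]) - (gridDim[1] + 1) / 2) * voxelSize
  cy <- (seq_len(gridDim[2]) - (gridDim[2] + 1) / 2) * voxelSize
  inside <- outer(cx^2 / semiAxes[1]^2, cy^2 / semiAxes[2]^2, `+`) <= 1
  grid[, , 1L][inside] <- parenchymaMass
  if (!is.null(vesselPositions) && length(vesselPositions)) {
    if (is.list(vesselPositions)) vesselPositions <- do.call(rbind, vesselPositions)
    for (k in seq_len(nrow(vesselPositions))) {
      ij <- nearestVoxel(vesselPositions[k, 1], vesselPositions[k, 2],
                         gridDim, voxelSize)
      grid[ij[1], ij[2], 1L] <- vesselFactor * parenchymaMass
    }
  }
  TracerMap(grid, voxelSize = c(voxelSize, voxelSize, voxelSize))
}

#' Brain mask of a phantom
#'
#' Logical per-voxel indicator of nonzero tracer, flattened in the voxel
#' order used by [ImageSeries()] (x fastest).
#'
#' @param tracer a [TracerMap-class]
#' @param slice which z slice (default center)
#' @return logical vector of length nx*ny
#' @export
phantomMask <- function(tracer, slice = NULL) {
  d <- dim(tracer@grid)
  if (is.null(slice)) slice <- (d[3] + 1) %/% 2
  as.vector(tracer@grid[, , slice] > 0)
}
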