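#' Baseline tissue optical properties at 690 and 850 nm
#'
#' Literature absorption and reduced-scattering coefficients for the five
#' head-tissue types used throughout the simulation (scalp, skull,
#' cerebrospinal fluid, gray matter, white matter). The reduced scattering
#' coefficient already folds in the scattering anisotropy (g ~ 0.9 in
#' tissue), so it is the only scattering quantity carried.
#'
#' @param refractive_index Tissue refractive index (dimensionless), applied
#'   uniformly to all tissues.
#' @return A data.frame with columns `tissue`, `wavelength` (nm), `mua`
#'   (mm^-1), `musp` (mm^-1), `n`.
#' @export
tissue_optical_properties <- function(refractive_index = 1.4) {
  tissues <- c("scalp", "skull", "CSF", "gray", "white")
  tab <- data.frame(
    tissue = rep(tissues, times = 2),
    wavelength = rep(c(690, 850), each = 5),
    mua = c(0.0159, 0.0101, 0.0040, 0.0201, 0.0171,
            0.0190, 0.0139, 0.0040, 0.0192, 0.0208),
    musp = c(0.8000, 1.0000, 0.3000, 0.9727, 1.3333,
             0.6400, 0.8400, 0.3000, 0.6726, 1.0107),
    stringsAsFactors = FALSE
  )
  tab$n <- refractive_index
  tab
}

#' Look up optical properties for one tissue and wavelength
#'
#' @param tissue Tissue label (one of scalp, skull, CSF, gray, white).
#' @param wavelength Wavelength in nm (690 or 850).
#' @param table Property table as returned by [tissue_optical_properties()].
#' @return A list with `mua`, `musp`, `n`.
#' @export
get_tissue_property <- function(tissue, wavelength, table = tissue_optical_properties()) {
  row <- table[table$tissue == tissue & table$wavelength == wavelength, ]
  if (nrow(row) != 1L) {
    stop("no optical properties for tissue '", tissue, "' at ", wavelength, " nm")
  }
  list(mua = row$mua, musp = row$musp, n = row$n)
}

#' Tissue layer order used by the layered slab
#' @keywords internal
slab_tissues <- function() c("scalp", "skull", "CSF", "gray", "white")

#' Build a voxelized five-layer head slab phantom
#'
#' The phantom is a flat slab standing in for a patch of the head below a
#' high-density optode array: scalp, skull, CSF and gray-matter layers of
#' given thickness stacked from the optical surface (z = 0) downward, with
#' white matter filling the remaining depth. Voxels are isotropic; each voxel
#' takes the label of the layer containing its center. Depth is measured at
#' voxel centers below the top surface plane. The slab is treated as
#' laterally periodic (the lateral faces are domain truncation, not air);
#' only the top and bottom faces are optical boundaries.
#'
#' @param layer_thicknesses Named or ordered numeric vector of thicknesses in
#'   mm for scalp, skull, CSF and gray matter (white fills the rest).
#' @param lateral_extent Lateral size of the slab in mm (square footprint).
#' @param depth_extent Total slab depth in mm.
#' @param voxel_size Isotropic voxel edge in mm.
#' @param properties Optical property table ([tissue_optical_properties()]).
#' @param refractive_index Internal refractive index used for the boundary
#'   reflection parameter.
#' @return An object of class `dot_phantom`: voxel label array, grid
#'   geometry, depth map, tissue masks and the property table.
#' @export
build_layered_slab <- function(layer_thicknesses = c(scalp = 4, skull = 7, CSF = 2, gray = 4),
                               lateral_extent = 120,
                               depth_extent = 60,
                               voxel_size = 2,
                               properties = tissue_optical_properties(),
                               refractive_index = 1.4) {
  th <- as.numeric(layer_thicknesses)
  if (length(th) != 4L || any(!is.finite(th)) || any(th <= 0)) {
    stop("invalid geometry: need four positive layer thicknesses (scalp, skull, CSF, gray)")
  }
  if (lateral_extent <= 0 || depth_extent <= 0 || voxel_size <= 0) {
    stop("invalid geometry: extents and voxel size must be positive")
  }
  if (sum(th) >= depth_extent) {
    stop("invalid geometry: layers exceed slab depth; white matter must fill remaining depth")
  }
  h <- voxel_size
  nx <- as.integer(round(lateral_extent / h))
  nz <- as.integer(round(depth_extent / h))
  if (abs(nx * h - lateral_extent) > 1e-9 || abs(nz * h - depth_extent) > 1e-9) {
    stop("invalid geometry: voxel size must tile the slab extents")
  }
  ny <- nx

  zc <- (seq_len(nz) - 0.5) * h            # voxel-center depth below surface
  bounds <- cumsum(th)                      # layer interfaces in mm
  zlab <- findInterval(zc, bounds) + 1L     # 1..5, center-based assignment
  zlab[zlab > 5L] <- 5L
  if (!any(zlab == 5L)) stop("invalid geometry: no white-matter voxels remain")

  labels <- array(rep(zlab, each = nx * ny), dim = c(nx, ny, nz))

  structure(list(
    nx = nx, ny = ny, nz = nz, h = h,
    extent = c(lateral_extent, lateral_extent, depth_extent),
    tissues = slab_tissues(),
    labels = labels,
    layer_labels = zlab,
    layer_thicknesses = stats::setNames(th, slab_tissues()[1:4]),
    depth_z = zc,
    properties = properties,
    refractive_index = refractive_index
  ), class = "dot_phantom")
}

#' @export
print.dot_phantom <- function(x, ...) {
  cat("Layered slab phantom:", x$nx, "x", x$ny, "x", x$nz, "voxels @", x$h, "mm\n")
  cat("  extent:", paste(x$extent, collapse = " x "), "mm\n")
  counts <- table(factor(x$layer_labels, levels = 1:5, labels = x$tissues))
  cat("  z-layers per tissue:", paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Voxel-center physical coordinates (mm)
#'
#' @param phantom A `dot_phantom`.
#' @return List of coordinate vectors `x`, `y` (lateral) and `z` (depth).
#' @export
voxel_centers <- function(phantom) {
  list(x = (seq_len(phantom$nx) - 0.5) * phantom$h,
       y = (seq_len(phantom$ny) - 0.5) * phantom$h,
       z = phantom$depth_z)
}

#' Per-voxel depth map (mm below the optical surface)
#' @param phantom A `dot_phantom`.
#' @return 3D array of voxel-center depths.
#' @export
depth_map <- function(phantom) {
  array(rep(phantom$depth_z, each = phantom$nx * phantom$ny),
        dim = c(phantom$nx, phantom$ny, phantom$nz))
}

#' Brain mask (gray or white matter)
#' @param phantom A `dot_phantom`.
#' @return Logical 3D array.
#' @export
brain_mask <- function(phantom) {
  phantom$labels == 4L | phantom$labels == 5L
}

#' Surface mask (voxel layer facing the optical boundary)
#' @param phantom A `dot_phantom`.
#' @return Logical 3D array, TRUE on the top voxel layer.
#' @export
surface_mask <- function(phantom) {
  m <- array(FALSE, dim = c(phantom$nx, phantom$ny, phantom$nz))
  m[, , 1] <- TRUE
  m
}

#' Per-z-layer optical properties of the slab at one wavelength
#' @keywords internal
slab_layer_props <- function(phantom, wavelength) {
  props <- lapply(phantom$tissues, get_tissue_property,
                  wavelength = wavelength, table = phantom$properties)
  mua <- vapply(props, `[[`, numeric(1), "mua")[phantom$layer_labels]
  musp <- vapply(props, `[[`, numeric(1), "musp")[phantom$layer_labels]
  list(mua = mua, musp = musp)
}

#' Place an interleaved checkerboard source/detector array on the slab surface
#'
#' Sources and detectors alternate on a square lattice of the given pitch so
#' that the first four nearest-neighbor source-detector separations are
#' p, p*sqrt(5), 3p and p*sqrt(13) (13.00, 29.07, 39.00, 46.87 mm at the
#' default 13-mm pitch). The lattice is centered on the slab surface.
#'
#' @param pitch Lattice spacing in mm.
#' @param n_rows,n_cols Lattice dimensions.
#' @param phantom A `dot_phantom` whose top surface carries the array.
#' @return An object of class `dot_optodes` with `sources` and `detectors`
#'   data.frames (columns `id`, `x`, `y`, `z` in mm; z = 0 on the surface).
#' @export
place_checkerboard_array <- function(pitch = 13, n_rows = 7, n_cols = 7, phantom) {
  if (pitch <= 0 || n_rows < 1 || n_cols < 1) stop("invalid array geometry")
  Lx <- phantom$extent[1]; Ly <- phantom$extent[2]
  x0 <- (Lx - (n_cols - 1) * pitch) / 2
  y0 <- (Ly - (n_rows - 1) * pitch) / 2
  if (x0 < 0 || y0 < 0) {
    stop("out of bounds: array footprint exceeds the phantom surface")
  }
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  grid$x <- x0 + (grid$col - 1) * pitch
  grid$y <- y0 + (grid$row - 1) * pitch
  is_src <- (grid$col + grid$row) %% 2 == 0   # corner color -> sources
  src <- grid[is_src, c("x", "y")]
  det <- grid[!is_src, c("x", "y")]
  sources <- data.frame(id = seq_len(nrow(src)), x = src$x, y = src$y, z = 0)
  detectors <- data.frame(id = seq_len(nrow(det)), x = det$x, y = det$y, z = 0)
  structure(list(sources = sources, detectors = detectors, pitch = pitch,
                 n_rows = n_rows, n_cols = n_cols),
            class = "dot_optodes")
}

#' @export
print.dot_optodes <- function(x, ...) {
  cat("Checkerboard optode array:", nrow(x$sources), "sources,",
      nrow(x$detectors), "detectors, pitch", x$pitch, "mm\n")
  invisible(x)
}

#' Nominal nearest-neighbor separation centers (mm)
#' @keywords internal
nn_centers <- function() c(13, 29, 39, 47)

#' Enumerate source-detector channels up to a nearest-neighbor class
#'
#' Channels are source-detector pairs whose separation falls within +/- 1 mm
#' of the nominal class separations 13, 29, 39, 47 mm. Classes are
#' cumulative: `max_nn = 3` keeps first- through third-nearest neighbors
#' (a moderate-dynamic-range system), `max_nn = 4` adds the 47-mm channels
#' (strong dynamic range).
#'
#' @param array A `dot_optodes` object.
#' @param max_nn Highest class to include (3 or 4).
#' @param window Half-width of the class separation window in mm.
#' @return A `dot_channels` data.frame with columns `src`, `det`, `sep_mm`,
#'   `nn`, carrying `max_nn` as an attribute.
#' @export
enumerate_channels <- function(array, max_nn = 3, window = 1) {
  if (!max_nn %in% c(3L, 4L, 3, 4)) stop("max_nn must be 3 or 4")
  s <- array$sources; d <- array$detectors
  sep <- sqrt(outer(s$x, d$x, "-")^2 + outer(s$y, d$y, "-")^2)
  centers <- nn_centers()
  out <- vector("list", max_nn)
  for (k in seq_len(max_nn)) {
    hit <- which(abs(sep - centers[k]) <= window, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      out[[k]] <- data.frame(src = s$id[hit[, 1]], det = d$id[hit[, 2]],
                             sep_mm = sep[hit], nn = k)
    }
  }
  ch <- do.call(rbind, out)
  ch <- ch[order(ch$nn, ch$src, ch$det), ]
  rownames(ch) <- NULL
  attr(ch, "max_nn") <- as.integer(max_nn)
  class(ch) <- c("dot_channels", "data.frame")
  ch
}

#' Define the evaluation region of interest
#'
#' Voxels laterally at least `lateral_margin` inside the optode footprint
#' and, when a sensitivity volume is supplied, with summed baseline
#' intensity (fluence magnitude over all sources and detectors) at least
#' `sensitivity_floor` times its maximum. The floor reproduces the
#' "optically accessible" depth bound: with the default 1e-5 floor the ROI
#' reaches roughly 35 mm below the surface.
#'
#' @param phantom A `dot_phantom`.
#' @param array A `dot_optodes`.
#' @param lateral_margin Margin inside the optode footprint, mm.
#' @param sensitivity_floor Fraction of the sensitivity maximum below which
#'   voxels are excluded (0 disables the cut).
#' @param sensitivity Optional 3D volume (same grid) of summed baseline
#'   intensity; required when `sensitivity_floor > 0`.
#' @return Logical 3D mask.
#' @export
define_roi <- function(phantom, array, lateral_margin = 10,
                       sensitivity_floor = 1e-5, sensitivity = NULL) {
  cc <- voxel_centers(phantom)
  opt <- rbind(array$sources[, c("x", "y")], array$detectors[, c("x", "y")])
  xr <- range(opt$x) + c(lateral_margin, -lateral_margin)
  yr <- range(opt$y) + c(lateral_margin, -lateral_margin)
  inx <- cc$x >= xr[1] & cc$x <= xr[2]
  iny <- cc$y >= yr[1] & cc$y <= yr[2]
  mask <- array(outer(outer(inx, iny, "&"), rep(TRUE, phantom$nz), "&"),
                dim = c(phantom$nx, phantom$ny, phantom$nz))
  if (sensitivity_floor > 0) {
    if (is.null(sensitivity)) {
      stop("a summed sensitivity volume is required when sensitivity_floor > 0")
    }
    mask <- mask & (sensitivity >= sensitivity_floor * max(sensitivity))
  }
  if (!any(mask)) stop("degenerate ROI: no voxels satisfy the constraints")
  mask
}

#' Index a region of interest for reconstruction and metrics
#'
#' Flattens an ROI mask into the vectors the inversion and metric code use:
#' linear voxel indices, voxel-center coordinates, depths and tissue labels.
#'
#' @param phantom A `dot_phantom`.
#' @param mask Logical 3D ROI mask.
#' @return A `dot_roi` list: `idx`, `coords` (n x 3 mm), `depth`, `label`,
#'   `brain` (logical), `mask`, `n`, `voxel_volume` (mm^3).
#' @export
roi_index <- function(phantom, mask) {
  idx <- which(mask)
  dims <- dim(mask)
  ai <- arrayInd(idx, dims)
  cc <- voxel_centers(phantom)
  coords <- cbind(cc$x[ai[, 1]], cc$y[ai[, 2]], cc$z[ai[, 3]])
  lab <- phantom$labels[idx]
  structure(list(idx = idx, coords = coords, depth = coords[, 3],
                 label = lab, brain = lab >= 4L, mask = mask,
                 n = length(idx), voxel_volume = phantom$h^3),
            class = "dot_roi")
}

#' Write optode positions as TSV
#' @param array A `dot_optodes`.
#' @param path Output file.
#' @export
write_optodes_tsv <- function(array, path) {
  s <- cbind(type = "source", array$sources)
  d <- cbind(type = "detector", array$detectors)
  tab <- rbind(s, d)
  names(tab) <- c("type", "id", "x_mm", "y_mm", "z_mm")
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the channel list as TSV
#' @param channels A `dot_channels` data.frame.
#' @param path Output file.
#' @export
write_channels_tsv <- function(channels, path) {
  tab <- as.data.frame(channels)
  names(tab) <- c("src", "det", "sep_mm", "nn")
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
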