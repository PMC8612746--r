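# Frequency-domain photon diffusion forward model on the voxel grid.
#
# Working units: lengths in mm, time in ns, frequencies in MHz
# (converted internally to rad/ns). The discrete operator is
#   S = -div(D grad) + mua - i*omega/v    (D = 1/[3(mua+musp)], mm)
# discretized by flux balance with harmonic-mean face diffusivities,
# Robin (partial-current) boundaries on the top and bottom faces and
# periodic lateral boundaries. Fluence is source-normalized: the source
# stamp integrates to 1, so in an infinite homogeneous medium the solution
# approaches exp(-k r) / (4 pi D r), k = sqrt((mua - i omega/v)/D).

#' Speed of light in vacuum, mm/ns
#' @keywords internal
c0_mm_ns <- function() 299.792458

#' Angular modulation frequency in rad/ns from MHz
#' @keywords internal
omega_rad_ns <- function(frequency_mhz) 2 * pi * frequency_mhz * 1e-3

#' Effective internal reflection parameter for a refractive-index mismatch
#'
#' Polynomial fit for the effective reflection coefficient of the
#' tissue-air interface; `A = (1 + R_eff) / (1 - R_eff)` scales the
#' extrapolated boundary distance `z_b = 2 A D`.
#'
#' @param n_in Internal refractive index (external medium assumed 1.0).
#' @return The dimensionless boundary parameter A.
#' @export
boundary_A <- function(n_in = 1.4) {
  reff <- -1.440 / n_in^2 + 0.710 / n_in + 0.668 + 0.0636 * n_in
  (1 + reff) / (1 - reff)
}

#' Optical medium descriptors for one wavelength
#' @keywords internal
fd_medium <- function(phantom, wavelength) {
  lp <- slab_layer_props(phantom, wavelength)
  n <- phantom$refractive_index
  v <- c0_mm_ns() / n
  Dm <- 1 / (3 * (lp$mua + lp$musp))
  list(mua = lp$mua, musp = lp$musp, Dm = Dm, v = v, n = n)
}

#' Infinite-medium frequency-domain Green's function
#'
#' Closed-form fluence at distance `r` from a unit point source in a
#' homogeneous medium: `exp(-k_eff r) / (4 pi D_m r)` with
#' `k_eff = sqrt((mua - i omega/v) / D_m)` taking the root with positive
#' real part. At `omega = 0` this reduces to the continuous-wave kernel
#' `exp(-r sqrt(3 mua (mua + musp))) / (4 pi D_m r)`.
#'
#' @param props List with `mua`, `musp` (mm^-1) and `n`.
#' @param r Source-field distance(s), mm; must be positive.
#' @param frequency Modulation frequency in MHz.
#' @return Complex fluence (vectorized over `r`).
#' @export
greens_homogeneous <- function(props, r, frequency = 0) {
  if (any(r <= 0)) stop("singularity: r must be positive")
  v <- c0_mm_ns() / props$n
  Dm <- 1 / (3 * (props$mua + props$musp))
  omega <- omega_rad_ns(frequency)
  k <- sqrt(complex(real = props$mua, imaginary = -omega / v) / Dm)
  exp(-k * r) / (4 * pi * Dm * r)
}

#' Semi-infinite-medium Green's function by image sources
#'
#' Extrapolated-boundary construction: the physical isotropic source sits
#' at depth `1/musp` below the surface point; a negative image source is
#' mirrored about the extrapolated boundary plane at height `z_b = 2 A D_m`
#' above the surface. The fluence vanishes on the extrapolated plane.
#'
#' @param props List with `mua`, `musp`, `n`.
#' @param source_surface_point Numeric (x, y, z) of the surface launch
#'   point; its z is the surface plane (depth measured along +z into the
#'   medium).
#' @param field_point Numeric (x, y, z) of the evaluation point.
#' @param frequency Modulation frequency, MHz.
#' @return Complex fluence.
#' @export
greens_semi_infinite <- function(props, source_surface_point, field_point, frequency = 0) {
  z0 <- 1 / props$musp
  Dm <- 1 / (3 * (props$mua + props$musp))
  zb <- 2 * boundary_A(props$n) * Dm
  zs <- source_surface_point[3]
  real_src <- c(source_surface_point[1:2], zs + z0)
  img_src <- c(source_surface_point[1:2], zs - z0 - 2 * zb)
  r1 <- sqrt(sum((field_point - real_src)^2))
  r2 <- sqrt(sum((field_point - img_src)^2))
  greens_homogeneous(props, r1, frequency) - greens_homogeneous(props, r2, frequency)
}

#' Trilinear source/detector stamp on the voxel grid
#'
#' Represents a point at continuous position (x, y, z) as trilinear weights
#' on the 8 surrounding voxel centers (periodic lateral wrap, clamped in
#' depth). Used both to inject sources and to read out fluence, so that
#' source-detector reciprocity holds exactly in the discrete model.
#'
#' @param phantom A `dot_phantom`.
#' @param x,y Lateral position, mm.
#' @param z Depth below the surface, mm.
#' @return A `dot_stamp` list with per-axis indices and weights.
#' @export
make_stamp <- function(phantom, x, y, z) {
  h <- phantom$h
  axis_weights <- function(u, nvox, periodic) {
    ui <- u / h + 0.5              # continuous voxel index
    i0 <- floor(ui)
    t <- ui - i0
    idx <- c(i0, i0 + 1)
    w <- c(1 - t, t)
    if (periodic) {
      idx <- ((idx - 1) %% nvox) + 1
    } else {
      if (idx[1] < 1) { idx <- c(1, 1); w <- c(1, 0) }
      if (idx[2] > nvox) { idx <- c(nvox, nvox); w <- c(1, 0) }
    }
    list(idx = as.integer(idx), w = w)
  }
  sx <- axis_weights(x, phantom$nx, TRUE)
  sy <- axis_weights(y, phantom$ny, TRUE)
  sz <- axis_weights(z, phantom$nz, FALSE)
  structure(list(ix = sx$idx, wx = sx$w, iy = sy$idx, wy = sy$w,
                 iz = sz$idx, wz = sz$w, pos = c(x, y, z)),
            class = "dot_stamp")
}

#' Linear voxel indices and weights of a stamp
#' @keywords internal
stamp_entries <- function(phantom, stamp) {
  nx <- phantom$nx; ny <- phantom$ny
  gi <- expand.grid(a = 1:2, b = 1:2, c = 1:2)
  idx <- stamp$ix[gi$a] + (stamp$iy[gi$b] - 1L) * nx +
    (stamp$iz[gi$c] - 1L) * nx * ny
  w <- stamp$wx[gi$a] * stamp$wy[gi$b] * stamp$wz[gi$c]
  keep <- w > 0
  list(idx = idx[keep], w = w[keep])
}

#' Read out a fluence field at a trilinear stamp
#'
#' @param phantom A `dot_phantom`.
#' @param field Complex or numeric 3D field array.
#' @param stamp A `dot_stamp`.
#' @return The stamp-weighted field value (the discrete measurement).
#' @export
measure_stamp <- function(phantom, field, stamp) {
  se <- stamp_entries(phantom, stamp)
  sum(field[se$idx] * se$w)
}

#' Depth of the isotropic-source representation of a surface optode
#'
#' One reduced-scattering mean free path (`1/musp`) into the top tissue
#' layer at the given wavelength.
#'
#' @param phantom A `dot_phantom`.
#' @param wavelength 690 or 850 nm.
#' @return Depth below the surface, mm.
#' @export
optode_source_depth <- function(phantom, wavelength) {
  1 / get_tissue_property(phantom$tissues[phantom$layer_labels[1]],
                          wavelength, phantom$properties)$musp
}

# ---------------------------------------------------------------------------
# Fast solver for layered media: 2D lateral DFT + complex tridiagonal in z.
# Solves exactly the same discrete system as the sparse solver below when the
# medium is laterally uniform (which the layered slab is).
# ---------------------------------------------------------------------------

#' Vertical stencil coefficients shared by both solvers
#' @keywords internal
fd_z_coeffs <- function(phantom, med, omega) {
  h <- phantom$h
  nz <- phantom$nz
  Dz <- med$Dm       # per z-layer
  muaz <- med$mua
  gz <- h * 2 * Dz[-nz] * Dz[-1] / (Dz[-nz] + Dz[-1])    # vertical face conductance
  glat <- h * Dz                                          # lateral face conductance
  A <- boundary_A(med$n)
  gtop <- h^2 * 2 * Dz[1] / (h + 4 * A * Dz[1])           # Robin, z_b = 2 A D
  gbot <- h^2 * 2 * Dz[nz] / (h + 4 * A * Dz[nz])
  mass <- complex(real = muaz * h^3, imaginary = -omega / med$v * h^3)
  list(gz = gz, glat = glat, gtop = gtop, gbot = gbot, mass = mass)
}

#' Vectorized Thomas solve of the per-mode tridiagonal systems
#' @keywords internal
thomas_modes <- function(b, a, cc, r) {
  # b: nmode x nz complex diagonal; a, cc: length-nz sub/super (a[1], cc[nz]
  # unused); r: length-nz RHS (same for all modes). Returns nmode x nz.
  nz <- ncol(b)
  cp <- matrix(0i, nrow(b), nz)
  dp <- matrix(0i, nrow(b), nz)
  cp[, 1] <- cc[1] / b[, 1]
  dp[, 1] <- r[1] / b[, 1]
  for (z in 2:nz) {
    den <- b[, z] - a[z] * cp[, z - 1]
    cp[, z] <- cc[z] / den
    dp[, z] <- (r[z] - a[z] * dp[, z - 1]) / den
  }
  u <- matrix(0i, nrow(b), nz)
  u[, nz] <- dp[, nz]
  for (z in (nz - 1):1) u[, z] <- dp[, z] - cp[, z] * u[, z + 1]
  u
}

#' Solve the frequency-domain diffusion equation in the layered slab
#'
#' Spectral solver for laterally uniform (layered) media: a 2D discrete
#' Fourier transform over the periodic lateral axes reduces the voxel
#' system to one complex tridiagonal solve in depth per lateral mode. The
#' solution is exact (to round-off) for the same finite-difference operator
#' used by [solve_fd_diffusion()], at a tiny fraction of the cost, and is
#' the solver used by the frequency sweep.
#'
#' @param phantom A `dot_phantom` (layered).
#' @param wavelength 690 or 850 (nm).
#' @param frequency Modulation frequency, MHz.
#' @param stamps List of `dot_stamp` sources.
#' @param extract_idx Optional linear voxel indices; when given, a complex
#'   matrix `length(extract_idx) x length(stamps)` is returned instead of
#'   full field arrays.
#' @return List of complex 3D fluence arrays, or a complex matrix.
#' @export
solve_layered <- function(phantom, wavelength, frequency, stamps, extract_idx = NULL) {
  nx <- phantom$nx; ny <- phantom$ny; nz <- phantom$nz
  med <- fd_medium(phantom, wavelength)
  omega <- omega_rad_ns(frequency)
  zc <- fd_z_coeffs(phantom, med, omega)

  mx <- 2 - 2 * cos(2 * pi * (0:(nx - 1)) / nx)
  my <- 2 - 2 * cos(2 * pi * (0:(ny - 1)) / ny)
  mu <- outer(mx, rep(1, ny)) + outer(rep(1, nx), my)     # nx x ny

  gzl <- c(0, zc$gz); gzr <- c(zc$gz, 0)
  diag_z <- zc$mass + gzl + gzr
  diag_z[1] <- diag_z[1] + zc$gtop
  diag_z[nz] <- diag_z[nz] + zc$gbot
  a <- c(0, -zc$gz)        # sub-diagonal, a[z] couples z-1 -> z
  cc <- c(-zc$gz, 0)       # super-diagonal

  # group stamps by depth profile (optodes share one; internal sources differ)
  zkey <- vapply(stamps, function(s) paste(s$iz, signif(s$wz, 12), collapse = ","), "")
  groups <- split(seq_along(stamps), zkey)

  nmode <- nx * ny
  muv <- as.vector(mu)
  out <- vector("list", length(stamps))
  need_matrix <- !is.null(extract_idx)
  if (need_matrix) {
    res <- matrix(0i, length(extract_idx), length(stamps))
  }

  px <- 0:(nx - 1); py <- 0:(ny - 1)
  for (g in groups) {
    s_z <- numeric(nz)
    st0 <- stamps[[g[1]]]
    s_z[st0$iz] <- s_z[st0$iz] + st0$wz
    b <- matrix(0i, nmode, nz)
    for (z in seq_len(nz)) b[, z] <- zc$glat[z] * muv + diag_z[z]
    U <- thomas_modes(b, a, cc, s_z)

    for (si in g) {
      st <- stamps[[si]]
      ex <- st$wx[1] * exp(-2i * pi * px * (st$ix[1] - 1) / nx) +
            st$wx[2] * exp(-2i * pi * px * (st$ix[2] - 1) / nx)
      ey <- st$wy[1] * exp(-2i * pi * py * (st$iy[1] - 1) / ny) +
            st$wy[2] * exp(-2i * pi * py * (st$iy[2] - 1) / ny)
      slat <- outer(ex, ey)
      field <- array(0i, dim = c(nx, ny, nz))
      for (z in seq_len(nz)) {
        plane <- matrix(U[, z], nx, ny) * slat
        field[, , z] <- stats::fft(plane, inverse = TRUE) / nmode
      }
      if (need_matrix) res[, si] <- field[extract_idx] else out[[si]] <- field
    }
  }
  if (need_matrix) res else out
}

# ---------------------------------------------------------------------------
# General sparse finite-difference solver (arbitrary voxelwise absorption),
# used for validation and for the brute-force perturbation oracle.
# ---------------------------------------------------------------------------

#' Assemble the sparse finite-difference operator
#' @keywords internal
fd_operator <- function(phantom, wavelength, dmua = NULL) {
  nx <- phantom$nx; ny <- phantom$ny; nz <- phantom$nz
  h <- phantom$h
  med <- fd_medium(phantom, wavelength)
  Dv <- array(rep(med$Dm, each = nx * ny), dim = c(nx, ny, nz))
  muav <- array(rep(med$mua, each = nx * ny), dim = c(nx, ny, nz))
  if (!is.null(dmua)) muav <- muav + dmua
  N <- nx * ny * nz
  vox <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add_faces <- function(v1, v2, g) {
    ii <<- c(ii, v1, v2, v1, v2)
    jj <<- c(jj, v2, v1, v1, v2)
    xx <<- c(xx, -g, -g, g, g)
  }
  harm <- function(a, b) 2 * a * b / (a + b)

  idx <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  # x faces (periodic)
  i2 <- ifelse(idx$i == nx, 1L, idx$i + 1L)
  g <- h * harm(Dv[cbind(idx$i, idx$j, idx$k)], Dv[cbind(i2, idx$j, idx$k)])
  add_faces(vox(idx$i, idx$j, idx$k), vox(i2, idx$j, idx$k), g)
  # y faces (periodic)
  j2 <- ifelse(idx$j == ny, 1L, idx$j + 1L)
  g <- h * harm(Dv[cbind(idx$i, idx$j, idx$k)], Dv[cbind(idx$i, j2, idx$k)])
  add_faces(vox(idx$i, idx$j, idx$k), vox(idx$i, j2, idx$k), g)
  # z faces (no wrap)
  zi <- idx[idx$k < nz, ]
  g <- h * harm(Dv[cbind(zi$i, zi$j, zi$k)], Dv[cbind(zi$i, zi$j, zi$k + 1L)])
  add_faces(vox(zi$i, zi$j, zi$k), vox(zi$i, zi$j, zi$k + 1L), g)

  Sr <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
  A <- boundary_A(med$n)
  dg <- as.vector(muav) * h^3
  top <- which(idx$k == 1L)
  bot <- which(idx$k == nz)
  dg[top] <- dg[top] + h^2 * 2 * Dv[cbind(idx$i[top], idx$j[top], 1L)] /
    (h + 4 * A * Dv[cbind(idx$i[top], idx$j[top], 1L)])
  dg[bot] <- dg[bot] + h^2 * 2 * Dv[cbind(idx$i[bot], idx$j[bot], nz)] /
    (h + 4 * A * Dv[cbind(idx$i[bot], idx$j[bot], nz)])
  Sr <- Sr + Matrix::Diagonal(N, dg)
  s_imag <- -h^3 / med$v   # times omega gives the imaginary diagonal
  list(Sr = Sr, s_imag = s_imag, N = N, med = med)
}

#' Solve the frequency-domain diffusion equation on the voxel grid
#'
#' General-purpose finite-difference solver: the complex system
#' `(Sr + i omega s I) phi = q` is solved as an equivalent real block
#' system by sparse LU. Handles arbitrary voxelwise absorption
#' perturbations (`dmua`), which is what the brute-force Jacobian oracle
#' needs; for the unperturbed layered slab it agrees with [solve_layered()]
#' to round-off. The relative residual of every solve is checked against
#' `tol` (default 1e-8) and a numerical-failure error is raised otherwise.
#'
#' @param phantom A `dot_phantom`.
#' @param stamps A `dot_stamp` or list of stamps (unit sources).
#' @param frequency Modulation frequency, MHz.
#' @param wavelength 690 or 850 nm.
#' @param dmua Optional 3D array of absorption perturbations (mm^-1) added
#'   to the absorption mass term (diffusion coefficients held at baseline,
#'   matching the no-scattering-change linearization).
#' @param tol Maximum admissible relative residual.
#' @return A complex 3D fluence array (or list of arrays for several
#'   stamps) with attribute `residual`.
#' @export
solve_fd_diffusion <- function(phantom, stamps, frequency = 0, wavelength = 850,
                               dmua = NULL, tol = 1e-8) {
  if (frequency < 0) stop("frequency must be non-negative")
  single <- inherits(stamps, "dot_stamp")
  if (single) stamps <- list(stamps)
  op <- fd_operator(phantom, wavelength, dmua)
  N <- op$N
  omega <- omega_rad_ns(frequency)
  Q <- matrix(0, N, length(stamps))
  for (s in seq_along(stamps)) {
    se <- stamp_entries(phantom, stamps[[s]])
    Q[se$idx, s] <- Q[se$idx, s] + se$w
  }
  # The real part Sr of the complex operator Sr + i*s*I is symmetric positive
  # definite, so the complex solve reduces to two sparse Cholesky solves:
  # (Sr^2 + s^2 I) u = Sr q, then Sr v = -s u.
  Sr <- Matrix::forceSymmetric(op$Sr)
  if (omega == 0) {
    ch <- Matrix::Cholesky(Sr, LDL = FALSE)
    sol <- as.matrix(Matrix::solve(ch, Q, system = "A"))
    resid <- max(sqrt(colSums(as.matrix(Sr %*% sol - Q)^2))) /
      max(sqrt(colSums(Q^2)))
    phi <- sol + 0i
  } else {
    si <- omega * op$s_imag
    Sr2 <- Matrix::forceSymmetric(Sr %*% Sr + Matrix::Diagonal(N, si^2))
    ch2 <- Matrix::Cholesky(Sr2, LDL = FALSE)
    chS <- Matrix::Cholesky(Sr, LDL = FALSE)
    u <- as.matrix(Matrix::solve(ch2, as.matrix(Sr %*% Q), system = "A"))
    v <- as.matrix(Matrix::solve(chS, -si * u, system = "A"))
    ru <- as.matrix(Sr %*% u) - si * v - Q
    rv <- si * u + as.matrix(Sr %*% v)
    resid <- max(sqrt(colSums(ru^2 + rv^2))) / max(sqrt(colSums(Q^2)))
    phi <- u + 1i * v
  }
  if (!is.finite(resid) || resid > tol) {
    stop("numerical failure: relative residual ", signif(resid, 3),
         " exceeds tolerance ", tol)
  }
  fields <- lapply(seq_along(stamps), function(s) {
    f <- array(phi[, s], dim = c(phantom$nx, phantom$ny, phantom$nz))
    attr(f, "residual") <- resid
    f
  })
  if (single) fields[[1]] else fields
}

#' Summed baseline fluence magnitude over all optodes
#'
#' The "Green's-function fall-off in intensity for all sources and
#' detectors": the voxelwise sum of |fluence| from every optode position,
#' evaluated with the continuous-wave forward model and summed over
#' wavelengths. [define_roi()] thresholds this volume at a small fraction
#' of its maximum to bound the optically accessible depth.
#'
#' @param phantom A `dot_phantom`.
#' @param array A `dot_optodes`.
#' @param wavelengths Wavelengths to sum over.
#' @return 3D volume, normalized to maximum 1.
#' @export
summed_baseline_intensity <- function(phantom, array, wavelengths = c(690, 850)) {
  pos <- rbind(array$sources[, c("x", "y")], array$detectors[, c("x", "y")])
  acc <- array(0, dim = c(phantom$nx, phantom$ny, phantom$nz))
  for (wl in wavelengths) {
    z0 <- optode_source_depth(phantom, wl)
    stamps <- lapply(seq_len(nrow(pos)), function(i)
      make_stamp(phantom, pos$x[i], pos$y[i], z0))
    fields <- solve_layered(phantom, wl, 0, stamps)
    for (f in fields) acc <- acc + abs(Re(f))
  }
  acc / max(acc)
}
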