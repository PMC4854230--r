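# Density maps: MRC/CCP4 I/O, model-derived density simulation, B-factor
# sharpening and global cross-correlation.

#' Construct a density grid
#'
#' A 3-D scalar field stored as an R array of dim `(nx, ny, nz)` with the x
#' index fastest, matching the on-disk MRC column order after axis
#' normalisation.  `origin` is the position (Angstrom) of the center of
#' voxel `[1,1,1]`.
#'
#' @param values numeric 3-D array.
#' @param spacing voxel spacing, Angstrom per voxel (length 1 or 3).
#' @param origin position of the first voxel center (length 3).
#' @param resolution_hint nominal map resolution in Angstrom, or `NA`.
#' @export
density_grid <- function(values, spacing = 1, origin = c(0, 0, 0),
                         resolution_hint = NA_real_) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L, all(spacing > 0), all(is.finite(origin)))
  if (!all(is.finite(values))) stop("non-finite density values")
  x <- list(values = values, dims = dim(values), spacing = spacing,
            origin = origin, resolution_hint = resolution_hint)
  class(x) <- "density_grid"
  x
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("density_grid: %d x %d x %d voxels, spacing %.3g/%.3g/%.3g A, origin (%.2f, %.2f, %.2f)\n",
              x$dims[1L], x$dims[2L], x$dims[3L], x$spacing[1L], x$spacing[2L],
              x$spacing[3L], x$origin[1L], x$origin[2L], x$origin[3L]))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(a$dims, b$dims) && all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Construct a voxel index set
#'
#' A set of voxel indices into a specific grid, stored as 1-based linear
#' indices (deduplicated, sorted).
#'
#' @param idx integer vector of linear indices, or a 3-column matrix of
#'   (ix, iy, iz) voxel indices.
#' @param grid the `density_grid` the indices refer to.
#' @export
grid_index_set <- function(idx, grid) {
  d <- grid$dims
  if (is.matrix(idx)) {
    stopifnot(ncol(idx) == 3L)
    if (any(idx < 1L) || any(idx[, 1L] > d[1L]) || any(idx[, 2L] > d[2L]) ||
        any(idx[, 3L] > d[3L]))
      stop("voxel indices out of grid bounds")
    idx <- idx[, 1L] + d[1L] * ((idx[, 2L] - 1L) + d[2L] * (idx[, 3L] - 1L))
  }
  idx <- as.integer(idx)
  if (length(idx) && (min(idx) < 1L || max(idx) > prod(d)))
    stop("linear voxel indices out of grid bounds")
  x <- list(idx = sort(unique(idx)), dims = d)
  class(x) <- "grid_index_set"
  x
}

# ---------------------------------------------------------------------------
# MRC/CCP4 I/O (2014 dialect).  No installed package reads MRC, so the
# 1024-byte header is parsed here directly.

read_mrc_header <- function(con, endian) {
  ints1 <- readBin(con, "integer", 10L, size = 4L, endian = endian)
  cella <- readBin(con, "numeric", 3L, size = 4L, endian = endian)
  cellb <- readBin(con, "numeric", 3L, size = 4L, endian = endian)
  axmap <- readBin(con, "integer", 3L, size = 4L, endian = endian)
  dstats <- readBin(con, "numeric", 3L, size = 4L, endian = endian)
  ispg <- readBin(con, "integer", 2L, size = 4L, endian = endian)
  readBin(con, "raw", 100L)                       # extra words 26-49
  orig <- readBin(con, "numeric", 3L, size = 4L, endian = endian)
  maptag <- rawToChar(readBin(con, "raw", 4L))
  readBin(con, "raw", 4L)                         # machst
  rms <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  nlabl <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  readBin(con, "raw", 800L)
  list(nc = ints1[1L], nr = ints1[2L], ns = ints1[3L], mode = ints1[4L],
       start = ints1[5:7], m = ints1[8:10], cella = cella,
       mapcrs = axmap, origin = orig, maptag = maptag, nsymbt = ispg[2L],
       rms = rms, nlabl = nlabl)
}

#' Read an MRC/CCP4 density map
#'
#' Axis order is normalised to x-fastest on read.  The origin is taken from
#' the ORIGIN header record when non-zero, otherwise from
#' NXSTART/NYSTART/NZSTART times the voxel spacing.  Modes 2 (32-bit float)
#' and 1 (16-bit int) are accepted.
#'
#' @param path file path.
#' @return a `density_grid`.
#' @export
read_mrc <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024) stop("not an MRC file (shorter than its header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_mrc_header(con, "little")
  endian <- "little"
  if (hdr$mode < 0L || hdr$mode > 16L || hdr$nc <= 0L || hdr$nc > 1e7) {
    seek(con, 0L)
    hdr <- read_mrc_header(con, "big")
    endian <- "big"
  }
  nvox <- as.numeric(hdr$nc) * hdr$nr * hdr$ns
  if (nvox <= 0) stop("MRC header declares non-positive dimensions")
  if (!(hdr$mode %in% c(1L, 2L)))
    stop("unsupported MRC mode ", hdr$mode,
         " (only 32-bit float and 16-bit int are read)")
  bpv <- if (hdr$mode == 2L) 4L else 2L
  expected <- 1024 + max(0L, hdr$nsymbt) + nvox * bpv
  if (sz < expected)
    stop("MRC data block smaller than the header-declared size (",
         sz, " < ", expected, " bytes)")
  if (hdr$nsymbt > 0L) readBin(con, "raw", hdr$nsymbt)
  vals <- if (hdr$mode == 2L)
    readBin(con, "numeric", nvox, size = 4L, endian = endian)
  else
    as.numeric(readBin(con, "integer", nvox, size = 2L, endian = endian,
                       signed = TRUE))
  arr <- array(vals, dim = c(hdr$nc, hdr$nr, hdr$ns))
  mapcrs <- hdr$mapcrs
  if (!setequal(mapcrs, 1:3)) mapcrs <- 1:3
  ## permute (columns, rows, sections) -> (x, y, z)
  perm <- match(1:3, mapcrs)
  arr <- aperm(arr, perm)
  spacing <- ifelse(hdr$m > 0, hdr$cella / hdr$m, 1)
  start_axis <- hdr$start[perm]
  origin <- if (any(abs(hdr$origin) > 1e-6)) hdr$origin
            else start_axis * spacing
  density_grid(arr, spacing = spacing, origin = origin)
}

#' Write a density grid as an MRC/CCP4 map (mode 2)
#' @param grid a `density_grid`.
#' @param path output path.
#' @export
write_mrc <- function(grid, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- grid$dims
  v <- as.numeric(grid$values)
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(c(d, 2L, 0L, 0L, 0L, d))
  wf(d * grid$spacing)
  wf(c(90, 90, 90))
  wi(1:3)
  wf(c(min(v), max(v), mean(v)))
  wi(c(1L, 0L))
  writeBin(raw(100L), con)
  wf(grid$origin)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)
  wf(stats::sd(v) * sqrt((length(v) - 1) / length(v)))
  wi(0L)
  writeBin(raw(800L), con)
  writeBin(v, con, size = 4L, endian = "little")
  invisible(path)
}

# ---------------------------------------------------------------------------
# model-derived density

ELEMENT_Z <- c(H = 1, C = 6, N = 7, O = 8, NA. = 11, MG = 12, P = 15, S = 16,
               CL = 17, K = 19, CA = 20, MN = 25, FE = 26, ZN = 30, SE = 34)

atomic_numbers <- function(elements) {
  key <- toupper(elements)
  key[key == "NA"] <- "NA."
  z <- ELEMENT_Z[key]
  if (any(is.na(z))) {
    bad <- unique(elements[is.na(z)])
    warning("unknown element(s) ", paste(bad, collapse = ", "),
            "; using carbon weight")
    z[is.na(z)] <- 6
  }
  unname(z)
}

#' Bounding grid for a structure
#' @param structure a `model_structure`.
#' @param spacing voxel spacing, Angstrom.
#' @param pad margin added around the model, Angstrom.
#' @return an all-zero `density_grid` covering the model.
#' @export
bounding_grid <- function(structure, spacing = 1, pad = 6) {
  xyz <- coords(structure)
  spacing <- rep_len(spacing, 3L)
  lo <- floor((apply(xyz, 2L, min) - pad) / spacing) * spacing
  hi <- apply(xyz, 2L, max) + pad
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  density_grid(array(0, dims), spacing = spacing, origin = lo)
}

#' Simulate model-derived density
#'
#' Each atom contributes an isotropic Gaussian of integral equal to its
#' atomic number, with real-space width `sigma = sigma_factor * resolution`
#' (default 0.356, so the Fourier transform falls to half its maximum at a
#' spatial frequency of 1/resolution), truncated at a per-axis box of
#' `3 sigma`.
#'
#' @param structure a `model_structure`.
#' @param resolution target resolution in Angstrom (> 0).
#' @param spacing voxel spacing used when no grid is supplied.
#' @param grid optional `density_grid` whose geometry the output must share
#'   (required for voxel-wise SMOC/CCC against that grid).
#' @param sigma_factor Gaussian width per Angstrom of resolution.
#' @param pad margin for the automatic bounding grid.
#' @return a `density_grid` of non-negative model density.
#' @export
simulate_density <- function(structure, resolution, spacing = 1, grid = NULL,
                             sigma_factor = 0.356, pad = 6) {
  if (!is.numeric(resolution) || resolution <= 0)
    stop("resolution must be positive")
  if (is.null(grid)) grid <- bounding_grid(structure, spacing, pad = pad)
  sigma <- sigma_factor * resolution
  xyz <- coords(structure)
  lo <- grid$origin - 3 * sigma
  hi <- grid$origin + (grid$dims - 1L) * grid$spacing + 3 * sigma
  outside <- xyz[, 1L] < lo[1L] | xyz[, 2L] < lo[2L] | xyz[, 3L] < lo[3L] |
    xyz[, 1L] > hi[1L] | xyz[, 2L] > hi[2L] | xyz[, 3L] > hi[3L]
  if (any(outside))
    warning(sum(outside), " atom(s) outside the grid plus margin; ",
            "their contribution is clipped")
  w <- atomic_numbers(structure$atoms$element)
  rho <- .simulate_density_cpp(xyz, w, as.integer(grid$dims), grid$origin,
                               grid$spacing, sigma, 3)
  density_grid(array(rho, grid$dims), spacing = grid$spacing,
               origin = grid$origin, resolution_hint = resolution)
}

# ---------------------------------------------------------------------------
# sharpening and global correlation

#' Sharpen (or blur) a map by a B factor
#'
#' Scales Fourier amplitudes by `exp(-B s^2 / 4)` where `s` is the spatial
#' frequency magnitude in 1/Angstrom; negative `b_factor` sharpens.  The
#' zero-frequency term is unscaled, so the mean density is preserved.
#'
#' @param grid a `density_grid`.
#' @param b_factor B factor in Angstrom^2.
#' @return the rescaled `density_grid`.
#' @export
sharpen_map <- function(grid, b_factor) {
  if (b_factor == 0) return(grid)
  d <- grid$dims
  freq <- function(n, sp) {
    k <- 0:(n - 1L)
    k[k > n %/% 2] <- k[k > n %/% 2] - n
    k / (n * sp)
  }
  fx <- freq(d[1L], grid$spacing[1L])
  fy <- freq(d[2L], grid$spacing[2L])
  fz <- freq(d[3L], grid$spacing[3L])
  s2 <- outer(outer(fx^2, fy^2, `+`), fz^2, `+`)
  ft <- stats::fft(grid$values)
  out <- Re(stats::fft(ft * exp(-b_factor * s2 / 4), inverse = TRUE)) / prod(d)
  density_grid(out, spacing = grid$spacing, origin = grid$origin,
               resolution_hint = grid$resolution_hint)
}

#' Add Gaussian noise to a map
#'
#' Seeded additive white Gaussian noise, the only experimental-map artefact
#' the synthetic benchmarks emulate.
#'
#' @param grid a `density_grid`.
#' @param sd noise standard deviation, in map units.
#' @param seed integer seed.
#' @return the noisy `density_grid`.
#' @export
add_map_noise <- function(grid, sd, seed = 1L) {
  stopifnot(sd >= 0)
  set.seed(as.integer(seed))
  density_grid(grid$values +
                 array(stats::rnorm(prod(grid$dims), sd = sd), grid$dims),
               spacing = grid$spacing, origin = grid$origin,
               resolution_hint = grid$resolution_hint)
}

#' Global cross-correlation between two maps
#'
#' Mean-subtracted Pearson correlation over the mask (default: whole grid).
#' Invariant under positive affine rescaling of either map, in contrast to
#' [smoc_segment()], which is sensitive to additive offsets.
#'
#' @param grid_a,grid_b `density_grid` objects on identical geometry.
#' @param mask optional `grid_index_set` restricting the correlation.
#' @return correlation in `[-1, 1]`.
#' @export
global_ccc <- function(grid_a, grid_b, mask = NULL) {
  if (!same_geometry(grid_a, grid_b))
    stop("grids do not share geometry (dims/spacing/origin)")
  a <- as.numeric(grid_a$values)
  b <- as.numeric(grid_b$values)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "grid_index_set"))
    if (!identical(mask$dims, grid_a$dims))
      stop("mask was built for a different grid")
    a <- a[mask$idx]
    b <- b[mask$idx]
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in one of the maps over the mask")
  stats::cor(a, b)
}
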