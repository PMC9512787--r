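#' Density maps
#'
#' A density map is a 3D grid of real values on an isotropic lattice:
#' `grid` (array, physical X,Y,Z axis order), `voxel` (Angstrom) and
#' `origin` (physical coordinate of the first voxel centre, Angstrom).
#'
#' @param grid 3D numeric array
#' @param voxel voxel edge in Angstrom (> 0)
#' @param origin length-3 coordinate of grid\[1,1,1\]
#' @return an object of class `density_map`
#' @export
density_map <- function(grid, voxel, origin = c(0, 0, 0)) {
  stopifnot(length(dim(grid)) == 3, voxel > 0, length(origin) == 3)
  if (any(dim(grid) < 2)) stop("grid needs >= 2 voxels per axis", call. = FALSE)
  if (!all(is.finite(grid))) stop("non-finite map values", call. = FALSE)
  structure(list(grid = grid, voxel = as.numeric(voxel),
                 origin = as.numeric(origin)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<density_map> %d x %d x %d voxels @ %.3f A, origin (%.2f, %.2f, %.2f)\n",
              d[1], d[2], d[3], x$voxel, x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  values in [%.4g, %.4g]\n", min(x$grid), max(x$grid)))
  invisible(x)
}

#' Read / write MRC (CCP4 2014) density maps
#'
#' Minimal MRC2014 support: mode 2 (32-bit float) maps, little-endian.
#' On read, the axis order recorded in the header (`MAPC`/`MAPR`/`MAPS`)
#' is normalised to physical X,Y,Z; the origin is taken from the
#' `ORIGIN` record when set, else from `NXSTART`-style offsets. Only
#' isotropic voxels are supported. `voxel_override` replaces the header
#' voxel size (e.g. a recalibrated pixel size for a deposited
#' negative-stain map).
#'
#' @param path file path
#' @param voxel_override optional voxel size in Angstrom replacing the
#'   header value
#' @return a [density_map()]
#' @export
read_map <- function(path, voxel_override = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nxyz <- hdr_int[1:3]
  mode <- hdr_int[4]
  if (any(nxyz <= 0) || any(nxyz > 4096)) {
    stop("corrupt or truncated MRC header in '", path, "'", call. = FALSE)
  }
  if (mode != 2) {
    stop("unsupported MRC mode ", mode, " (only mode 2 float)", call. = FALSE)
  }
  nstart <- hdr_int[5:7]
  mxyz <- hdr_int[8:10]
  cella <- hdr_num[11:13]
  mapcrs <- hdr_int[17:19]
  nsymbt <- hdr_int[24]
  origin_rec <- hdr_num[50:52]
  if (!all(sort(mapcrs) == 1:3)) {
    stop("cannot normalise axis order MAPC/MAPR/MAPS = ",
         paste(mapcrs, collapse = ","), call. = FALSE)
  }
  vox_axes <- cella / mxyz
  if (any(!is.finite(vox_axes)) ||
      diff(range(vox_axes)) > 1e-3 * mean(vox_axes)) {
    stop("anisotropic voxel size not supported", call. = FALSE)
  }
  voxel <- mean(vox_axes)
  seek(con, 1024 + nsymbt)
  nvox <- prod(nxyz)
  vals <- readBin(con, "numeric", n = nvox, size = 4, endian = "little")
  if (length(vals) != nvox) {
    stop("truncated MRC data in '", path, "'", call. = FALSE)
  }
  f <- array(vals, dim = nxyz)              # file axis order (c, r, s)
  perm <- match(1:3, mapcrs)                # physical axis -> file axis
  g <- aperm(f, perm)
  nstart_xyz <- nstart[perm]
  if (!is.null(voxel_override)) voxel <- voxel_override
  origin <- if (any(abs(origin_rec) > 1e-6)) {
    origin_rec
  } else {
    nstart_xyz * voxel
  }
  density_map(g, voxel, origin)
}

#' @rdname read_map
#' @param m a [density_map()]
#' @export
write_map <- function(m, path) {
  g <- m$grid
  d <- dim(g)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                       # NX NY NZ
  wi(2)                       # MODE float32
  wi(c(0, 0, 0))              # NXSTART
  wi(d)                       # MX MY MZ
  wf(d * m$voxel)             # CELLA
  wf(c(90, 90, 90))           # CELLB
  wi(1:3)                     # MAPC MAPR MAPS
  wf(c(min(g), max(g), mean(g)))
  wi(1)                       # ISPG
  wi(0)                       # NSYMBT
  wi(rep(0, 25))              # EXTRA (words 26-49, incl. EXTTYP slot)
  wf(m$origin)                # ORIGIN (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(g))            # RMS
  wi(0)                       # NLABL
  writeBin(raw(800), con)     # labels
  wf(as.vector(g))
  invisible(path)
}

# element -> atomic number, for amplitude weighting
atomic_number <- function(elesy) {
  z <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, FE = 26, ZN = 30)
  out <- z[toupper(trimws(elesy))]
  out[is.na(out)] <- 6
  unname(out)
}

#' Simulate a density map from an atomic model
#'
#' Sums per-atom isotropic Gaussians on a regular grid, the standard way
#' a model is converted into density for rigid-body docking and
#' cross-correlation scoring at a stated resolution. The Gaussian width
#' is `sigma = resolution * sigma_factor`; the default `sigma_factor`
#' `1/(pi*sqrt(2))` matches the convention of the common visualisation
#' tools, which is what one must use to compare correlation values with
#' fits performed there. Amplitudes are proportional to atomic number
#' (uniform for Calpha-only models, which are all carbon).
#'
#' @param s atom table
#' @param resolution target resolution in Angstrom
#' @param voxel_size grid spacing (default `resolution / 3`)
#' @param pad box padding beyond the model extent (default
#'   `2 * resolution`)
#' @param sigma_factor Gaussian width per unit resolution
#' @return a [density_map()]
#' @export
simulate_map <- function(s, resolution = 8,
                         voxel_size = resolution / 3,
                         pad = 2 * resolution,
                         sigma_factor = 1 / (pi * sqrt(2))) {
  if (nrow(s) == 0) stop("empty structure", call. = FALSE)
  if (resolution <= 2 * voxel_size) {
    stop("resolution must exceed twice the voxel size (sampling)",
         call. = FALSE)
  }
  xyz <- coords(s)
  amp <- atomic_number(s$elesy)
  sigma <- resolution * sigma_factor
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  d <- pmax(2L, as.integer(ceiling((hi - lo) / voxel_size)) + 1L)
  g <- array(0, dim = d)
  ax <- lapply(1:3, function(k) lo[k] + (seq_len(d[k]) - 1) * voxel_size)
  cut <- 4 * sigma
  for (i in seq_len(nrow(xyz))) {
    rng <- lapply(1:3, function(k) {
      which(abs(ax[[k]] - xyz[i, k]) <= cut)
    })
    if (any(lengths(rng) == 0)) next
    gx <- exp(-(ax[[1]][rng[[1]]] - xyz[i, 1])^2 / (2 * sigma^2))
    gy <- exp(-(ax[[2]][rng[[2]]] - xyz[i, 2])^2 / (2 * sigma^2))
    gz <- exp(-(ax[[3]][rng[[3]]] - xyz[i, 3])^2 / (2 * sigma^2))
    g[rng[[1]], rng[[2]], rng[[3]]] <-
      g[rng[[1]], rng[[2]], rng[[3]]] +
      amp[i] * (gx %o% gy %o% gz)
  }
  density_map(g, voxel_size, lo)
}

# trilinear interpolation of map values at physical points (N x 3);
# points outside the grid give `outside` (default 0)
interp_map <- function(m, pts, outside = 0) {
  d <- dim(m$grid)
  u <- sweep(pts, 2, m$origin) / m$voxel     # 0-based fractional index
  i0 <- floor(u)
  f <- u - i0
  ok <- i0[, 1] >= 0 & i0[, 2] >= 0 & i0[, 3] >= 0 &
    i0[, 1] <= d[1] - 2 & i0[, 2] <= d[2] - 2 & i0[, 3] <= d[3] - 2
  out <- rep(outside, nrow(pts))
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE] + 1          # 1-based lower corner
  f <- f[ok, , drop = FALSE]
  g <- m$grid
  idx <- function(dx, dy, dz) {
    g[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  v <-
    idx(0, 0, 0) * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
    idx(1, 0, 0) * f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) +
    idx(0, 1, 0) * (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) +
    idx(0, 0, 1) * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
    idx(1, 1, 0) * f[, 1] * f[, 2] * (1 - f[, 3]) +
    idx(1, 0, 1) * f[, 1] * (1 - f[, 2]) * f[, 3] +
    idx(0, 1, 1) * (1 - f[, 1]) * f[, 2] * f[, 3] +
    idx(1, 1, 1) * f[, 1] * f[, 2] * f[, 3]
  out[ok] <- v
  out
}

# physical coordinates of every voxel centre of a map (N x 3)
grid_points <- function(m) {
  d <- dim(m$grid)
  as.matrix(expand.grid(
    x = m$origin[1] + (seq_len(d[1]) - 1) * m$voxel,
    y = m$origin[2] + (seq_len(d[2]) - 1) * m$voxel,
    z = m$origin[3] + (seq_len(d[3]) - 1) * m$voxel
  ))
}

#' Cross-correlation between two density maps
#'
#' Pearson correlation (about the mean) between two maps on a common
#' grid: `b` is interpolated trilinearly onto `a`'s grid. The default
#' mask restricts the comparison to voxels where the resampled `b`
#' exceeds 1% of its maximum, so empty box regions do not dilute the
#' coefficient; `"overlap"` uses every voxel of `a`'s grid that falls
#' inside `b`'s box.
#'
#' @param a,b [density_map()] objects
#' @param mask `"above_threshold"` (default) or `"overlap"`
#' @param threshold_frac mask threshold as a fraction of the resampled
#'   maximum
#' @return correlation coefficient in `[-1, 1]`
#' @export
cross_correlation <- function(a, b, mask = c("above_threshold", "overlap"),
                              threshold_frac = 0.01) {
  mask <- match.arg(mask)
  pts <- grid_points(a)
  bv <- interp_map(b, pts, outside = NA_real_)
  av <- as.vector(a$grid)
  inside <- !is.na(bv)
  keep <- if (mask == "above_threshold") {
    mx <- max(bv[inside], 0)
    inside & bv >= threshold_frac * mx
  } else {
    inside
  }
  if (sum(keep) < 2) stop("no overlapping voxels", call. = FALSE)
  if (stats::sd(av[keep]) == 0 || stats::sd(bv[keep]) == 0) {
    stop("zero variance in masked region", call. = FALSE)
  }
  stats::cor(av[keep], bv[keep])
}

# pose parameterisation for fitting: p = (rotation vector [rad], shift
# [A]); rotation applied about the model centroid, shift added after
pose_to_transform <- function(p, center) {
  th <- sqrt(sum(p[1:3]^2))
  R <- if (th < 1e-12) diag(3) else rotation_matrix(p[1:3] / th, th * 180 / pi)
  t <- as.numeric(center - R %*% center) + p[4:6]
  rigid_transform(R, t)
}

# deterministic axis-angle rotation grid: lat/long axis grid at
# `step` degrees plus angles step..180, identity included
rotation_grid <- function(step) {
  axes <- list(c(0, 0, 1))
  lat <- seq(step, 180 - step / 2, by = step)
  for (th in lat) {
    n_lon <- max(1L, round(360 * sin(th * pi / 180) / step))
    for (ph in seq(0, 360 - 1e-9, length.out = n_lon + 1)[seq_len(n_lon)]) {
      axes[[length(axes) + 1]] <-
        c(sin(th * pi / 180) * cos(ph * pi / 180),
          sin(th * pi / 180) * sin(ph * pi / 180),
          cos(th * pi / 180))
    }
  }
  angles <- seq(step, 180, by = step)
  rots <- list(c(0, 0, 0))
  for (ax in axes) {
    for (an in angles) {
      rots[[length(rots) + 1]] <- ax * an * pi / 180
    }
  }
  rots
}

#' Rigid-body fit of a model into a density map
#'
#' Places an atomic model into a density map as a rigid body and scores
#' the placement by cross-correlation between the target map and a map
#' simulated from the posed model at the stated resolution. With
#' `search = NULL` only deterministic local refinement from the identity
#' placement is performed (the model is assumed pre-positioned); with a
#' search specification, an exhaustive coarse grid over rotations
#' (uniform axis-angle grid) and translations is scanned using a fast
#' interpolated-density score, and the best candidates are refined
#' locally against the full cross-correlation. Deterministic for fixed
#' parameters.
#'
#' @param s atom table
#' @param m target [density_map()]
#' @param resolution simulation resolution in Angstrom (default 8)
#' @param search `NULL` for local-only, or a list with `rot_step_deg`
#'   (default 15), `trans_range` (Angstrom, default `2 * resolution`),
#'   `trans_step` (default `resolution / 2`)
#' @param top_k number of coarse candidates refined locally
#' @param sigma_factor passed to [simulate_map()]
#' @return an object of class `fit_result`: `transform`, `cc`,
#'   `cc_identity`, `trace` (tibble of refined candidates)
#' @export
rigid_fit <- function(s, m, resolution = 8, search = NULL, top_k = 5,
                      sigma_factor = 1 / (pi * sqrt(2))) {
  ca <- ca_atoms(s)
  if (nrow(ca) < 3) ca <- s
  xyz <- coords(ca)
  center <- colMeans(xyz)
  cc_of <- function(tf) {
    posed <- apply_transform(s, tf)
    sim <- simulate_map(posed, resolution = resolution,
                        voxel_size = m$voxel, pad = resolution,
                        sigma_factor = sigma_factor)
    cross_correlation(m, sim)
  }
  proxy <- function(p) {
    tf <- pose_to_transform(p, center)
    mean(interp_map(m, apply_transform(xyz, tf)))
  }
  starts <- list(rep(0, 6))
  if (!is.null(search)) {
    rot_step <- search$rot_step_deg %||% 15
    trans_range <- search$trans_range %||% (2 * resolution)
    trans_step <- search$trans_step %||% (resolution / 2)
    rots <- rotation_grid(rot_step)
    # recentre the model on the density centre of mass as search origin
    w <- pmax(as.vector(m$grid), 0)
    com <- colSums(grid_points(m) * w) / sum(w)
    base_shift <- com - center
    # stage 1: rotations at the centred position
    sc1 <- purrr::map_dbl(rots, function(r) proxy(c(r, base_shift)))
    keep_r <- order(sc1, decreasing = TRUE)[seq_len(min(20, length(rots)))]
    # stage 2: translation grid around the centred position
    tg <- seq(-trans_range, trans_range, by = trans_step)
    shifts <- as.matrix(expand.grid(tg, tg, tg))
    cand <- list(); cand_sc <- numeric(0)
    for (k in keep_r) {
      sc2 <- purrr::map_dbl(seq_len(nrow(shifts)), function(i) {
        proxy(c(rots[[k]], base_shift + shifts[i, ]))
      })
      b <- which.max(sc2)
      cand[[length(cand) + 1]] <- c(rots[[k]], base_shift + shifts[b, ])
      cand_sc <- c(cand_sc, sc2[b])
    }
    starts <- cand[order(cand_sc, decreasing = TRUE)[
      seq_len(min(top_k, length(cand)))]]
    starts <- c(starts, list(rep(0, 6)))   # identity always considered
  }
  refine <- function(p0) {
    opt <- stats::optim(p0, function(p) -cc_of(pose_to_transform(p, center)),
                        method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-8))
    list(p = opt$par, cc = -opt$value)
  }
  refined <- purrr::map(starts, refine)
  trace <- tibble::tibble(
    candidate = seq_along(refined),
    cc = purrr::map_dbl(refined, "cc"))
  best <- refined[[which.max(trace$cc)]]
  cc_id <- cc_of(rigid_transform())
  if (cc_id > best$cc) best <- list(p = rep(0, 6), cc = cc_id)
  structure(
    list(transform = pose_to_transform(best$p, center),
         cc = best$cc, cc_identity = cc_id, trace = trace,
         resolution = resolution),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> cc = %.4f (identity placement: %.4f)\n",
              x$cc, x$cc_identity))
  print(x$transform)
  invisible(x)
}

#' Fraction of a model covered by density
#'
#' Flags, per residue, whether the Calpha atom sits in density at or
#' above a contour level — the map-side view of model segments "not
#' covered by the density", which indicates local flexibility.
#'
#' @param s atom table
#' @param m [density_map()]
#' @param contour contour level (same units as the map values)
#' @return a list: `fraction` (covered fraction of Calpha atoms),
#'   `residues` (tibble `chain`, `resno`, `density`, `covered`)
#' @export
coverage <- function(s, m, contour) {
  ca <- ca_atoms(s)
  vals <- interp_map(m, coords(ca), outside = -Inf)
  res <- tibble::tibble(chain = ca$chain, resno = ca$resno,
                        density = vals, covered = vals >= contour)
  list(fraction = mean(res$covered), residues = res)
}
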