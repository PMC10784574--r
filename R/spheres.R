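#' Configuration of the Gaussian-sphere benchmark
#'
#' Describes the synthetic five-frame "wormhole" phantom: a 3D Gaussian blob
#' of amplitude `100/sqrt(2*pi)` and unit standard deviation whose center
#' drifts by 0.8 per axis per frame along the main diagonal, whose central
#' ball (radius 1.5 about the current center) is scaled by `1 + a_i` with
#' gain factors `a = (0, 0.1, 0.2, 0.1, 0)` to imitate mass gain then loss,
#' and whose frames `i = 1..4` are smoothed with a Gaussian filter of
#' standard deviation `(i + 1) * sqrt(0.2)` voxels to imitate diffusion.
#'
#' The blob lives in continuous coordinates; voxel index `i` maps to
#' coordinate `(i - origin_index) * scale` per axis. The default scale
#' `10 / n1` and origin index `ceiling(0.36 * n1)` place the five centers
#' (0 to 3.2 per axis) and about three standard deviations of every blob
#' inside the box, landing the centers exactly on grid points at the default
#' 50-voxel extent.
#'
#' @param n Per-axis voxel count of the cubic grid (default 50).
#' @param gain_factors Center-region scaling factors, one per frame.
#' @param drift Center displacement per axis per frame (coordinate units).
#' @param amplitude Peak of the unsmoothed, unscaled blob.
#' @param indicator_radius Radius (coordinate units) of the center ball.
#' @param smoothing_std Per-frame smoothing standard deviations (voxels).
#' @param scale Coordinate units per voxel.
#' @param origin_index Voxel index mapped to coordinate 0.
#' @return An object of class `uromt_sphere_config`.
#' @export
sphere_config <- function(n = 50L,
                          gain_factors = c(0, 0.1, 0.2, 0.1, 0),
                          drift = 0.8,
                          amplitude = 100 / sqrt(2 * pi),
                          indicator_radius = 1.5,
                          smoothing_std = seq_along(gain_factors) * sqrt(0.2),
                          scale = 10 / n,
                          origin_index = ceiling(0.36 * n)) {
  stopifnot(n >= 4, indicator_radius > 0, all(smoothing_std >= 0), scale > 0)
  smoothing_std[1L] <- 0  # the first frame is never smoothed
  structure(list(n = as.integer(n), frames = length(gain_factors),
                 gain_factors = gain_factors, drift = drift,
                 amplitude = amplitude, indicator_radius = indicator_radius,
                 smoothing_std = smoothing_std, scale = scale,
                 origin_index = origin_index),
            class = "uromt_sphere_config")
}

# continuous coordinates of all cell centers under the config's mapping
sphere_coordinates <- function(cfg, grid) {
  idx <- cell_index_triples(grid)
  (idx - cfg$origin_index) * cfg$scale
}

# evaluate the frame-i blob (0-based frame index) on the coordinate matrix
gaussian_blob <- function(cfg, coords, frame) {
  ctr <- cfg$drift * frame
  d2 <- (coords[, 1] - ctr)^2 + (coords[, 2] - ctr)^2 + (coords[, 3] - ctr)^2
  cfg$amplitude * exp(-d2 / 2)
}

# radius ball indicator about the frame-f (possibly fractional) center
sphere_indicator <- function(cfg, coords, frame) {
  ctr <- cfg$drift * frame
  d2 <- (coords[, 1] - ctr)^2 + (coords[, 2] - ctr)^2 + (coords[, 3] - ctr)^2
  as.numeric(d2 <= cfg$indicator_radius^2)
}

# separable Gaussian smoothing of a flattened volume: truncated kernel
# (radius 4 std), renormalized, reflective borders; std in voxels
gaussian_smooth <- function(grid, field, std) {
  if (std <= 0) return(field)
  radius <- max(1L, ceiling(4 * std))
  kern <- exp(-(seq(-radius, radius))^2 / (2 * std^2))
  kern <- kern / sum(kern)
  arr <- array(field, dim = c(grid$n1, grid$n2, grid$n3))
  for (a in 1:3) {
    ext <- dim(arr)[a]
    if (ext < 2L) next
    # reflective (symmetric) padding indices
    pad <- c(rev(seq_len(min(radius, ext))), seq_len(ext),
             ext + 1L - seq_len(min(radius, ext)))
    while (length(pad) < ext + 2L * radius) # tiny extents: re-reflect
      pad <- c(pad[1L], pad, pad[length(pad)])
    arr <- apply_along_axis(arr, a, function(line) {
      padded <- line[pad]
      as.numeric(stats::filter(padded, kern, sides = 2))[radius + seq_len(ext)]
    })
  }
  as.vector(arr)
}

# apply a vector function along one axis of a 3D array
apply_along_axis <- function(arr, a, fn) {
  d <- dim(arr)
  perm <- switch(a, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  inv <- order(perm)
  tmp <- aperm(arr, perm)
  mat <- matrix(tmp, nrow = dim(tmp)[1])
  mat <- apply(mat, 2, fn)
  aperm(array(mat, dim = dim(tmp)), inv)
}

#' Generate the five Gaussian-sphere frames
#'
#' Builds the benchmark frames: frame `i` (0-based) samples the drifting
#' blob, scales the radius-1.5 center ball by `1 + a_i`, and smooths with
#' the frame's standard deviation. Also returns a per-pair indicator
#' generator: for the pair carrying frame `i` to `i + 1`, substep `j` of `m`
#' uses the ball translated linearly to center `0.8 * (i + j/m)` per axis.
#'
#' @param cfg A [sphere_config()].
#' @return List with `frames` (list of flattened volumes), `grid` (the
#'   matching [grid_spec()], unit spacings), `indicator_for(pair, j, m)`
#'   (function returning the substep ball indicator; `pair` 1-based, `j`
#'   from 0), and `pair_indicators(pair, m)` (list of the `m` substep
#'   indicators of one pair).
#' @export
gaussian_sphere_frames <- function(cfg = sphere_config()) {
  grid <- grid_spec(cfg$n, cfg$n, cfg$n)
  coords <- sphere_coordinates(cfg, grid)
  # warn when the box cannot hold the blobs (3 std about the last center)
  span <- (cfg$n - cfg$origin_index) * cfg$scale
  if (cfg$drift * (cfg$frames - 1) + 3 > span ||
      (cfg$origin_index - 1) * cfg$scale < 3)
    warning("grid too small to contain the spheres; blobs are truncated")
  frames <- lapply(seq_len(cfg$frames) - 1L, function(i) {
    g <- gaussian_blob(cfg, coords, i)
    g <- (1 + cfg$gain_factors[i + 1L] * sphere_indicator(cfg, coords, i)) * g
    gaussian_smooth(grid, g, cfg$smoothing_std[i + 1L])
  })
  indicator_for <- function(pair, j, m) {
    sphere_indicator(cfg, coords, (pair - 1L) + j / m)
  }
  pair_indicators <- function(pair, m) {
    lapply(seq_len(m) - 1L, function(j) indicator_for(pair, j, m))
  }
  list(frames = frames, grid = grid, config = cfg,
       indicator_for = indicator_for, pair_indicators = pair_indicators)
}

#' Two-frame benchmark with an unrestricted indicator
#'
#' The first two sphere frames with an all-ones indicator, the setting where
#' the relative source is free to act everywhere and the fitted source is
#' negative where the blob departs and positive where it arrives.
#'
#' @param cfg A [sphere_config()].
#' @return List with `rho0`, `rho1`, `chi` (all-ones), `grid`, `config`.
#' @export
translated_pair <- function(cfg = sphere_config()) {
  gen <- gaussian_sphere_frames(cfg)
  list(rho0 = gen$frames[[1L]], rho1 = gen$frames[[2L]],
       chi = rep.int(1, gen$grid$n), grid = gen$grid, config = cfg)
}
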