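#' Solver parameters
#'
#' Physical and numerical parameters of the free-end-point transport problem:
#' the diffusion coefficient `sigma`, the Fisher-Rao source weight `alpha`,
#' the end-point mismatch weight `beta`, and the Gauss-Newton / inner-solver
#' settings.
#'
#' @param sigma Diffusion coefficient (length^2 per time, >= 0).
#' @param alpha Weight of the source penalty (> 0). Large `alpha` suppresses
#'   the relative source and recovers the balanced (mass-conserving) limit.
#' @param beta Weight of the terminal image mismatch (>= 0; a zero weight
#'   drops the fitting term, which is degenerate for fitting but useful for
#'   diagnostics of the remaining terms).
#' @param max_iter Maximum Gauss-Newton iterations per image pair.
#' @param pcg_tol,pcg_maxiter Relative-residual tolerance and iteration cap
#'   of the inner preconditioned conjugate-gradient solve. Loose inner solves
#'   are standard for Gauss-Newton.
#' @param damping Levenberg-style regularization of the inner solve: the
#'   conjugate-gradient operator is `H + lambda I` with
#'   `lambda = damping * max(diag H)`. Bounds the step in near-empty voxels
#'   where the Gauss-Newton curvature is almost singular.
#' @param armijo_c1 Sufficient-decrease constant of the backtracking line
#'   search.
#' @param max_backtracks Maximum step halvings in the line search.
#' @param cost_tol Relative cost-decrease stopping tolerance.
#' @param verbose Print per-iteration progress.
#' @return An object of class `uromt_params`.
#' @export
uromt_params <- function(sigma = 0.002, alpha = 9000, beta = 5000,
                         max_iter = 10L, pcg_tol = 1e-2, pcg_maxiter = 20L,
                         damping = 1e-3,
                         armijo_c1 = 1e-4, max_backtracks = 12L,
                         cost_tol = 1e-4, verbose = FALSE) {
  stopifnot(sigma >= 0, alpha > 0, beta >= 0, max_iter >= 1, damping >= 0)
  structure(list(sigma = sigma, alpha = alpha, beta = beta,
                 max_iter = as.integer(max_iter),
                 pcg_tol = pcg_tol, pcg_maxiter = as.integer(pcg_maxiter),
                 damping = damping,
                 armijo_c1 = armijo_c1,
                 max_backtracks = as.integer(max_backtracks),
                 cost_tol = cost_tol, verbose = isTRUE(verbose)),
            class = "uromt_params")
}

#' Transport cost and its breakdown
#'
#' Evaluates the discrete cost `Gamma = Gamma1 + alpha*Gamma2 + beta*Gamma3`:
#' kinetic energy `Gamma1 = (dt dx dy dz) * sum_i rho_{i+1}' (vx_i^2 + vy_i^2
#' + vz_i^2)`, Fisher-Rao source energy `Gamma2 = (dt dx dy dz) * sum_i
#' rho_{i+1}' (r_i^2 chi_i)`, and end-point mismatch `Gamma3 = (dx dy dz) *
#' ||rho_m - rho1_img||^2`. Step-`i` controls are paired with the state
#' `rho_{i+1}` they produce, matching the block-vector discretization (and
#' the gradient formulas derived from it).
#'
#' @param seq A [propagate_sequence()] result for these controls.
#' @param controls The [control_fields()] used to produce `seq`.
#' @param rho1_img Length-`n` target image.
#' @param params A [uromt_params()] object.
#' @return A list of class `uromt_cost` with `gamma1`, `gamma2`, `gamma3`,
#'   `total`.
#' @export
cost_terms <- function(seq, controls, rho1_img, params) {
  grid <- seq$grid
  check_scalar_field(grid, rho1_img, "rho1_img")
  hvol <- cell_volume(grid)
  hst <- grid$dt * hvol
  g1 <- 0; g2 <- 0
  for (i in seq_len(grid$m)) {
    vi <- split_velocity(grid, controls$v[[i]])
    rho_next <- seq$rho[[i + 1L]]
    g1 <- g1 + sum(rho_next * (vi$x^2 + vi$y^2 + vi$z^2))
    g2 <- g2 + sum(rho_next * controls$r[[i]]^2 * controls$chi[[i]])
  }
  g1 <- hst * g1
  g2 <- hst * g2
  g3 <- hvol * sum((seq$rho[[grid$m + 1L]] - rho1_img)^2)
  structure(list(gamma1 = g1, gamma2 = g2, gamma3 = g3,
                 total = g1 + params$alpha * g2 + params$beta * g3),
            class = "uromt_cost")
}

#' @export
print.uromt_cost <- function(x, ...) {
  cat(sprintf("Gamma = %.6g  (energy %.6g, source %.6g, mismatch %.6g)\n",
              x$total, x$gamma1, x$gamma2, x$gamma3))
  invisible(x)
}

#' Normalized mean squared error (percent)
#'
#' `||rho_final - rho_img||^2 / ||rho_img||^2 * 100`, a local fidelity
#' measure between the final interpolated image and the target frame.
#'
#' @param rho_final,rho_img Flattened images on the same grid.
#' @return NMSE in percent.
#' @export
nmse <- function(rho_final, rho_img) {
  stopifnot(length(rho_final) == length(rho_img))
  denom <- sum(rho_img^2)
  if (denom == 0) stop("reference image has zero norm")
  100 * sum((rho_final - rho_img)^2) / denom
}

#' Percent change in total mass
#'
#' `|sum(rho_final) - sum(rho_img)| / sum(rho_img) * 100`, a global fidelity
#' measure of how well total mass is matched.
#'
#' @param rho_final,rho_img Flattened images on the same grid.
#' @return PCTM in percent.
#' @export
pctm <- function(rho_final, rho_img) {
  stopifnot(length(rho_final) == length(rho_img))
  denom <- sum(rho_img)
  if (denom == 0) stop("reference image has zero total mass")
  100 * abs(sum(rho_final) - denom) / denom
}
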