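# Adjoint machinery: matrix-free application of the state Jacobians
# J_v = d rho / d v and J_r = d rho / d r (lower-triangular block matrices
# over substeps), their final block rows, and their transposes, from the
# per-step operators cached by propagate_sequence(). These feed the analytic
# gradient and the Gauss-Newton Hessian-vector handle.

# split a concatenated control vector into per-step pieces
as_step_list <- function(x, m, step_len) {
  if (is.list(x)) {
    stopifnot(length(x) == m)
    return(x)
  }
  stopifnot(length(x) == m * step_len)
  lapply(seq_len(m), function(i) x[((i - 1L) * step_len + 1L):(i * step_len)])
}

require_chain <- function(seq) {
  if (is.null(seq$S) || is.null(seq$B))
    stop("sequence was propagated without cache_jacobian = TRUE")
  invisible(TRUE)
}

# R(r_i) applied to a vector (diagonal)
apply_R <- function(seq, i, x) {
  (1 + seq$grid$dt * seq$controls$r[[i]] * seq$controls$chi[[i]]) * x
}

#' Apply a state Jacobian to a control perturbation
#'
#' Computes `J x` by the forward recursion over substeps: the step-`j`
#' injection is `B_j x_{v,j}` for a velocity perturbation (`B_j` the
#' sensitivity of the particle-in-cell advection to its velocity, with the
#' post-source density held fixed) or `dt * S_j (rho_j * chi_j * x_{r,j})`
#' for a source perturbation, pushed through the remaining diffusion /
#' advection / source factors.
#'
#' @param seq A [propagate_sequence()] result with cached operators.
#' @param x Control perturbation: concatenated length `3mn` (velocity) or
#'   `mn` (source) vector, or a list of per-step vectors.
#' @param wrt `"velocity"` or `"source"`.
#' @param rows `"all"` returns the stacked `[d rho_1; ...; d rho_m]`
#'   (length `mn`); `"final"` returns only `d rho_m` (length `n`).
#' @return Numeric vector as described.
#' @export
jacobian_apply <- function(seq, x, wrt = c("velocity", "source"),
                           rows = c("all", "final")) {
  wrt <- match.arg(wrt); rows <- match.arg(rows)
  require_chain(seq)
  grid <- seq$grid
  m <- grid$m; n <- grid$n
  xs <- as_step_list(x, m, if (wrt == "velocity") 3L * n else n)
  u <- numeric(n)
  out <- if (rows == "all") vector("list", m) else NULL
  for (j in seq_len(m)) {
    inj <- if (wrt == "velocity") {
      as.numeric(seq$B[[j]] %*% xs[[j]])
    } else {
      grid$dt * as.numeric(seq$S[[j]] %*%
        (seq$rho[[j]] * seq$controls$chi[[j]] * xs[[j]]))
    }
    carried <- if (j == 1L) numeric(n) else
      as.numeric(seq$S[[j]] %*% apply_R(seq, j, u))
    u <- apply_diffusion_inverse(seq$solver, carried + inj)
    if (rows == "all") out[[j]] <- u
  }
  if (rows == "all") unlist(out) else u
}

# Shared backward recursion: given per-density weights w_1..w_m (list), walk
# steps m..1 with t_j = L^{-1}(w_{j+1} + R_{j+1} S_{j+1}' t_{j+1}) and emit
# the velocity and/or source adjoint components at each step.
jacobian_transpose_core <- function(seq, w_list, want_v, want_r) {
  grid <- seq$grid
  m <- grid$m; n <- grid$n
  out_v <- if (want_v) vector("list", m) else NULL
  out_r <- if (want_r) vector("list", m) else NULL
  carry <- numeric(n)
  for (j in rev(seq_len(m))) {
    t <- apply_diffusion_inverse(seq$solver, w_list[[j]] + carry)
    St <- as.numeric(Matrix::crossprod(seq$S[[j]], t))
    if (want_v) out_v[[j]] <- as.numeric(Matrix::crossprod(seq$B[[j]], t))
    if (want_r) out_r[[j]] <-
      grid$dt * seq$rho[[j]] * seq$controls$chi[[j]] * St
    if (j > 1L) carry <- apply_R(seq, j, St)
  }
  list(v = if (want_v) unlist(out_v), r = if (want_r) unlist(out_r))
}

#' Apply a state Jacobian transpose to a density-shaped vector
#'
#' Computes `J' w` by the reverse (adjoint) recursion of [jacobian_apply()];
#' the diffusion solve is symmetric, so the same factorization serves both
#' directions. Satisfies the adjoint identity `<J x, w> = <x, J' w>`.
#'
#' @param seq A [propagate_sequence()] result with cached operators.
#' @param w Length-`mn` stacked vector (for `rows = "all"`) or length-`n`
#'   vector (for `rows = "final"`).
#' @inheritParams jacobian_apply
#' @return Control-shaped vector: length `3mn` (velocity) or `mn` (source).
#' @export
jacobian_transpose_apply <- function(seq, w, wrt = c("velocity", "source"),
                                     rows = c("all", "final")) {
  wrt <- match.arg(wrt); rows <- match.arg(rows)
  require_chain(seq)
  grid <- seq$grid
  m <- grid$m; n <- grid$n
  w_list <- if (rows == "all") {
    as_step_list(w, m, n)
  } else {
    stopifnot(length(w) == n)
    c(replicate(m - 1L, numeric(n), simplify = FALSE), list(w))
  }
  res <- jacobian_transpose_core(seq, w_list,
                                 want_v = wrt == "velocity",
                                 want_r = wrt == "source")
  if (wrt == "velocity") res$v else res$r
}

# per-step density rho_{i+1} replicated over the three velocity components;
# this is M' rho for the axis-summing operator M = I_m (x) [I | I | I]
replicate_rho_blocks <- function(seq) {
  unlist(lapply(seq_len(seq$grid$m),
                function(i) rep.int(seq$rho[[i + 1L]], 3L)))
}

# stacked M (v . v): per step the per-voxel sum vx^2 + vy^2 + vz^2
stacked_speed_sq <- function(seq) {
  grid <- seq$grid
  lapply(seq_len(grid$m), function(i) {
    vi <- split_velocity(grid, seq$controls$v[[i]])
    vi$x^2 + vi$y^2 + vi$z^2
  })
}

#' Analytic gradient of the transport cost
#'
#' Evaluates the gradient of `Gamma` with respect to the concatenated
#' velocity and source controls. Per control block:
#' `g_v = (dt dx dy dz) (2 v . rep(rho) + J_v' M(v.v)) + alpha (dt dx dy dz)
#' J_v' (r.r.chi) + 2 beta (dx dy dz) (J_v^m)' (rho_m - rho1_img)` and the
#' analogous `g_r` with the direct Fisher-Rao term
#' `2 alpha (dt dx dy dz) (r.chi).rho`. The two Jacobian-transpose terms
#' share one backward recursion.
#'
#' @param seq A [propagate_sequence()] result with cached operators.
#' @param rho1_img Length-`n` target image.
#' @param params A [uromt_params()] object.
#' @return List with `g_v` (length `3mn`) and `g_r` (length `mn`).
#' @export
transport_gradient <- function(seq, rho1_img, params) {
  require_chain(seq)
  grid <- seq$grid
  m <- grid$m; n <- grid$n
  hvol <- cell_volume(grid)
  hst <- grid$dt * hvol
  sp2 <- stacked_speed_sq(seq)
  # shared adjoint weights: all-rows terms plus the final-row mismatch term
  w_list <- lapply(seq_len(m), function(i) {
    hst * sp2[[i]] +
      (params$alpha * hst) * seq$controls$r[[i]]^2 * seq$controls$chi[[i]]
  })
  w_list[[m]] <- w_list[[m]] +
    (2 * params$beta * hvol) * (seq$rho[[m + 1L]] - rho1_img)
  adj <- jacobian_transpose_core(seq, w_list, want_v = TRUE, want_r = TRUE)
  direct_v <- 2 * hst * unlist(seq$controls$v) * replicate_rho_blocks(seq)
  direct_r <- 2 * params$alpha * hst *
    unlist(lapply(seq_len(m), function(i)
      seq$controls$r[[i]] * seq$controls$chi[[i]] * seq$rho[[i + 1L]]))
  list(g_v = direct_v + adj$v, g_r = direct_r + adj$r)
}

#' Gauss-Newton Hessian-vector product
#'
#' Applies the Gauss-Newton approximation of the Hessian of `Gamma` to a
#' stacked direction `x = [x_v; x_r]` without materializing any matrix:
#' elementwise (diagonal) curvature from the kinetic and Fisher-Rao terms
#' plus the rank-structured terminal term
#' `2 beta (dx dy dz) (J^m)' (J^m x)` coupling velocity and source through
#' the shared final-state sensitivity. The operator is symmetric positive
#' semidefinite for nonnegative densities.
#'
#' @param seq A [propagate_sequence()] result with cached operators.
#' @param params A [uromt_params()] object.
#' @param x Stacked direction of length `3mn + mn`.
#' @return `H x`, same length and layout as `x`.
#' @export
hessian_apply <- function(seq, params, x) {
  require_chain(seq)
  grid <- seq$grid
  m <- grid$m; n <- grid$n
  nv <- 3L * m * n
  stopifnot(length(x) == nv + m * n)
  x_v <- x[seq_len(nv)]
  x_r <- x[nv + seq_len(m * n)]
  hvol <- cell_volume(grid)
  hst <- grid$dt * hvol
  diag_v <- 2 * hst * replicate_rho_blocks(seq)
  diag_r <- 2 * params$alpha * hst *
    unlist(lapply(seq_len(m), function(i)
      seq$controls$chi[[i]] * seq$rho[[i + 1L]]))
  # final-state sensitivity in the combined direction, one forward recursion
  u <- numeric(n)
  xs_v <- as_step_list(x_v, m, 3L * n)
  xs_r <- as_step_list(x_r, m, n)
  for (j in seq_len(m)) {
    inj <- as.numeric(seq$B[[j]] %*% xs_v[[j]]) +
      grid$dt * as.numeric(seq$S[[j]] %*%
        (seq$rho[[j]] * seq$controls$chi[[j]] * xs_r[[j]]))
    carried <- if (j == 1L) numeric(n) else
      as.numeric(seq$S[[j]] %*% apply_R(seq, j, u))
    u <- apply_diffusion_inverse(seq$solver, carried + inj)
  }
  w_list <- c(replicate(m - 1L, numeric(n), simplify = FALSE),
              list((2 * params$beta * hvol) * u))
  adj <- jacobian_transpose_core(seq, w_list, want_v = TRUE, want_r = TRUE)
  c(diag_v * x_v + adj$v, diag_r * x_r + adj$r)
}

# closed-form Jacobi preconditioner diagonal: the elementwise curvature
# terms of the Gauss-Newton Hessian (terminal term omitted; its diagonal is
# not available in closed form)
hessian_diagonal <- function(seq, params) {
  grid <- seq$grid
  hst <- grid$dt * cell_volume(grid)
  c(2 * hst * replicate_rho_blocks(seq),
    2 * params$alpha * hst *
      unlist(lapply(seq_len(grid$m), function(i)
        seq$controls$chi[[i]] * seq$rho[[i + 1L]])))
}
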