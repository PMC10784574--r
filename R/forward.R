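#' Control fields for one image pair
#'
#' Bundles the per-substep velocity fields, relative sources and indicators
#' driving one transport loop. Each of the `m` substeps carries a length-`3n`
#' velocity `[vx; vy; vz]`, a length-`n` relative source and a length-`n`
#' binary indicator.
#'
#' @param grid A [grid_spec()] object.
#' @param v List of `m` length-`3n` velocity vectors, or `NULL` for all-zero.
#' @param r List of `m` length-`n` relative-source vectors, or `NULL` for zero.
#' @param chi List of `m` length-`n` indicators in `{0,1}`, a single length-`n`
#'   indicator recycled over substeps, or `NULL` for all-ones.
#' @return An object of class `uromt_controls`.
#' @export
control_fields <- function(grid, v = NULL, r = NULL, chi = NULL) {
  m <- grid$m
  if (is.null(v)) v <- replicate(m, numeric(3L * grid$n), simplify = FALSE)
  if (is.null(r)) r <- replicate(m, numeric(grid$n), simplify = FALSE)
  if (is.null(chi)) chi <- rep.int(1, grid$n)
  if (!is.list(chi)) chi <- replicate(m, chi, simplify = FALSE)
  stopifnot(length(v) == m, length(r) == m, length(chi) == m)
  for (i in seq_len(m)) {
    check_vector_field(grid, v[[i]], sprintf("v[[%d]]", i))
    check_scalar_field(grid, r[[i]], sprintf("r[[%d]]", i))
    check_scalar_field(grid, chi[[i]], sprintf("chi[[%d]]", i))
    if (!all(chi[[i]] %in% c(0, 1)))
      stop(sprintf("chi[[%d]] must be binary", i))
  }
  structure(list(v = v, r = r, chi = chi, grid = grid),
            class = "uromt_controls")
}

#' Advance a density by one substep
#'
#' One substep of the operator-split dynamics: relative source, then
#' particle-in-cell advection, then implicit diffusion,
#' `rho_{i+1} = L^{-1} S(v_i) R(r_i) rho_i`. Advection and diffusion conserve
#' total mass, so the ledger `sum(out) = sum((1 + dt*r*chi)*rho)` holds to
#' solver tolerance.
#'
#' @param rho Length-`n` density at the start of the substep.
#' @param v Length-`3n` substep velocity.
#' @param r,chi Length-`n` relative source and indicator.
#' @param solver A [diffusion_solver()] for the grid.
#' @return The density after the substep.
#' @export
propagate_step <- function(rho, v, r, chi, solver) {
  grid <- solver$grid
  rho_src <- apply_source(rho, r, chi, grid$dt)
  S <- advection_matrix(grid, v)
  apply_diffusion_inverse(solver, as.numeric(S %*% rho_src))
}

#' Propagate a density through all substeps
#'
#' Runs the split dynamics from `rho0` through the `m` substeps of one image
#' pair and returns the full state sequence. With `cache_jacobian = TRUE` the
#' per-step advection matrices, their velocity derivatives and the post-source
#' densities are retained, which is what the adjoint recursions need; this is
#' the "Jacobian chain" consumed by [jacobian_apply()] and friends.
#'
#' @param rho0 Length-`n` nonnegative initial density.
#' @param controls A [control_fields()] object.
#' @param solver A [diffusion_solver()].
#' @param cache_jacobian Keep per-step operators for adjoint computations.
#' @return An object of class `uromt_sequence`: list with `rho` (list of
#'   `m+1` densities, `rho[[1]]` the initial state), `grid`, `controls`,
#'   `solver`, and when cached, `S`, `B`, `rho_src` per step.
#' @export
propagate_sequence <- function(rho0, controls, solver, cache_jacobian = TRUE) {
  grid <- solver$grid
  check_scalar_field(grid, rho0, "rho0")
  m <- grid$m
  rho <- vector("list", m + 1L)
  rho[[1L]] <- rho0
  Ss <- if (cache_jacobian) vector("list", m) else NULL
  Bs <- if (cache_jacobian) vector("list", m) else NULL
  srcs <- if (cache_jacobian) vector("list", m) else NULL
  for (i in seq_len(m)) {
    rs <- apply_source(rho[[i]], controls$r[[i]], controls$chi[[i]], grid$dt)
    S <- advection_matrix(grid, controls$v[[i]])
    rho[[i + 1L]] <- apply_diffusion_inverse(solver, as.numeric(S %*% rs))
    if (cache_jacobian) {
      Ss[[i]] <- S
      srcs[[i]] <- rs
      Bs[[i]] <- advection_derivative(grid, controls$v[[i]], rs)
    }
  }
  structure(list(rho = rho, grid = grid, controls = controls, solver = solver,
                 S = Ss, B = Bs, rho_src = srcs),
            class = "uromt_sequence")
}

#' Total mass at every time step
#'
#' @param seq A [propagate_sequence()] result.
#' @return Numeric vector of length `m + 1` with `sum(rho_i) * dx*dy*dz`.
#' @export
mass_trajectory <- function(seq) {
  vapply(seq$rho, sum, numeric(1)) * cell_volume(seq$grid)
}
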