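#' Preconditioned conjugate gradients on a matrix-free handle
#'
#' Approximately solves `H x = -g` for a symmetric positive semidefinite
#' operator given as a function, with a diagonal (Jacobi) preconditioner.
#' Stops at the relative-residual tolerance or the iteration cap; if the
#' returned iterate is not a descent direction for `g`, the preconditioned
#' steepest-descent direction is returned instead and flagged.
#'
#' @param hx Function of one vector argument returning `H %*% x`.
#' @param g Gradient vector (right-hand side is `-g`).
#' @param diag_precond Nonnegative preconditioner diagonal (regularized
#'   internally), or `NULL` for the identity.
#' @param rtol Relative residual tolerance.
#' @param maxit Iteration cap.
#' @return List with `x`, `iterations`, `residual` (relative), and
#'   `fallback` (TRUE when the steepest-descent fallback was taken).
#' @export
pcg_solve <- function(hx, g, diag_precond = NULL, rtol = 1e-2, maxit = 20L) {
  b <- -g
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0)
    return(list(x = numeric(length(g)), iterations = 0L, residual = 0,
                fallback = FALSE))
  d <- if (is.null(diag_precond)) rep.int(1, length(g)) else {
    floor_val <- 1e-8 * max(diag_precond, 1e-300)
    pmax(diag_precond, floor_val)
  }
  x <- numeric(length(g))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  it <- 0L
  res <- 1
  while (it < maxit) {
    Hp <- hx(p)
    pHp <- sum(p * Hp)
    if (!is.finite(pHp) || pHp <= 0) break   # curvature breakdown
    alpha <- rz / pHp
    x <- x + alpha * p
    r <- r - alpha * Hp
    it <- it + 1L
    res <- sqrt(sum(r * r)) / bnorm
    if (res <= rtol) break
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  if (sum(g * x) < 0)
    return(list(x = x, iterations = it, residual = res, fallback = FALSE))
  list(x = b / d, iterations = it, residual = res, fallback = TRUE)
}

#' Backtracking (Armijo) line search
#'
#' Finds the largest step `t` in `{1, 1/2, 1/4, ...}` with
#' `f(x0 + t d) <= f(x0) + c1 t g'd`, where evaluations that violate the
#' source feasibility guard (density would turn negative) count as failures
#' and trigger further halving. An ascent direction is an error; an
#' exhausted search returns `t = 0`.
#'
#' @param cost_fn Function of a control vector returning the scalar cost
#'   (may throw on infeasible points).
#' @param x0 Current control vector.
#' @param direction Descent direction.
#' @param g Gradient at `x0`.
#' @param f0 Cost at `x0` (recomputed if `NULL`).
#' @param c1 Armijo constant.
#' @param max_backtracks Maximum halvings.
#' @return List with `t` (accepted step, 0 on failure) and `f` (cost at the
#'   accepted point, `f0` when `t = 0`).
#' @export
line_search <- function(cost_fn, x0, direction, g, f0 = NULL,
                        c1 = 1e-4, max_backtracks = 12L) {
  slope <- sum(g * direction)
  if (slope >= 0) stop("line search requires a descent direction")
  if (is.null(f0)) f0 <- cost_fn(x0)
  t <- 1
  for (k in seq_len(max_backtracks + 1L)) {
    f_try <- tryCatch(cost_fn(x0 + t * direction), error = function(e) NA_real_)
    if (is.finite(f_try) && f_try <= f0 + c1 * t * slope)
      return(list(t = t, f = f_try))
    t <- t / 2
  }
  list(t = 0, f = f0)
}

# pack/unpack controls <-> one stacked vector [v; r]
pack_controls <- function(controls) c(unlist(controls$v), unlist(controls$r))

unpack_controls <- function(grid, x, chi) {
  m <- grid$m; n <- grid$n
  nv <- 3L * m * n
  control_fields(grid,
                 v = as_step_list(x[seq_len(nv)], m, 3L * n),
                 r = as_step_list(x[nv + seq_len(m * n)], m, n),
                 chi = chi)
}

#' Gauss-Newton solver for one image pair
#'
#' Minimizes the transport cost over the per-substep velocity and relative
#' source: each iteration evaluates the cost and analytic gradient, solves
#' the Gauss-Newton system `H x = -g` approximately by preconditioned
#' conjugate gradients on the matrix-free Hessian handle, and takes an
#' Armijo-backtracked step. Deterministic given inputs and settings; never
#' returns a worse-than-initial cost.
#'
#' @param rho0 Length-`n` nonnegative initial image.
#' @param rho1_img Length-`n` nonnegative target image.
#' @param chi Indicator: a single length-`n` vector held over substeps, or a
#'   list of `m` per-substep vectors.
#' @param params A [uromt_params()] object.
#' @param grid A [grid_spec()] object.
#' @param init Optional initial [control_fields()] (default zero controls).
#' @param solver Optional prebuilt [diffusion_solver()] to reuse across
#'   loops.
#' @return An object of class `uromt_solution`: `controls` (optimal), `seq`
#'   (final propagated sequence), `cost_history` (data frame of per-iteration
#'   cost breakdowns, step lengths and PCG statistics), `metrics` (final
#'   NMSE/PCTM against `rho1_img`), and `termination`.
#' @export
gauss_newton <- function(rho0, rho1_img, chi, params, grid, init = NULL,
                         solver = NULL) {
  check_scalar_field(grid, rho0, "rho0")
  check_scalar_field(grid, rho1_img, "rho1_img")
  if (any(rho0 < 0) || any(rho1_img < 0))
    stop("input images must be nonnegative")
  if (is.null(solver)) solver <- diffusion_solver(grid, params$sigma)
  controls <- if (is.null(init)) control_fields(grid, chi = chi) else init
  chi_list <- controls$chi

  cost_of <- function(xvec) {
    ctr <- unpack_controls(grid, xvec, chi_list)
    sq <- propagate_sequence(rho0, ctr, solver, cache_jacobian = FALSE)
    cost_terms(sq, ctr, rho1_img, params)$total
  }

  x <- pack_controls(controls)
  seq_cur <- propagate_sequence(rho0, controls, solver)
  cost_cur <- cost_terms(seq_cur, controls, rho1_img, params)
  history <- list(iteration_record(0L, cost_cur, NA_real_, NA_integer_, FALSE,
                                   seq_cur, rho1_img))
  termination <- "max_iterations"

  for (it in seq_len(params$max_iter)) {
    grad <- transport_gradient(seq_cur, rho1_img, params)
    g <- c(grad$g_v, grad$g_r)
    gnorm <- sqrt(sum(g * g))
    if (gnorm == 0) { termination <- "zero_gradient"; break }
    hdiag <- hessian_diagonal(seq_cur, params)
    lambda <- params$damping * max(hdiag)
    pcg <- pcg_solve(function(z) hessian_apply(seq_cur, params, z) + lambda * z,
                     g, diag_precond = hdiag + lambda,
                     rtol = params$pcg_tol, maxit = params$pcg_maxiter)
    ls <- line_search(cost_of, x, pcg$x, g, f0 = cost_cur$total,
                      c1 = params$armijo_c1,
                      max_backtracks = params$max_backtracks)
    if (ls$t == 0) { termination <- "no_step"; break }
    x <- x + ls$t * pcg$x
    controls <- unpack_controls(grid, x, chi_list)
    seq_cur <- propagate_sequence(rho0, controls, solver)
    cost_prev <- cost_cur$total
    cost_cur <- cost_terms(seq_cur, controls, rho1_img, params)
    history[[length(history) + 1L]] <-
      iteration_record(it, cost_cur, ls$t, pcg$iterations, pcg$fallback,
                       seq_cur, rho1_img)
    if (params$verbose)
      message(sprintf(
        "  GN iter %d: Gamma = %.6g (step %.3g, %d PCG iters%s)",
        it, cost_cur$total, ls$t, pcg$iterations,
        if (pcg$fallback) ", fallback" else ""))
    rel_drop <- (cost_prev - cost_cur$total) / max(cost_prev, .Machine$double.eps)
    if (rel_drop < params$cost_tol) { termination <- "cost_tolerance"; break }
  }

  rho_final <- seq_cur$rho[[grid$m + 1L]]
  structure(list(
    controls = controls,
    seq = seq_cur,
    cost_history = do.call(rbind, history),
    metrics = c(nmse = nmse(rho_final, rho1_img),
                pctm = pctm(rho_final, rho1_img)),
    termination = termination,
    grid = grid, params = params
  ), class = "uromt_solution")
}

iteration_record <- function(it, cost, step, pcg_iters, fallback, seq,
                             rho1_img) {
  rho_final <- seq$rho[[length(seq$rho)]]
  data.frame(iteration = it, gamma1 = cost$gamma1, gamma2 = cost$gamma2,
             gamma3 = cost$gamma3, total = cost$total,
             nmse = nmse(rho_final, rho1_img),
             pctm = pctm(rho_final, rho1_img),
             step = step, pcg_iterations = pcg_iters, fallback = fallback)
}

#' @export
print.uromt_solution <- function(x, ...) {
  h <- x$cost_history
  cat(sprintf("uromt solution: %d accepted iteration(s), termination: %s\n",
              nrow(h) - 1L, x$termination))
  cat(sprintf("cost %.6g -> %.6g; NMSE %.3f%%, PCTM %.3f%%\n",
              h$total[1], h$total[nrow(h)],
              x$metrics[["nmse"]], x$metrics[["pctm"]]))
  invisible(x)
}
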