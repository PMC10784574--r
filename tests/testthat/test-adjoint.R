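test_that("Jacobian application is linear and matches simple closed forms", {
  set.seed(41)
  g <- grid_spec(3, 3, 2, dt = 0.4, m = 1)
  solver <- diffusion_solver(g, 0)
  rho0 <- stats::runif(g$n, 0.5, 2)
  chi <- stats::rbinom(g$n, 1, 0.6)
  ctr <- control_fields(g, chi = chi)
  seqc <- propagate_sequence(rho0, ctr, solver)
  # zero perturbation maps to zero
  expect_equal(jacobian_apply(seqc, numeric(3 * g$n), "velocity", "all"),
               numeric(g$n))
  # m = 1, sigma = 0, v = 0, source direction e_k: J e_k = dt * rho0*chi*e_k
  for (k in c(1L, 7L)) {
    ek <- numeric(g$n); ek[k] <- 1
    expect_equal(jacobian_apply(seqc, ek, "source", "final"),
                 g$dt * rho0 * chi * ek)
  }
  # diagonal transpose in the same configuration
  w <- stats::rnorm(g$n)
  expect_equal(jacobian_transpose_apply(seqc, w, "source", "final"),
               g$dt * rho0 * chi * w)
})

test_that("Jacobians match central finite differences of the propagation", {
  set.seed(42)
  g <- grid_spec(4, 3, 3, dt = 0.4, m = 2)
  solver <- diffusion_solver(g, 0.002)
  rho0 <- stats::runif(g$n, 0.5, 2)
  ctr <- random_controls(g, chi_p = 0.6)
  seqc <- propagate_sequence(rho0, ctr, solver)
  # the PIC weights are piecewise linear in the displacement; the step must
  # stay within the current linear piece at every displaced point
  h <- 1e-7
  stacked <- function(v, r) {
    c2 <- control_fields(g, v, r, ctr$chi)
    s2 <- propagate_sequence(rho0, c2, solver, cache_jacobian = FALSE)
    unlist(s2$rho[-1L])
  }
  for (trial in 1:3) {
    dv <- replicate(g$m, stats::rnorm(3 * g$n), simplify = FALSE)
    fd <- (stacked(Map(function(a, b) a + h * b, ctr$v, dv), ctr$r) -
           stacked(Map(function(a, b) a - h * b, ctr$v, dv), ctr$r)) / (2 * h)
    an <- jacobian_apply(seqc, unlist(dv), "velocity", "all")
    expect_lt(max(abs(fd - an)) / max(abs(fd)), 1e-5)
    dr <- replicate(g$m, stats::rnorm(g$n), simplify = FALSE)
    fd <- (stacked(ctr$v, Map(function(a, b) a + h * b, ctr$r, dr)) -
           stacked(ctr$v, Map(function(a, b) a - h * b, ctr$r, dr))) / (2 * h)
    an <- jacobian_apply(seqc, unlist(dr), "source", "all")
    expect_lt(max(abs(fd - an)) / max(abs(fd)), 1e-5)
  }
})

test_that("transpose application satisfies the adjoint identity", {
  set.seed(43)
  g <- grid_spec(4, 4, 3, dt = 0.4, m = 2)
  solver <- diffusion_solver(g, 0.002)
  rho0 <- stats::runif(g$n, 0.5, 2)
  ctr <- random_controls(g, chi_p = 0.7)
  seqc <- propagate_sequence(rho0, ctr, solver)
  for (trial in 1:5) {
    w_all <- stats::rnorm(g$m * g$n)
    w_fin <- stats::rnorm(g$n)
    x_v <- stats::rnorm(3 * g$m * g$n)
    x_r <- stats::rnorm(g$m * g$n)
    for (case in list(
      list(x = x_v, wrt = "velocity", rows = "all", w = w_all),
      list(x = x_r, wrt = "source", rows = "all", w = w_all),
      list(x = x_v, wrt = "velocity", rows = "final", w = w_fin),
      list(x = x_r, wrt = "source", rows = "final", w = w_fin))) {
      lhs <- sum(jacobian_apply(seqc, case$x, case$wrt, case$rows) * case$w)
      rhs <- sum(case$x *
                 jacobian_transpose_apply(seqc, case$w, case$wrt, case$rows))
      expect_lt(abs(lhs - rhs) / max(abs(lhs), abs(rhs)), 1e-9)
    }
  }
})

test_that("stacked all-rows application is consistent with the final row", {
  set.seed(44)
  g <- grid_spec(3, 3, 3, dt = 0.4, m = 3)
  solver <- diffusion_solver(g, 0.002)
  rho0 <- stats::runif(g$n, 0.5, 2)
  ctr <- random_controls(g)
  seqc <- propagate_sequence(rho0, ctr, solver)
  x <- stats::rnorm(3 * g$m * g$n)
  all_rows <- jacobian_apply(seqc, x, "velocity", "all")
  final <- jacobian_apply(seqc, x, "velocity", "final")
  expect_equal(all_rows[(g$m - 1L) * g$n + seq_len(g$n)], final)
})

test_that("gradient vanishes at the stationary trivial point", {
  g <- grid_spec(3, 3, 3, dt = 0.4, m = 2)
  solver <- diffusion_solver(g, 0)
  rho0 <- blob_field(g)
  ctr <- control_fields(g, chi = stats::rbinom(g$n, 1, 0.5))
  seqc <- propagate_sequence(rho0, ctr, solver)
  gr <- transport_gradient(seqc, rho0, uromt_params(alpha = 5, beta = 7))
  expect_equal(gr$g_v, numeric(3 * g$m * g$n))
  expect_equal(gr$g_r, numeric(g$m * g$n))
})

test_that("with zero controls only the mismatch term drives the gradient", {
  set.seed(45)
  g <- grid_spec(3, 3, 2, dt = 0.4, m = 2)
  solver <- diffusion_solver(g, 0)
  rho0 <- stats::runif(g$n, 0.5, 2)
  rho1 <- stats::runif(g$n, 0.5, 2)
  chi <- stats::rbinom(g$n, 1, 0.6)
  ctr <- control_fields(g, chi = chi)
  seqc <- propagate_sequence(rho0, ctr, solver)
  p <- uromt_params(alpha = 5, beta = 7)
  gr <- transport_gradient(seqc, rho1, p)
  mismatch <- seqc$rho[[g$m + 1L]] - rho1
  expected_r <- 2 * p$beta * g$dx * g$dy * g$dz *
    jacobian_transpose_apply(seqc, mismatch, "source", "final")
  expect_equal(gr$g_r, expected_r)
})

test_that("gradient matches central finite differences of the cost", {
  set.seed(46)
  g <- grid_spec(5, 5, 4, dt = 0.4, m = 2)
  p <- uromt_params(sigma = 0.002, alpha = 100, beta = 50)
  solver <- diffusion_solver(g, p$sigma)
  rho0 <- stats::runif(g$n, 0.5, 2)
  rho1 <- stats::runif(g$n, 0.5, 2)
  ctr <- random_controls(g, chi_p = 0.6)
  seqc <- propagate_sequence(rho0, ctr, solver)
  gr <- transport_gradient(seqc, rho1, p)
  cost_of <- function(v, r) {
    c2 <- control_fields(g, v, r, ctr$chi)
    s2 <- propagate_sequence(rho0, c2, solver, cache_jacobian = FALSE)
    cost_terms(s2, c2, rho1, p)$total
  }
  h <- 1e-5
  for (trial in 1:5) {
    dv <- replicate(g$m, stats::rnorm(3 * g$n), simplify = FALSE)
    fd <- (cost_of(Map(function(a, b) a + h * b, ctr$v, dv), ctr$r) -
           cost_of(Map(function(a, b) a - h * b, ctr$v, dv), ctr$r)) / (2 * h)
    expect_lt(abs(fd - sum(gr$g_v * unlist(dv))) / abs(fd), 1e-4)
    dr <- replicate(g$m, stats::rnorm(g$n), simplify = FALSE)
    fd <- (cost_of(ctr$v, Map(function(a, b) a + h * b, ctr$r, dr)) -
           cost_of(ctr$v, Map(function(a, b) a - h * b, ctr$r, dr))) / (2 * h)
    expect_lt(abs(fd - sum(gr$g_r * unlist(dr))) / abs(fd), 1e-4)
  }
})

test_that("Hessian handle is symmetric, positive and diagonal when beta = 0", {
  set.seed(47)
  g <- grid_spec(4, 3, 3, dt = 0.4, m = 2)
  p <- uromt_params(sigma = 0.002, alpha = 11, beta = 3)
  solver <- diffusion_solver(g, p$sigma)
  rho0 <- stats::runif(g$n, 0.5, 2)
  ctr <- random_controls(g, chi_p = 0.6)
  seqc <- propagate_sequence(rho0, ctr, solver)
  dim_x <- 4L * g$m * g$n
  expect_equal(hessian_apply(seqc, p, numeric(dim_x)), numeric(dim_x))
  for (trial in 1:5) {
    x <- stats::rnorm(dim_x); y <- stats::rnorm(dim_x)
    Hx <- hessian_apply(seqc, p, x); Hy <- hessian_apply(seqc, p, y)
    expect_lt(abs(sum(x * Hy) - sum(y * Hx)) / abs(sum(x * Hy)), 1e-9)
    expect_gte(sum(x * Hx), 0)
  }
  # beta = 0: purely elementwise curvature
  p0 <- uromt_params(sigma = 0.002, alpha = 11, beta = 0)
  x <- stats::rnorm(dim_x)
  Hx <- hessian_apply(seqc, p0, x)
  hst <- g$dt * g$dx * g$dy * g$dz
  nv <- 3L * g$m * g$n
  rho_rep <- unlist(lapply(seq_len(g$m),
                           function(i) rep(seqc$rho[[i + 1L]], 3)))
  rho_chi <- unlist(lapply(seq_len(g$m),
                           function(i) ctr$chi[[i]] * seqc$rho[[i + 1L]]))
  expect_equal(Hx[seq_len(nv)], 2 * hst * rho_rep * x[seq_len(nv)])
  expect_equal(Hx[nv + seq_len(g$m * g$n)],
               2 * p0$alpha * hst * rho_chi * x[nv + seq_len(g$m * g$n)])
})
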