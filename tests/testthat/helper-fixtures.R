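# Shared fixtures: small random instances, dense oracles, and memoized
# scaled sphere solves reused across test files.

# random controls with per-step velocity and source fields
random_controls <- function(grid, v_sd = 0.2, r_sd = 0.1, chi_p = 1) {
  v <- replicate(grid$m, stats::rnorm(3 * grid$n, sd = v_sd), simplify = FALSE)
  r <- replicate(grid$m, stats::rnorm(grid$n, sd = r_sd), simplify = FALSE)
  chi <- replicate(grid$m, stats::rbinom(grid$n, 1, chi_p), simplify = FALSE)
  control_fields(grid, v, r, chi)
}

# dense-matrix oracle for the forward chain: explicit L^{-1} S R products
dense_forward_oracle <- function(grid, rho0, controls, sigma) {
  Ld <- diag(grid$n) - sigma * grid$dt *
    as.matrix(neumann_laplacian(grid))
  rho <- rho0
  out <- list(rho)
  for (i in seq_len(grid$m)) {
    Rm <- diag(1 + grid$dt * controls$r[[i]] * controls$chi[[i]],
               nrow = grid$n)
    Sd <- as.matrix(advection_matrix(grid, controls$v[[i]]))
    rho <- solve(Ld, Sd %*% Rm %*% rho)
    out[[i + 1L]] <- as.numeric(rho)
  }
  out
}

# a normalized Gaussian blob on an arbitrary grid (test density)
blob_field <- function(grid, center = NULL, width = NULL, amplitude = 1) {
  if (is.null(center)) center <- (c(grid$n1, grid$n2, grid$n3) + 1) / 2
  if (is.null(width)) width <- max(2, min(grid$n1, grid$n2, grid$n3) / 5)
  idx <- uromt:::cell_index_triples(grid)
  d2 <- (idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2 +
    (idx[, 3] - center[3])^2
  amplitude * exp(-d2 / (2 * width^2))
}

# --- memoized scaled sphere solves (shared by unit and acceptance tests) ---
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# reduced sphere data: 24^3 grid, m = 4 substeps per pair
sphere_fixture <- function() memo("sphere_fixture", function() {
  cfg <- sphere_config(n = 24)
  gen <- gaussian_sphere_frames(cfg)
  grid <- grid_spec(24, 24, 24, m = 4, dt = 0.4)
  list(cfg = cfg, gen = gen, grid = grid)
})

# study 1: five frames, translated-ball indicators, Table-1 weights
sphere_study1 <- function() memo("sphere_study1", function() {
  fx <- sphere_fixture()
  params <- uromt_params(sigma = 0.002, alpha = 9000, beta = 5000,
                         max_iter = 10)
  indicators <- lapply(1:4, function(k) fx$gen$pair_indicators(k, fx$grid$m))
  list(solutions = run_multiframe(fx$gen$frames, indicators, params, fx$grid),
       indicators = indicators, params = params)
})

# study 2 / alpha sweep: first frame pair, unrestricted indicator, beta = 50
sphere_pair_solution <- function(alpha) {
  memo(sprintf("sphere_pair_%g", alpha), function() {
    fx <- sphere_fixture()
    pair <- translated_pair(fx$cfg)
    params <- uromt_params(sigma = 0.002, alpha = alpha, beta = 50,
                           max_iter = 15, cost_tol = 1e-5)
    gauss_newton(pair$rho0, pair$rho1, pair$chi, params, fx$grid)
  })
}

# union of the per-substep ball indicators of a set of loops
indicator_union <- function(fx, loops) {
  u <- numeric(fx$grid$n)
  for (k in loops)
    for (j in 0:(fx$grid$m - 1L))
      u <- pmax(u, fx$gen$indicator_for(k, j, fx$grid$m))
  u
}
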