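# build a solution-like object carrying prescribed velocity fields and a
# density sequence, sufficient for the Lagrangian post-processing
lagr_fake <- function(grid, v_steps, rho_states, sigma = 0.002) {
  structure(list(controls = list(v = v_steps),
                 seq = list(rho = rho_states),
                 params = list(sigma = sigma),
                 grid = grid),
            class = "uromt_solution")
}

uniform_v <- function(grid, vx, vy = 0, vz = 0) {
  c(rep(vx, grid$n), rep(vy, grid$n), rep(vz, grid$n))
}

test_that("seeding thresholds and strides enumerate the expected centers", {
  g <- grid_spec(6, 6, 6, dt = 0.4, m = 1)
  rho <- blob_field(g, amplitude = 2)
  expect_warning(s <- seed_points(rho, g, threshold = 3), "no seed")
  expect_equal(nrow(s), 0L)
  all_pts <- seed_points(rho, g, threshold = 0, stride = 1)
  expect_equal(nrow(all_pts), g$n)
  # stride-2 count against brute-force enumeration
  idx <- uromt:::cell_index_triples(g)
  thr <- 0.5
  manual <- sum(rho > thr & idx[, 1] %% 2 == 1 & idx[, 2] %% 2 == 1 &
                idx[, 3] %% 2 == 1)
  expect_equal(nrow(seed_points(rho, g, threshold = thr, stride = 2)), manual)
})

test_that("zero velocity gives stationary paths and zero flux vectors", {
  g <- grid_spec(5, 5, 5, dt = 0.4, m = 2)
  rho <- blob_field(g)
  sol <- lagr_fake(g, replicate(g$m, numeric(3 * g$n), simplify = FALSE),
                   replicate(g$m + 1L, rho, simplify = FALSE))
  seeds <- seed_points(rho, g, threshold = 0.5, stride = 2)
  paths <- trace_pathlines(list(sol), seeds)
  for (p in paths$paths)
    expect_equal(max(abs(sweep(p$vertices, 2, p$vertices[1, ]))), 0)
  fv <- flux_vectors(paths)
  expect_equal(fv$norm, numeric(nrow(fv)))
  expect_equal(unname(as.matrix(fv[, c("x0", "y0", "z0")])),
               unname(seeds))
})

test_that("a uniform velocity yields straight paths of length speed * T", {
  g <- grid_spec(12, 6, 6, dt = 0.5, m = 2)
  rho <- rep(1, g$n)
  v <- uniform_v(g, 0.8)     # displacement 0.8 * 0.5 = 0.4 per substep
  nloops <- 2L
  sols <- replicate(nloops, lagr_fake(
    g, replicate(g$m, v, simplify = FALSE),
    replicate(g$m + 1L, rho, simplify = FALSE)), simplify = FALSE)
  seeds <- matrix(c(2, 3, 3), 1, dimnames = list(NULL, c("x", "y", "z")))
  paths <- trace_pathlines(sols, seeds)
  p <- paths$paths[[1]]
  total_T <- nloops * g$m * g$dt
  expect_equal(nrow(p$vertices), nloops * g$m + 1L)
  expect_equal(p$vertices[nrow(p$vertices), ], c(2 + 0.8 * total_T, 3, 3),
               ignore_attr = TRUE)
  # straight: every substep advances by the same increment
  incr <- diff(p$vertices)
  expect_equal(incr, matrix(rep(c(0.4, 0, 0), each = nrow(incr)),
                            ncol = 3), ignore_attr = TRUE)
  expect_equal(p$speed, rep(0.8, nloops * g$m + 1L))
  fv <- flux_vectors(paths)
  expect_equal(fv$norm, 0.8 * total_T)
})

test_that("paths are clamped inside the domain box", {
  g <- grid_spec(5, 5, 5, dt = 0.4, m = 3)
  rho <- rep(1, g$n)
  sol <- lagr_fake(g, replicate(g$m, uniform_v(g, 50, 50, 50),
                                simplify = FALSE),
                   replicate(g$m + 1L, rho, simplify = FALSE))
  seeds <- seed_points(rho, g, stride = 2)
  paths <- trace_pathlines(list(sol), seeds)
  for (p in paths$paths) {
    expect_true(all(p$vertices >= 1))
    expect_true(all(p$vertices <= 5))
  }
})

test_that("Peclet attributes follow the flux-ratio convention", {
  g <- grid_spec(8, 4, 4, dt = 0.4, m = 1)
  v <- uniform_v(g, 2)
  # uniform density: gradient vanishes, advection dominates entirely
  sol <- lagr_fake(g, list(v), list(rep(3, g$n), rep(3, g$n)), sigma = 0)
  seeds <- matrix(c(3, 2, 2), 1, dimnames = list(NULL, c("x", "y", "z")))
  paths <- trace_pathlines(list(sol), seeds)
  expect_true(all(is.infinite(paths$paths[[1]]$peclet)))
  # linear density ramp rho = x: |grad rho| = 1, Pe = rho |v| / sigma
  idx <- uromt:::cell_index_triples(g)
  ramp <- as.numeric(idx[, 1])
  sigma <- 0.01
  sol2 <- lagr_fake(g, list(v), list(ramp, ramp), sigma = sigma)
  paths2 <- trace_pathlines(list(sol2), seeds)
  rho_here <- 3  # ramp value at the seed x = 3
  expect_equal(paths2$paths[[1]]$peclet[1], rho_here * 2 / (sigma * 1),
               tolerance = 1e-9)
})

test_that("flux-vector norms never exceed the path arc length", {
  set.seed(71)
  g <- grid_spec(6, 6, 6, dt = 0.4, m = 3)
  rho <- blob_field(g)
  sol <- lagr_fake(g, replicate(g$m, stats::rnorm(3 * g$n, sd = 1),
                                simplify = FALSE),
                   replicate(g$m + 1L, rho, simplify = FALSE))
  seeds <- seed_points(rho, g, threshold = 0.3, stride = 2)
  paths <- trace_pathlines(list(sol), seeds)
  fv <- flux_vectors(paths)
  arcs <- vapply(paths$paths, uromt:::path_arc_length, numeric(1))
  expect_true(all(fv$norm <= arcs + 1e-12))
})

test_that("speed-line attributes agree with the interpolated speed map", {
  set.seed(72)
  g <- grid_spec(6, 6, 6, dt = 0.4, m = 2)
  rho <- blob_field(g)
  v_steps <- replicate(g$m, stats::rnorm(3 * g$n, sd = 0.3), simplify = FALSE)
  sol <- lagr_fake(g, v_steps, replicate(g$m + 1L, rho, simplify = FALSE))
  seeds <- seed_points(rho, g, threshold = 0.5, stride = 2)
  paths <- trace_pathlines(list(sol), seeds)
  # first-vertex speed equals the interpolated velocity norm at the seed
  vc <- uromt:::split_velocity(g, v_steps[[1]])
  sp_seed <- sqrt(uromt:::trilinear_interp(g, vc$x, seeds)^2 +
                  uromt:::trilinear_interp(g, vc$y, seeds)^2 +
                  uromt:::trilinear_interp(g, vc$z, seeds)^2)
  first <- vapply(paths$paths, function(p) p$speed[1], numeric(1))
  expect_equal(first, sp_seed, tolerance = 1e-12)
  # seeds sit on cell centers, so this equals the speed map there
  smap <- speed_map(v_steps[[1]], g)
  at_centers <- smap[uromt:::flatten_index(g, seeds[, 1], seeds[, 2],
                                           seeds[, 3])]
  expect_equal(first, at_centers, tolerance = 1e-12)
})
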