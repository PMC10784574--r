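#' Run the transport solver over an image sequence
#'
#' Chains `q - 1` transport loops over a time-ordered sequence of `q`
#' images: loop `k` fits the velocity and relative source carrying frame
#' `k - 1` to frame `k`. With `chain_interpolations = TRUE`, loop `k > 1`
#' starts from the previous loop's final interpolated image instead of the
#' raw frame, which keeps the prolonged dynamics temporally smooth and
#' avoids re-injecting frame noise.
#'
#' @param images List of `q >= 2` length-`n` nonnegative images.
#' @param indicators Per-loop indicators: `NULL` (all-ones everywhere), a
#'   single length-`n` vector shared by all loops, or a list of length
#'   `q - 1` whose element `k` is either a length-`n` vector (held constant
#'   over substeps) or a list of `m` per-substep vectors.
#' @param params A [uromt_params()] object.
#' @param grid A [grid_spec()] object.
#' @param chain_interpolations Start each loop from the previous loop's
#'   final interpolation.
#' @return List of `q - 1` [gauss_newton()] solutions, in loop order.
#' @export
run_multiframe <- function(images, indicators = NULL, params, grid,
                           chain_interpolations = FALSE) {
  q <- length(images)
  if (q < 2) stop("need at least two images")
  for (im in images) check_scalar_field(grid, im, "image")
  n_loops <- q - 1L
  ind_list <- resolve_indicators(indicators, n_loops, grid)
  solver <- diffusion_solver(grid, params$sigma)
  solutions <- vector("list", n_loops)
  rho_start <- images[[1L]]
  for (k in seq_len(n_loops)) {
    if (params$verbose) message(sprintf("loop %d of %d", k, n_loops))
    sol <- tryCatch(
      gauss_newton(rho_start, images[[k + 1L]], ind_list[[k]], params, grid,
                   solver = solver),
      error = function(e) stop(sprintf("loop %d: %s", k, conditionMessage(e)),
                               call. = FALSE))
    solutions[[k]] <- sol
    rho_start <- if (chain_interpolations)
      pmax(sol$seq$rho[[grid$m + 1L]], 0) else images[[k + 1L]]
  }
  solutions
}

# normalize the accepted indicator conventions to a list of length n_loops,
# each element a single vector or a per-substep list
resolve_indicators <- function(indicators, n_loops, grid) {
  if (is.null(indicators))
    return(replicate(n_loops, rep.int(1, grid$n), simplify = FALSE))
  if (!is.list(indicators))
    return(replicate(n_loops, indicators, simplify = FALSE))
  if (length(indicators) != n_loops)
    stop(sprintf("indicators list has length %d; expected q - 1 = %d",
                 length(indicators), n_loops))
  indicators
}
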