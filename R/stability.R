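#' Probability that a neuron's summed input is positive
#'
#' With `n_active` neurons firing, a neuron's input accumulation is a sum of
#' `n_active` synapses that are +1 with probability `e1` and -1 otherwise
#' (a random-sampling picture of the matrix columns).  The number of +1
#' terms is binomial, and for large counts the firing probability
#' `P(X > 0) = P(successes > n/2)` is approximated by the truncated normal
#' form `pnorm((n - n*e1)/sigma) - pnorm((n/2 - n*e1)/sigma)` with
#' `sigma = sqrt(n * e1 * (1 - e1))`; the first term implements the
#' truncation at `n` successes.  `continuity = TRUE` applies the half-unit
#' continuity correction, which tracks the exact binomial tail closely (the
#' uncorrected form overshoots near `e1 = 0.5`, where the mass of the tied
#' outcome — silent by the threshold rule — is largest).
#'
#' @param n_active number of currently active neurons (positive).
#' @param e1 excitatory fraction in \[0, 1\]; the degenerate limits are
#'   handled exactly (`e1 = 1` gives 1 for `n_active >= 1`, `e1 = 0` gives 0).
#' @param continuity apply the continuity correction?  Default `FALSE`
#'   (plain normal approximation).
#' @return firing probability in \[0, 1\].
#' @examples
#' firing_probability(100, 0.5)  # ~0.5
#' @export
firing_probability <- function(n_active, e1, continuity = FALSE) {
  if (any(n_active <= 0)) stop_param("`n_active` must be positive")
  if (e1 < 0 || e1 > 1) stop_param("`e1` must be in [0, 1]")
  if (e1 == 1) return(rep_len(1, length(n_active)))
  if (e1 == 0) return(rep_len(0, length(n_active)))
  sigma <- sqrt(n_active * e1 * (1 - e1))
  # with the half-unit correction the lower boundary sits between the largest
  # non-firing success count floor(n/2) and the smallest firing one
  hi <- n_active + if (continuity) 0.5 else 0
  lo <- if (continuity) floor(n_active / 2) + 0.5 else n_active / 2
  stats::pnorm((hi - n_active * e1) / sigma) -
    stats::pnorm((lo - n_active * e1) / sigma)
}

#' Equilibrium active-neuron count of a random assembly
#'
#' The expected number of active neurons evolves as
#' `n(t+1) = N * firing_probability(n(t), e1)`; equilibria are the fixed
#' points of this transcendental map.  Zero is always a fixed point; the
#' solver scans the map for sign changes, refines each crossing with
#' [stats::uniroot()], classifies each root as dynamically stable or
#' unstable from the local map slope, and returns the largest stable root.
#' An assembly with no stable positive root is `extinct` (over-inhibited:
#' activity dies out); a stable root near `N` is `saturated`
#' (over-excited); anything in between is `stable`.
#'
#' @param n_total total neuron count `N`.
#' @param e1 excitatory fraction.
#' @param tol root-finding tolerance.
#' @param continuity passed to [firing_probability()].
#' @param saturation_frac fraction of `N` above which a root is classified
#'   as saturated (default 0.95).
#' @return an object of class `stability_prediction`: list with `n_total`,
#'   `e1`, `n_star`, `classification`, `roots` (data frame of all positive
#'   roots with stability), `iterations`.
#' @examples
#' solve_equilibrium(500, 0.5)$n_star  # ~250
#' @export
solve_equilibrium <- function(n_total, e1, tol = 1e-8, continuity = FALSE,
                              saturation_frac = 0.95) {
  if (n_total < 1) stop_param("`n_total` must be >= 1")
  if (e1 == 1) {
    return(structure(list(n_total = n_total, e1 = e1, n_star = n_total,
                          classification = "saturated",
                          roots = data.frame(root = n_total, stable = TRUE),
                          iterations = 0L),
                     class = "stability_prediction"))
  }
  if (e1 == 0) {
    return(structure(list(n_total = n_total, e1 = e1, n_star = 0,
                          classification = "extinct",
                          roots = data.frame(root = numeric(), stable = logical()),
                          iterations = 0L),
                     class = "stability_prediction"))
  }
  g <- function(n) n_total * firing_probability(n, e1, continuity = continuity)
  f <- function(n) g(n) - n
  grid <- seq(1e-6, n_total, length.out = 2048L)
  fg <- vapply(grid, f, numeric(1))
  iterations <- length(grid)
  roots <- numeric()
  for (i in seq_len(length(grid) - 1L)) {
    if (fg[i] == 0) roots <- c(roots, grid[i])
    if (fg[i] * fg[i + 1L] < 0) {
      u <- stats::uniroot(f, c(grid[i], grid[i + 1L]), tol = tol)
      roots <- c(roots, u$root)
      iterations <- iterations + u$iter
    }
  }
  # full saturation makes f vanish at the endpoint without a sign change
  if (fg[length(grid)] == 0) roots <- c(roots, n_total)
  if (length(roots)) {
    h <- pmax(roots * 1e-5, 1e-7)
    slope <- (vapply(roots + h, g, numeric(1)) -
                vapply(pmax(roots - h, 1e-9), g, numeric(1))) / (2 * h)
    stable <- abs(slope) < 1
  } else {
    stable <- logical()
  }
  roots_df <- data.frame(root = roots, stable = stable)
  if (any(stable)) {
    n_star <- max(roots[stable])
    classification <- if (n_star >= saturation_frac * n_total) "saturated" else "stable"
  } else {
    n_star <- 0
    classification <- "extinct"
  }
  structure(list(n_total = n_total, e1 = e1, n_star = n_star,
                 classification = classification, roots = roots_df,
                 iterations = iterations),
            class = "stability_prediction")
}

#' @export
print.stability_prediction <- function(x, ...) {
  cat(sprintf("<stability_prediction> N = %d, E1 = %.3f: %s, n* = %.1f\n",
              x$n_total, x$e1, x$classification, x$n_star))
  if (nrow(x$roots)) {
    cat(sprintf("  positive roots: %s\n",
                paste(sprintf("%.1f%s", x$roots$root,
                              ifelse(x$roots$stable, "", " (unstable)")),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Predicted versus simulated assembly activity over a parameter grid
#'
#' For every combination of neuron count, excitatory fraction and synapse
#' density, runs seeded simulations, measures the steady-state mean active
#' count over the trailing half of the run, and pairs it with the
#' theoretical equilibrium.  The theory depends only on `(N, E1)`; in a
#' closed assembly the density (the proportion of zeros in `M`) does not
#' enter, which the density axis of the grid lets one verify empirically.
#'
#' @param n_list integer vector of neuron counts.
#' @param e1_list numeric vector of excitatory fractions.
#' @param density_list numeric vector of densities (default 1).
#' @param steps simulation length per run (steady state is measured over
#'   the trailing half).
#' @param n_seeds replicate simulations per grid cell.
#' @param seed base seed.
#' @param continuity passed to [solve_equilibrium()].
#' @return an object of class `phase_diagram`: a data frame with one row
#'   per grid cell: `n`, `e1`, `density`, `predicted`, `classification`,
#'   `simulated` (mean over seeds), `sim_sd`.
#' @export
phase_diagram <- function(n_list, e1_list, density_list = 1, steps = 2000,
                          n_seeds = 10L, seed = 1L, continuity = FALSE) {
  grid <- expand.grid(n = n_list, e1 = e1_list, density = density_list,
                      KEEP.OUT.ATTRS = FALSE)
  grid$predicted <- NA_real_
  grid$classification <- NA_character_
  grid$simulated <- NA_real_
  grid$sim_sd <- NA_real_
  for (i in seq_len(nrow(grid))) {
    pred <- solve_equilibrium(grid$n[i], grid$e1[i], continuity = continuity)
    acts <- vapply(seq_len(n_seeds), function(k) {
      sk <- derive_seed(seed, i * 1000L + k)
      mm <- random_connection_matrix(grid$n[i], e1 = grid$e1[i],
                                     density = grid$density[i], seed = sk)
      raster <- simulate_assembly(mm, steps = steps, init = "single", seed = sk)
      rows <- (steps %/% 2L):steps + 1L
      mean(rowSums(raster$spikes[rows, , drop = FALSE]))
    }, numeric(1))
    grid$predicted[i] <- pred$n_star
    grid$classification[i] <- pred$classification
    grid$simulated[i] <- mean(acts)
    grid$sim_sd[i] <- stats::sd(acts)
  }
  class(grid) <- c("phase_diagram", "data.frame")
  grid
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("<phase_diagram> theory vs simulation\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @param x a `phase_diagram`.
#' @param ... passed to `plot`.
#' @describeIn phase_diagram predicted and simulated activity against the
#'   excitatory fraction.
#' @export
plot.phase_diagram <- function(x, ...) {
  graphics::plot(x$e1, x$simulated, xlab = "excitatory fraction E1",
                 ylab = "mean active neurons", pch = 16, ...)
  graphics::points(x$e1, x$predicted, col = 2, pch = 1)
  graphics::legend("topleft", legend = c("simulated", "predicted"),
                   pch = c(16, 1), col = c(1, 2), bty = "n")
  invisible(x)
}
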