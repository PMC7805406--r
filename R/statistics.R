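#' Spike probabilities and mean accumulations of a raster
#'
#' The model's output variable is the spike probability `P_i`: the long-run
#' fraction of time steps on which neuron `i` fires.  Alongside it this
#' computes the mean accumulation `Xbar_i`, the time-averaged pre-threshold
#' input.  With `burn_in = "auto-cycle"` the analysis window is exactly one
#' attractor period after the transient, which makes both quantities exact
#' rationals with denominator equal to the period; if no attractor is found
#' within the recorded run the trailing half of the run is used instead,
#' with a warning.
#'
#' @param raster a [simulate_assembly()] result.
#' @param burn_in `"auto-cycle"` (default) or an integer number of initial
#'   steps to discard; the window is then `[burn_in, steps]`.
#' @return an object of class `spike_stats`: list with `p`, `xbar`,
#'   `counts` (integer spike counts), `xsum` (summed accumulations),
#'   `window` (`[from, to)` time indices), `width`, `period` (NA unless
#'   exact), and `exact_over_cycle`.
#' @examples
#' ring <- connection_matrix(rbind(c(0, 1), c(1, 0)))
#' s <- spike_probabilities(simulate_assembly(ring, 20, init = c(1, 0)))
#' s$p
#' @export
spike_probabilities <- function(raster, burn_in = "auto-cycle") {
  stopifnot(inherits(raster, "spike_raster"))
  exact <- FALSE
  period <- NA_integer_
  if (identical(burn_in, "auto-cycle")) {
    cyc <- raster_cycle(raster)
    if (cyc$found) {
      # start one step inside the attractor so that the accumulations of the
      # window are produced entirely by in-attractor states (the accumulation
      # at the re-entry step still depends on the last transient state)
      a <- cyc$transient + 1L
      period <- cyc$period
      if (a + period - 1L <= raster$steps) {
        from <- a
        to <- a + period
        exact <- TRUE
      } else {
        warning("attractor does not fit in the recorded run; ",
                "using trailing half instead")
        from <- max(1L, raster$steps %/% 2L)
        to <- raster$steps + 1L
      }
    } else {
      warning("no attractor found in the recorded run; using trailing half")
      from <- max(1L, raster$steps %/% 2L)
      to <- raster$steps + 1L
    }
  } else {
    if (burn_in >= raster$steps) {
      stop_param("`burn_in` must be smaller than the run length")
    }
    from <- max(1L, as.integer(burn_in))
    to <- raster$steps + 1L
  }
  rows <- (from:(to - 1L)) + 1L
  width <- length(rows)
  counts <- colSums(raster$spikes[rows, , drop = FALSE])
  xsum <- colSums(raster$accum[rows, , drop = FALSE])
  structure(list(p = counts / width, xbar = xsum / width, counts = counts,
                 xsum = xsum, window = c(from, to), width = width,
                 period = period, exact_over_cycle = exact, n = raster$n),
            class = "spike_stats")
}

#' @export
print.spike_stats <- function(x, ...) {
  cat(sprintf("<spike_stats> %d neurons, window [%d, %d)%s\n", x$n,
              x$window[1L], x$window[2L],
              if (x$exact_over_cycle)
                sprintf(", exact over one period (T = %d)", x$period)
              else ""))
  cat(sprintf("  P: mean %.3f, range [%.3f, %.3f]; mean Xbar %.3f\n",
              mean(x$p), min(x$p), max(x$p), mean(x$xbar)))
  invisible(x)
}

#' Conservation identity between accumulations and spike probabilities
#'
#' Over one full attractor period with no external input the mean
#' accumulation satisfies `Xbar = P %*% M` exactly: every input that a
#' neuron integrates during a cycle is a spike some neuron emitted during
#' that same cycle.  The residual `Xbar - P %*% M` is computed from the
#' integer counts, so over an exact cycle window it is identically zero.
#' If the statistics were not computed over a full period the identity is
#' only approximate and a warning is issued.
#'
#' @param stats a [spike_probabilities()] result.
#' @param m the [connection_matrix()] that generated the raster.
#' @return numeric residual vector (one entry per neuron).
#' @export
accumulation_residual <- function(stats, m) {
  stopifnot(inherits(stats, "spike_stats"), inherits(m, "connection_matrix"))
  if (!stats$exact_over_cycle) {
    warning("statistics are not exact over one attractor period; ",
            "the conservation identity is only approximate")
  }
  as.vector(stats$xsum - stats$counts %*% unclass(m)) / stats$width
}

#' Shannon entropy of a spike-probability vector
#'
#' Two variants are provided.  `"as-printed"` is the form the polarization
#' argument manipulates, `-sum(P_i * ln(P_i))`; `"bernoulli"` is the
#' per-neuron Bernoulli entropy `-sum(P_i ln P_i + (1 - P_i) ln(1 - P_i))`.
#' Natural logarithm throughout; terms with `P_i` equal to 0 (or 1, for the
#' Bernoulli variant) contribute zero (`0 * log 0 = 0`).
#'
#' @param p vector of spike probabilities in \[0, 1\].
#' @param variant `"as-printed"` (default) or `"bernoulli"`.
#' @return a non-negative scalar.
#' @examples
#' shannon_entropy(c(0.5, 0.5))  # = ln 2
#' @export
shannon_entropy <- function(p, variant = c("as-printed", "bernoulli")) {
  variant <- match.arg(variant)
  if (any(p < 0 | p > 1)) stop_param("probabilities must be in [0, 1]")
  plogp <- function(q) ifelse(q > 0, q * log(q), 0)
  s <- -sum(plogp(p))
  if (variant == "bernoulli") s <- s - sum(plogp(1 - p))
  s
}

#' Boltzmann entropy of an attractor
#'
#' An attractor of period `T` visited uniformly carries entropy
#' `k * ln(T)`.  Because the cycle is generated by deterministic dynamic
#' rules rather than being fully random, it is bounded by the Shannon
#' entropy of the spike probabilities: `S_T <= S_P`.
#'
#' @param period attractor period (>= 1; 1 means fixed point).
#' @param k scale constant, 1 by default.
#' @return `k * ln(period)`.
#' @export
boltzmann_entropy <- function(period, k = 1) {
  if (any(period < 1)) stop_param("`period` must be >= 1")
  k * log(period)
}

#' Fit the logistic spike-probability law
#'
#' Across the neurons of a stationary assembly, spike probability follows a
#' logistic function of the mean accumulation,
#' `P = 1 / (1 + exp(A * Xbar + C))` with `A < 0`.  The parameters are
#' estimated by least squares on the logit scale:
#' `logit(P) = -(A * Xbar + C)`.  Probabilities are clipped to
#' `[eps, 1 - eps]` before the transform.  On data generated exactly from
#' the law this recovers `(A, C)` to numerical precision; an optional
#' nonlinear refinement (`method = "nls"`) re-fits on the probability scale
#' starting from the logit solution.
#'
#' @param p vector of spike probabilities.
#' @param xbar vector of mean accumulations (same length).
#' @param eps clipping bound applied to `p` before the logit transform.
#' @param method `"logit-ls"` (default) or `"nls"`.
#' @return an object of class `logistic_fit`: list with `a`, `c`, `r2`,
#'   `n_points` and `method`.
#' @examples
#' x <- seq(-4, 4, length.out = 40)
#' f <- fit_logistic(1 / (1 + exp(-2 * x + 1)), x)
#' coef(f)  # a = -2, c = 1
#' @export
fit_logistic <- function(p, xbar, eps = 1e-6, method = c("logit-ls", "nls")) {
  method <- match.arg(method)
  if (length(p) != length(xbar)) stop_param("`p` and `xbar` lengths differ")
  if (length(p) < 3L) stop_param("need at least 3 points to fit")
  if (stats::var(xbar) == 0) stop_param("degenerate fit: `xbar` is constant")
  pc <- pmin(pmax(p, eps), 1 - eps)
  if (all(pc %in% c(eps, 1 - eps))) {
    stop_param("degenerate fit: all probabilities saturated at 0 or 1")
  }
  y <- logit(pc)
  fit <- stats::lm(y ~ xbar)
  a <- -unname(stats::coef(fit)[2L])
  cc <- -unname(stats::coef(fit)[1L])
  # a flat response carries no relation at all: report r2 = 0, not NaN
  r2 <- if (stats::var(y) == 0) 0 else summary(fit)$r.squared
  if (method == "nls") {
    nfit <- try(suppressWarnings(
      stats::nls(p ~ 1 / (1 + exp(a * xbar + c)),
                 start = list(a = a, c = cc),
                 control = stats::nls.control(warnOnly = TRUE))),
      silent = TRUE)
    if (!inherits(nfit, "try-error")) {
      a <- unname(stats::coef(nfit)["a"])
      cc <- unname(stats::coef(nfit)["c"])
      r2 <- 1 - sum(stats::resid(nfit)^2) / sum((p - mean(p))^2)
    }
  }
  structure(list(a = a, c = cc, r2 = r2, n_points = length(p),
                 method = method, eps = eps),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> P = 1 / (1 + exp(A*Xbar + C)): A = %.4f, C = %.4f\n",
              x$a, x$c))
  cat(sprintf("  r^2 = %.4f on %d points (%s)\n", x$r2, x$n_points, x$method))
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) c(a = object$a, c = object$c)

#' @param object a `logistic_fit`.
#' @param xbar accumulations at which to evaluate the fitted law.
#' @param ... ignored.
#' @describeIn fit_logistic predicted spike probabilities at new
#'   accumulation values.
#' @export
predict.logistic_fit <- function(object, xbar, ...) {
  1 / (1 + exp(object$a * xbar + object$c))
}

#' Entropy polarization under increasing stimulation
#'
#' Drives an assembly with a nested, increasing schedule of clamped
#' (persistently activated) neuron sets and measures, at each stage, the
#' Shannon entropy of the non-clamped ("observed") neurons' spike
#' probabilities and their mean active count.  Increasing stimulation
#' polarizes the observed spike probabilities toward 0 or 1, so the entropy
#' falls stage by stage; this is the model's picture of how accumulating
#' evidence sharpens a decision.
#'
#' @param m a [connection_matrix()].
#' @param clamp_schedule list of integer index vectors, nested and
#'   increasing (each stage's clamped set contains the previous one); an
#'   empty first element measures the closed-assembly baseline.
#' @param steps simulation length per stage.
#' @param seed integer seed (initial state; shared across stages).
#' @return an object of class `polarization_series`: a data frame with one
#'   row per stage (`n_clamped`, `entropy`, `active_mean`, `n_free`) and the
#'   per-stage probability vectors in `attr(, "p")`.
#' @export
polarization_experiment <- function(m, clamp_schedule, steps = 1200, seed = NULL) {
  stopifnot(inherits(m, "connection_matrix"))
  n <- nrow(m)
  prev <- integer()
  for (s in clamp_schedule) {
    if (!all(prev %in% s)) stop_param("clamp schedule must be nested/increasing")
    prev <- s
  }
  rows <- vector("list", length(clamp_schedule))
  pvecs <- vector("list", length(clamp_schedule))
  for (k in seq_along(clamp_schedule)) {
    clamped <- as.integer(clamp_schedule[[k]])
    protocol <- if (length(clamped)) {
      stimulus_protocol(protocol_window(0, Inf, clamp_on = clamped))
    } else {
      NULL
    }
    raster <- simulate_assembly(m, steps = steps, init = "single",
                                protocol = protocol, seed = seed)
    stats <- suppressWarnings(spike_probabilities(raster))
    free <- setdiff(seq_len(n), clamped)
    p_free <- stats$p[free]
    rows[[k]] <- data.frame(stage = k, n_clamped = length(clamped),
                            n_free = length(free),
                            entropy = shannon_entropy(p_free),
                            active_mean = sum(p_free))
    pvecs[[k]] <- stats$p
  }
  out <- do.call(rbind, rows)
  attr(out, "p") <- pvecs
  class(out) <- c("polarization_series", "data.frame")
  out
}

#' @export
print.polarization_series <- function(x, ...) {
  cat("<polarization_series>\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
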