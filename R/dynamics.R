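#' One synchronous update of a threshold assembly
#'
#' Computes the input accumulation `X_j = sum_i state_i * M[i, j] +
#' external_j` for every neuron and applies the threshold rule: a neuron
#' fires (1) iff `X_j > 0`; an accumulation of exactly zero leaves the
#' neuron silent.  Clamps override the threshold result *after* `X` is
#' computed, so clamped neurons still contribute to other neurons' inputs.
#'
#' @param state binary 0/1 vector of length `n` (the current state).
#' @param m a [connection_matrix()].
#' @param external optional numeric vector of additive inputs `S_i`.
#' @param clamp_on,clamp_off neuron indices forced to 1 (resp. 0).
#' @return a list with `values` (the next 0/1 state) and `accum` (the
#'   pre-threshold accumulations `X`).
#' @examples
#' m <- connection_matrix(rbind(c(0, 1), c(-1, 0)))
#' step_assembly(c(1, 0), m)$values
#' @export
step_assembly <- function(state, m, external = NULL, clamp_on = integer(),
                          clamp_off = integer()) {
  n <- nrow(m)
  if (length(state) != n) {
    stop_param("state length ", length(state), " does not match matrix n = ", n)
  }
  x <- as.vector(state %*% unclass(m))
  if (!is.null(external)) {
    if (length(external) != n) {
      stop_param("external input must have length n = ", n)
    }
    x <- x + external
  }
  values <- as.numeric(x > 0)
  if (length(clamp_on)) values[clamp_on] <- 1
  if (length(clamp_off)) values[clamp_off] <- 0
  list(values = values, accum = x)
}

#' Simulate a threshold assembly
#'
#' Iterates the synchronous dynamics for `steps` updates, recording the
#' binary firing history (spike raster) and the pre-threshold accumulations.
#' Row `t + 1` of the raster is the state at time `t` (time is 0-based);
#' the default initial state has exactly one active neuron, chosen by the
#' seeded RNG.  A run is a pure function of (matrix, initial state,
#' protocol, seed): re-running with the same arguments is bitwise
#' reproducible.
#'
#' @param m a [connection_matrix()].
#' @param steps number of updates (>= 1).
#' @param init initial state: `"single"` (one seeded random active neuron)
#'   or a binary vector of length `n`.
#' @param protocol an optional [stimulus_protocol()] (or an internal
#'   `function(t)` drive).
#' @param seed optional integer seed (used only for the default `init`).
#' @return an object of class `spike_raster`: a list with `spikes`
#'   (`(steps + 1) x n` binary matrix), `accum` (same shape; the first row,
#'   the initial state, has no accumulation and is `NA`), `protocol`,
#'   `seed` and `init`.
#' @examples
#' ring <- connection_matrix(rbind(c(0, 1), c(1, 0)))
#' r <- simulate_assembly(ring, steps = 6, init = c(1, 0))
#' r$spikes
#' @export
simulate_assembly <- function(m, steps, init = "single", protocol = NULL,
                              seed = NULL) {
  stopifnot(inherits(m, "connection_matrix"))
  if (steps < 1) stop_param("`steps` must be >= 1")
  n <- nrow(m)
  validate_protocol(protocol, n)
  if (identical(init, "single")) {
    state <- numeric(n)
    state[with_seed(seed, sample.int(n, 1L))] <- 1
  } else {
    if (length(init) != n || !all(init %in% c(0, 1))) {
      stop_param("`init` must be a 0/1 vector of length n = ", n)
    }
    state <- as.numeric(init)
  }
  ctl0 <- protocol_at(protocol, 0, n)
  if (length(ctl0$clamp_on)) state[ctl0$clamp_on] <- 1
  if (length(ctl0$clamp_off)) state[ctl0$clamp_off] <- 0

  spikes <- matrix(0, steps + 1L, n)
  accum <- matrix(NA_real_, steps + 1L, n)
  spikes[1L, ] <- state
  mm <- unclass(m)
  for (t in seq_len(steps)) {
    ctl <- protocol_at(protocol, t, n)
    x <- as.vector(state %*% mm)
    if (!is.null(ctl$external)) x <- x + ctl$external
    state <- as.numeric(x > 0)
    if (length(ctl$clamp_on)) state[ctl$clamp_on] <- 1
    if (length(ctl$clamp_off)) state[ctl$clamp_off] <- 0
    spikes[t + 1L, ] <- state
    accum[t + 1L, ] <- x
  }
  structure(list(spikes = spikes, accum = accum, protocol = protocol,
                 seed = seed, init = init, n = n, steps = steps),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d neurons, %d steps (rows 0..%d)\n",
              x$n, x$steps, x$steps))
  act <- rowSums(x$spikes)
  cat(sprintf("  active neurons: start %d, end %d, mean %.1f\n",
              act[1L], act[length(act)], mean(act)))
  invisible(x)
}

#' @param x a `spike_raster`.
#' @param ... ignored.
#' @describeIn simulate_assembly dot plot of the spike raster (time on the
#'   x-axis, one row per neuron).
#' @export
plot.spike_raster <- function(x, ...) {
  idx <- which(x$spikes == 1, arr.ind = TRUE)
  graphics::plot(idx[, 1L] - 1L, idx[, 2L], pch = ".", cex = 1.5,
                 xlab = "time step", ylab = "neuron",
                 main = "spike raster", ...)
  invisible(x)
}

#' Detect the attractor of a trajectory
#'
#' The state space of an `n`-neuron assembly is finite (`2^n` states) and the
#' dynamics are deterministic, so under a time-invariant drive every
#' trajectory ends in a fixed point or a loop.  `detect_cycle()` iterates
#' the dynamics and finds the smallest `(transient, period)` by state-revisit
#' hashing; hashing starts once the protocol has become time-invariant.
#' The search is capped at `horizon` steps and reports `found = FALSE`
#' (a valid result, not an error) if no revisit occurs within the cap.
#'
#' @inheritParams simulate_assembly
#' @param init initial 0/1 state vector.
#' @param horizon maximum number of steps to search (>= 1).
#' @return an object of class `cycle_info`: list with `found`,
#'   `transient_length` (steps before the attractor is entered, counted from
#'   time 0), `period` (1 means fixed point) and `horizon`.
#' @examples
#' ring <- connection_matrix(rbind(c(0, 1), c(1, 0)))
#' detect_cycle(ring, c(1, 0), horizon = 10)
#' @export
detect_cycle <- function(m, init, protocol = NULL, horizon = 1000L) {
  stopifnot(inherits(m, "connection_matrix"))
  if (horizon < 1) stop_param("`horizon` must be >= 1")
  n <- nrow(m)
  validate_protocol(protocol, n)
  if (length(init) != n || !all(init %in% c(0, 1))) {
    stop_param("`init` must be a 0/1 vector of length n = ", n)
  }
  t0 <- protocol_stationary_from(protocol)
  if (!is.finite(t0)) {
    stop_param("protocol never becomes time-invariant; periodicity is undefined")
  }
  state <- as.numeric(init)
  ctl0 <- protocol_at(protocol, 0, n)
  if (length(ctl0$clamp_on)) state[ctl0$clamp_on] <- 1
  if (length(ctl0$clamp_off)) state[ctl0$clamp_off] <- 0
  seen <- new.env(hash = TRUE, parent = emptyenv())
  mm <- unclass(m)
  record <- function(state, t) {
    key <- paste(state, collapse = "")
    prev <- seen[[key]]
    if (!is.null(prev)) return(prev)
    seen[[key]] <- t
    NULL
  }
  if (t0 <= 0) {
    hit <- record(state, 0)
  }
  for (t in seq_len(horizon)) {
    ctl <- protocol_at(protocol, t, n)
    x <- as.vector(state %*% mm)
    if (!is.null(ctl$external)) x <- x + ctl$external
    state <- as.numeric(x > 0)
    if (length(ctl$clamp_on)) state[ctl$clamp_on] <- 1
    if (length(ctl$clamp_off)) state[ctl$clamp_off] <- 0
    if (t >= t0) {
      hit <- record(state, t)
      if (!is.null(hit)) {
        return(structure(list(found = TRUE, transient_length = hit,
                              period = t - hit, horizon = horizon),
                         class = "cycle_info"))
      }
    }
  }
  structure(list(found = FALSE, transient_length = NA_integer_,
                 period = NA_integer_, horizon = horizon),
            class = "cycle_info")
}

#' @export
print.cycle_info <- function(x, ...) {
  if (x$found) {
    cat(sprintf("<cycle_info> attractor found: transient %d, period %d%s\n",
                x$transient_length, x$period,
                if (x$period == 1L) " (fixed point)" else ""))
  } else {
    cat(sprintf("<cycle_info> no attractor within horizon %d\n", x$horizon))
  }
  invisible(x)
}

# Locate the attractor inside an already-recorded raster by row hashing.
# Returns list(found, transient, period).  Hashing honours the protocol's
# stationary point, like detect_cycle().
raster_cycle <- function(raster) {
  t0 <- protocol_stationary_from(raster$protocol)
  if (!is.finite(t0)) return(list(found = FALSE))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (t in t0:raster$steps) {
    key <- paste(raster$spikes[t + 1L, ], collapse = "")
    prev <- seen[[key]]
    if (!is.null(prev)) {
      return(list(found = TRUE, transient = prev, period = t - prev))
    }
    seen[[key]] <- t
  }
  list(found = FALSE)
}
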