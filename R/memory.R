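#' Periodic spike trains
#'
#' A spike train of "homogeneous spike probability" is a deterministic
#' periodic binary pattern: the firing fraction is `sum(pattern) /
#' length(pattern)` and the `phase` shifts the pattern in time.  The value
#' of the train at time `t` is `pattern[((t + phase) mod period) + 1]`.
#' Determinism matters here: phase coupling is a relationship between
#' reproducible phases, which stochastic trains of the same rate would not
#' carry.
#'
#' @param pattern binary 0/1 vector giving one period.
#' @param phase integer phase offset in `[0, period)`.
#' @return an object of class `spike_train`.
#' @examples
#' spike_train(c(1, 0, 0, 0))  # probability 0.25
#' @export
spike_train <- function(pattern, phase = 0L) {
  if (!length(pattern) || !all(pattern %in% c(0, 1))) {
    stop_param("`pattern` must be a nonempty 0/1 vector")
  }
  pattern <- as.integer(pattern)
  phase <- as.integer(phase) %% length(pattern)
  structure(list(pattern = pattern, phase = phase, period = length(pattern),
                 probability = mean(pattern)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> period %d, phase %d, probability %.3f: %s\n",
              x$period, x$phase, x$probability,
              paste(x$pattern, collapse = "")))
  invisible(x)
}

#' @param train a [spike_train()].
#' @param t time index (0-based; vectorized).
#' @describeIn spike_train value of the train at time `t`.
#' @export
train_at <- function(train, t) {
  stopifnot(inherits(train, "spike_train"))
  train$pattern[((t + train$phase) %% train$period) + 1L]
}

lcm2 <- function(a, b) {
  gcd <- function(x, y) if (y == 0) x else gcd(y, x %% y)
  a %/% gcd(a, b) * b
}

#' Phase coupling of two spike trains
#'
#' A downstream neuron receiving two periodic trains fires at `t + 1` iff
#' `a(t) + b(t + offset) > threshold`.  With threshold 1 both inputs must
#' coincide (synchronous coupling selects the phase intersection); with
#' threshold 0 either suffices (the union).  The output is periodic with
#' period `lcm(period_a, period_b)`; its firing probability therefore
#' depends jointly on the two rates, their relative phase and the
#' threshold — the same two trains can yield many different output rates.
#'
#' @param a,b input [spike_train()]s.
#' @param offset integer phase offset applied to `b`.
#' @param threshold non-negative integer firing threshold.
#' @return the downstream [spike_train()] (period = lcm of the input
#'   periods, phase encoding the one-step transmission lag).
#' @examples
#' a <- spike_train(c(1, 0, 0, 0)); b <- spike_train(c(1, 0))
#' couple_trains(a, b, offset = 0, threshold = 1)$probability  # 0.25
#' couple_trains(a, b, offset = 0, threshold = 0)$probability  # 0.5
#' @export
couple_trains <- function(a, b, offset = 0L, threshold = 1L) {
  stopifnot(inherits(a, "spike_train"), inherits(b, "spike_train"))
  if (threshold < 0) stop_param("`threshold` must be >= 0")
  period <- lcm2(a$period, b$period)
  t <- 0:(period - 1L)
  o <- as.integer(train_at(a, t) + train_at(b, t + offset) > threshold)
  # downstream value at time t+1 reflects inputs at time t
  spike_train(o, phase = -1L)
}

#' Assembly graph for the phase-coupling memory framework
#'
#' Builds the short-term-memory wiring: two input units receive external
#' spike trains; four mutually unconnected coupling units each receive
#' unidirectional excitatory links from both input units; a single output
#' neuron receives unidirectional links from all four coupling units and
#' sits under a step-up threshold modulator.  Because the coupling units
#' are independent of each other, the relative phase imprinted by the
#' inputs persists in their internal attractors after the inputs are
#' removed — that retained phase relationship is the memory trace, and the
#' output unit reads it out under increasing thresholds.
#'
#' @param unit_size neurons per input/coupling unit.
#' @param e1 excitatory fraction of the units' internal random matrices.
#' @param link_count number of inter-unit links per (source unit, target)
#'   pair.
#' @param density internal matrix density.
#' @param seed integer seed; builds are deterministic given the seed.
#' @return an object of class `assembly_graph`: list with `matrix` (global
#'   [connection_matrix()]), `units` (named list of index vectors, units
#'   `in1`, `in2`, `c1`..`c4`, `out`), `state` (current global 0/1 state),
#'   `t`, and the build parameters.
#' @export
build_memory_framework <- function(unit_size = 50L, e1 = 0.5, link_count = 10L,
                                   density = 1, seed = NULL) {
  if (unit_size < 1) stop_param("`unit_size` must be >= 1")
  unit_names <- c("in1", "in2", "c1", "c2", "c3", "c4")
  n <- 6L * unit_size + 1L
  units <- stats::setNames(lapply(0:5, function(k) k * unit_size + seq_len(unit_size)),
                           unit_names)
  units$out <- n
  mat <- matrix(0, n, n)
  for (k in seq_along(unit_names)) {
    sub <- random_connection_matrix(unit_size, e1 = e1, density = density,
                                    seed = if (is.null(seed)) NULL else derive_seed(seed, k))
    mat[units[[k]], units[[k]]] <- unclass(sub)
  }
  link_seed <- 10L
  add_links <- function(mat, from, to, k) {
    pick <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, k), {
      data.frame(src = sample(from, link_count, replace = link_count > length(from)),
                 dst = sample(to, link_count, replace = TRUE))
    })
    mat[cbind(pick$src, pick$dst)] <- 1
    mat
  }
  for (iu in c("in1", "in2")) {
    for (cu in c("c1", "c2", "c3", "c4")) {
      link_seed <- link_seed + 1L
      mat <- add_links(mat, units[[iu]], units[[cu]], link_seed)
    }
  }
  for (cu in c("c1", "c2", "c3", "c4")) {
    link_seed <- link_seed + 1L
    src <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, link_seed),
                     sample(units[[cu]], link_count,
                            replace = link_count > unit_size))
    mat[cbind(src, units$out)] <- 1
  }
  g <- structure(list(matrix = connection_matrix(mat,
                        meta = list(unit_size = unit_size, e1 = e1,
                                    link_count = link_count, density = density,
                                    seed = seed)),
                      units = units, state = numeric(n), t = 0L,
                      unit_size = unit_size, e1 = e1, link_count = link_count,
                      seed = seed),
                 class = "assembly_graph")
  validate_assembly_graph(g)
  g
}

# Structural invariants: all inter-unit links unidirectional, coupling
# units mutually unconnected, output projects nowhere.
validate_assembly_graph <- function(g) {
  mat <- unclass(g$matrix)
  u <- g$units
  cu <- c("c1", "c2", "c3", "c4")
  for (a in cu) for (b in cu) {
    if (a != b && any(mat[u[[a]], u[[b]]] != 0)) {
      stop_param("coupling units must be mutually unconnected")
    }
  }
  for (iu in c("in1", "in2")) {
    for (other in c(cu, "out")) {
      if (any(mat[u[[other]], u[[iu]]] != 0)) {
        stop_param("links into input units violate unidirectionality")
      }
    }
    if (any(mat[u[["in1"]], u[["in2"]]] != 0) ||
        any(mat[u[["in2"]], u[["in1"]]] != 0)) {
      stop_param("input units must not be interconnected")
    }
  }
  if (any(mat[u$out, ] != 0)) {
    stop_param("output unit must have no outgoing links")
  }
  invisible(g)
}

#' @export
print.assembly_graph <- function(x, ...) {
  cat(sprintf("<assembly_graph> 2 input + 4 coupling units of %d neurons + 1 output (n = %d)\n",
              x$unit_size, nrow(x$matrix)))
  cat(sprintf("  internal E1 = %.2f, %d links per inter-unit pair; t = %d, %d neurons active\n",
              x$e1, x$link_count, x$t, sum(x$state)))
  invisible(x)
}

# Simulate the graph for `steps` updates under an optional function(t)
# protocol (t relative to the current graph time); returns the raster and
# advances the stored state.
run_graph <- function(g, steps, protocol = NULL) {
  raster <- simulate_assembly(g$matrix, steps = steps, init = g$state,
                              protocol = protocol)
  g$state <- raster$spikes[steps + 1L, ]
  g$t <- g$t + steps
  list(graph = g, raster = raster)
}

#' Present an input mode, then remove it
#'
#' Drives the two input units with the mode's spike trains (clamping every
#' neuron of an input unit to its train's current value) for
#' `present_steps` updates, then removes the drive.  The returned graph
#' state carries the mode-dependent phase relationships in the coupling
#' units; with no further input the phase memory remains there, until a
#' new presentation overwrites it.
#'
#' @param g an [build_memory_framework()] graph.
#' @param mode a list with [spike_train()]s `a` (input unit 1) and `b`
#'   (input unit 2).
#' @param present_steps number of driven updates (0 returns `g` unchanged).
#' @return the updated `assembly_graph`.
#' @export
present_and_remove <- function(g, mode, present_steps = 200L) {
  stopifnot(inherits(g, "assembly_graph"),
            inherits(mode$a, "spike_train"), inherits(mode$b, "spike_train"))
  if (present_steps == 0L) return(g)
  u <- g$units
  protocol <- function(t) {
    on <- c(if (train_at(mode$a, t) == 1) u$in1,
            if (train_at(mode$b, t) == 1) u$in2)
    off <- c(if (train_at(mode$a, t) == 0) u$in1,
             if (train_at(mode$b, t) == 0) u$in2)
    list(clamp_on = on, clamp_off = off)
  }
  run_graph(g, present_steps, protocol)$graph
}

#' Recall: read the stored phase pattern under a step-up threshold
#'
#' With the inputs absent, runs the graph at each output-unit threshold
#' level in turn (state carries over between levels, mimicking a stepwise
#' modulator) and records the output neuron's spike probability per level.
#' The modulator is implemented, consistently with the threshold rule, as
#' an additive external input of `-threshold` on the output neuron.
#'
#' @param g an [build_memory_framework()] graph (after presentation).
#' @param schedule non-decreasing integer vector of threshold levels.
#' @param steps_per_level updates simulated at each level.
#' @param mode_id optional label for the report.
#' @return an object of class `recall_report`: list with `mode_id`,
#'   `schedule`, `p_out` (output spike probability per level).
#' @export
recall <- function(g, schedule = seq(0L, 40L, by = 5L), steps_per_level = 300L,
                   mode_id = NA_character_) {
  stopifnot(inherits(g, "assembly_graph"))
  if (is.unsorted(schedule)) stop_param("`schedule` must be non-decreasing")
  n <- nrow(g$matrix)
  out_idx <- g$units$out
  p_out <- numeric(length(schedule))
  for (k in seq_along(schedule)) {
    ext <- numeric(n)
    ext[out_idx] <- -schedule[k]
    protocol <- function(t) list(external = ext)
    res <- run_graph(g, steps_per_level, protocol)
    g <- res$graph
    p_out[k] <- mean(res$raster$spikes[-1L, out_idx])
  }
  structure(list(mode_id = mode_id, schedule = schedule, p_out = p_out),
            class = "recall_report")
}

#' @export
print.recall_report <- function(x, ...) {
  cat(sprintf("<recall_report> mode %s\n", x$mode_id))
  print(stats::setNames(round(x$p_out, 3), x$schedule))
  invisible(x)
}

#' Separability of recall profiles
#'
#' Quantifies the visual distinctness of recall heat-map rows: the
#' Euclidean distance between the per-level output probability vectors of
#' every pair of reports, plus a flag indicating whether all pairwise
#' distances exceed a floor.
#'
#' @param reports list of [recall()] reports sharing one schedule.
#' @param floor minimum pairwise distance for separability.
#' @return list with `distances` (symmetric matrix) and `separable`.
#' @export
distinguishability <- function(reports, floor = 0.05) {
  if (length(reports) < 2L) stop_param("need at least 2 reports")
  lens <- vapply(reports, function(r) length(r$p_out), numeric(1))
  if (length(unique(lens)) != 1L) {
    stop_param("reports have mismatched schedule lengths")
  }
  scheds <- vapply(reports, function(r) paste(r$schedule, collapse = ","), "")
  if (length(unique(scheds)) != 1L) {
    stop_param("reports were produced under different schedules")
  }
  mat <- do.call(rbind, lapply(reports, `[[`, "p_out"))
  d <- as.matrix(stats::dist(mat))
  dimnames(d) <- list(vapply(reports, `[[`, "", "mode_id"),
                      vapply(reports, `[[`, "", "mode_id"))
  list(distances = d, separable = all(d[upper.tri(d)] > floor))
}

#' Default input modes
#'
#' Three input modes built from the canonical probability-0.25 and
#' probability-0.5 trains at distinct relative phases.  The exact mode
#' patterns are configuration, not a fixed property of the framework.
#'
#' @return a named list of three modes, each a list of trains `a` and `b`.
#' @export
default_input_modes <- function() {
  a <- c(1L, 0L, 0L, 0L)
  b <- c(1L, 0L)
  list(mode1 = list(a = spike_train(a, 0L), b = spike_train(b, 0L)),
       mode2 = list(a = spike_train(a, 0L), b = spike_train(b, 1L)),
       mode3 = list(a = spike_train(a, 1L), b = spike_train(b, 0L)))
}

#' Full memory-recall experiment
#'
#' Builds the framework, then for each input mode presents the mode from
#' the same initial graph, removes it, and reads the memory out under the
#' step-up threshold schedule.
#'
#' @inheritParams build_memory_framework
#' @param modes named list of modes (default [default_input_modes()]).
#' @param present_steps presentation length.
#' @param schedule threshold schedule for [recall()].
#' @param steps_per_level updates per threshold level.
#' @return list with `reports` (one [recall()] report per mode) and
#'   `distinguishability`.
#' @export
memory_recall_experiment <- function(unit_size = 50L, e1 = 0.5, link_count = 10L,
                                     seed = NULL, modes = default_input_modes(),
                                     present_steps = 200L,
                                     schedule = seq(0L, 40L, by = 5L),
                                     steps_per_level = 300L) {
  g0 <- build_memory_framework(unit_size = unit_size, e1 = e1,
                               link_count = link_count, seed = seed)
  reports <- lapply(names(modes), function(nm) {
    g <- present_and_remove(g0, modes[[nm]], present_steps = present_steps)
    recall(g, schedule = schedule, steps_per_level = steps_per_level,
           mode_id = nm)
  })
  names(reports) <- names(modes)
  list(reports = reports,
       distinguishability = distinguishability(reports))
}
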