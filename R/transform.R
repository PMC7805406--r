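#' Raw weighted, thresholded, delayed networks
#'
#' A raw network is the biological starting point of the simplification
#' pipeline: neurons carry a type (excitatory neurons have only
#' non-negative outgoing weights, inhibitory only non-positive — one sign
#' per row), a real activation threshold, and synapses carry a real weight
#' and an integer conduction delay (in steps, >= 1).  The pipeline
#' [simplify_network()] rewrites such a network, step for step
#' behavior-preserving for integer parameters, into a unit
#' \{-1, 0, 1\} [connection_matrix()].
#'
#' @param neurons data frame with columns `id` (unique character), `type`
#'   (`"excitatory"`, `"inhibitory"` or `"unit"` — the untyped neurons the
#'   pipeline itself introduces, which may carry synapses of either sign),
#'   `threshold` (numeric).
#' @param synapses data frame with columns `src`, `dst`, `weight`, `delay`.
#'   Parallel synapses with equal `(src, dst, delay)` are aggregated by
#'   summing their weights.
#' @return an object of class `raw_network`: list with `neurons`,
#'   `synapses`, `seeded_active` (ids of units that must start active, e.g.
#'   the bias unit) and `approximations` (a record of any lossy rewrites).
#' @export
raw_network <- function(neurons, synapses) {
  neurons <- as.data.frame(neurons, stringsAsFactors = FALSE)
  synapses <- as.data.frame(synapses, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "type", "threshold") %in% names(neurons)))
  if (nrow(synapses) == 0L) {
    synapses <- data.frame(src = character(), dst = character(),
                           weight = numeric(), delay = numeric())
  }
  stopifnot(all(c("src", "dst", "weight", "delay") %in% names(synapses)))
  neurons$id <- as.character(neurons$id)
  synapses$src <- as.character(synapses$src)
  synapses$dst <- as.character(synapses$dst)
  if (anyDuplicated(neurons$id)) stop_param("duplicated neuron ids")
  if (!all(neurons$type %in% c("excitatory", "inhibitory", "unit"))) {
    stop_param("neuron type must be excitatory, inhibitory or unit")
  }
  if (!all(synapses$src %in% neurons$id) || !all(synapses$dst %in% neurons$id)) {
    stop_param("synapse endpoints must be declared neurons")
  }
  if (any(synapses$delay < 1 | synapses$delay != round(synapses$delay))) {
    stop_param("delays must be integers >= 1")
  }
  if (nrow(synapses)) {
    key <- paste(synapses$src, synapses$dst, synapses$delay, sep = "\r")
    if (anyDuplicated(key)) {
      agg <- stats::aggregate(weight ~ src + dst + delay, synapses, sum)
      synapses <- agg[, c("src", "dst", "weight", "delay")]
    }
    synapses <- synapses[synapses$weight != 0, , drop = FALSE]
  }
  # Dale's sign consistency for typed neurons
  for (i in seq_len(nrow(neurons))) {
    if (neurons$type[i] == "unit") next
    w <- synapses$weight[synapses$src == neurons$id[i]]
    ok <- if (neurons$type[i] == "excitatory") all(w >= 0) else all(w <= 0)
    if (!ok) {
      stop_param("neuron '", neurons$id[i], "' (", neurons$type[i],
                 ") has outgoing weights of the wrong sign")
    }
  }
  if (!"origin" %in% names(neurons)) neurons$origin <- neurons$id
  if (!"role" %in% names(neurons)) neurons$role <- "original"
  rownames(neurons) <- NULL
  rownames(synapses) <- NULL
  structure(list(neurons = neurons, synapses = synapses,
                 seeded_active = character(), approximations = list()),
            class = "raw_network")
}

#' @export
print.raw_network <- function(x, ...) {
  cat(sprintf("<raw_network> %d neurons (%d excitatory, %d inhibitory, %d unit), %d synapses\n",
              nrow(x$neurons), sum(x$neurons$type == "excitatory"),
              sum(x$neurons$type == "inhibitory"),
              sum(x$neurons$type == "unit"), nrow(x$synapses)))
  if (length(x$approximations)) {
    cat("  approximations:", length(x$approximations), "recorded\n")
  }
  invisible(x)
}

# rebuild a raw_network keeping bookkeeping attributes
rebuild_raw <- function(old, neurons, synapses, seeded = NULL, approx = NULL) {
  out <- raw_network(neurons, synapses)
  out$seeded_active <- unique(c(old$seeded_active, seeded))
  out$approximations <- c(old$approximations, approx)
  out
}

#' Simulate a raw network directly
#'
#' Reference dynamics for the unsimplified network: neuron `j` fires at
#' time `t` iff `sum over synapses (w * Y_src(t - d)) > threshold_j`.
#' States before time 0 are taken to be silent.  This simulator is what the
#' simplification pipeline must agree with, step for step.
#'
#' @param raw a [raw_network()].
#' @param init character vector of neuron ids active at time 0 (units in
#'   `seeded_active` are always started active).
#' @param steps number of updates.
#' @return binary matrix of `(steps + 1)` rows (time 0..steps) with one
#'   column per neuron, in `raw$neurons$id` order.
#' @export
simulate_raw <- function(raw, init, steps) {
  stopifnot(inherits(raw, "raw_network"))
  ids <- raw$neurons$id
  n <- length(ids)
  init <- as.character(init)
  if (!all(init %in% ids)) stop_param("unknown neuron id in `init`")
  delays <- sort(unique(raw$synapses$delay))
  wmats <- lapply(delays, function(d) {
    w <- matrix(0, n, n, dimnames = list(ids, ids))
    sel <- raw$synapses$delay == d
    if (any(sel)) {
      s <- raw$synapses[sel, , drop = FALSE]
      w[cbind(match(s$src, ids), match(s$dst, ids))] <- s$weight
    }
    w
  })
  theta <- raw$neurons$threshold
  y <- matrix(0, steps + 1L, n, dimnames = list(NULL, ids))
  y[1L, ids %in% c(init, raw$seeded_active)] <- 1
  for (t in seq_len(steps)) {
    x <- numeric(n)
    for (k in seq_along(delays)) {
      td <- t - delays[k]
      if (td >= 0) x <- x + as.vector(y[td + 1L, ] %*% wmats[[k]])
    }
    y[t + 1L, ] <- as.numeric(x > theta)
  }
  y
}

#' Type equivalence: eliminate dedicated inhibitory neurons
#'
#' Rewrites every inhibitory neuron into synapses that inhibit its targets
#' directly, so that afterwards inhibition lives on edges, not on dedicated
#' neurons, and a row of the eventual matrix may mix both signs.  Each pair
#' of an incoming synapse `i -> h` and an outgoing synapse `h -> k` becomes
#' a relay chain `i -> r -> k` whose final edge carries the (negative)
#' outgoing weight and whose total delay is the sum of the two originals;
#' the relay inherits `h`'s threshold.  The construction is exact when `h`
#' acts as a pass-through — at most one incoming synapse — because then the
#' relay reproduces `h`'s input-output behavior per source.  An inhibitory
#' neuron with several convergent inputs has a genuinely nonlinear role;
#' it is still rewritten, but recorded in `approximations` with a warning.
#'
#' @param raw a [raw_network()].
#' @return a [raw_network()] with no inhibitory-typed neurons.
#' @export
eliminate_inhibitory_neurons <- function(raw) {
  stopifnot(inherits(raw, "raw_network"))
  counter <- 0L
  repeat {
    idx <- which(raw$neurons$type == "inhibitory")
    if (!length(idx)) return(raw)
    h <- raw$neurons$id[idx[1L]]
    inc <- raw$synapses[raw$synapses$dst == h & raw$synapses$src != h, , drop = FALSE]
    out <- raw$synapses[raw$synapses$src == h & raw$synapses$dst != h, , drop = FALSE]
    self <- any(raw$synapses$src == h & raw$synapses$dst == h)
    theta_h <- raw$neurons$threshold[idx[1L]]
    approx <- NULL
    if (nrow(out) > 0L && (self || nrow(inc) > 1L)) {
      reason <- if (self) "self-loop on inhibitory neuron" else
        sprintf("%d convergent inputs: pass-through equivalence does not hold", nrow(inc))
      approx <- list(list(id = h, op = "eliminate_inhibitory", reason = reason))
      warning("inhibitory neuron '", h, "' is not a pass-through (", reason,
              "); rewrite is approximate")
    }
    neurons <- raw$neurons[raw$neurons$id != h, , drop = FALSE]
    synapses <- raw$synapses[raw$synapses$src != h & raw$synapses$dst != h, , drop = FALSE]
    if (nrow(inc) == 0L && nrow(out) > 0L && theta_h < 0) {
      # fires spontaneously forever: keep it as an untyped unit instead
      neurons <- raw$neurons
      neurons$type[neurons$id == h] <- "unit"
      synapses <- raw$synapses
    } else if (nrow(inc) > 0L) {
      for (i in seq_len(nrow(inc))) {
        for (k in seq_len(nrow(out))) {
          counter <- counter + 1L
          rid <- sprintf("%s~r%d", h, counter)
          neurons <- rbind(neurons,
                           data.frame(id = rid, type = "unit",
                                      threshold = theta_h, origin = NA_character_,
                                      role = "relay"))
          synapses <- rbind(synapses,
                            data.frame(src = inc$src[i], dst = rid,
                                       weight = inc$weight[i], delay = inc$delay[i]),
                            data.frame(src = rid, dst = out$dst[k],
                                       weight = out$weight[k], delay = out$delay[k]))
        }
      }
    }
    raw <- rebuild_raw(raw, neurons, synapses, approx = approx)
  }
}

#' Threshold equivalence: unitize every activation threshold to zero
#'
#' Adds one always-on bias unit (a unit with a +1 self-loop, started
#' active) and, for every neuron with threshold `c != 0`, a bias synapse of
#' weight `-c`, after which the neuron's threshold is set to zero:
#' `X > c` is exactly `X - c > 0`.  Non-integer thresholds are first
#' replaced by their floor — for integer-valued accumulations `X > c` and
#' `X > floor(c)` are the same event, so this is exact for integer-weight
#' networks; it is recorded in `approximations` since it can differ for
#' fractional weights.
#'
#' @param raw a [raw_network()].
#' @return a [raw_network()] in which every threshold is zero.
#' @export
normalize_thresholds <- function(raw) {
  stopifnot(inherits(raw, "raw_network"))
  neurons <- raw$neurons
  synapses <- raw$synapses
  approx <- NULL
  frac <- neurons$threshold != floor(neurons$threshold)
  if (any(frac)) {
    approx <- lapply(neurons$id[frac], function(id) {
      list(id = id, op = "normalize_thresholds",
           reason = "non-integer threshold floored (exact only for integer weights)")
    })
    neurons$threshold <- floor(neurons$threshold)
  }
  nz <- which(neurons$threshold != 0)
  seeded <- NULL
  if (length(nz)) {
    bias <- "bias"
    while (bias %in% neurons$id) bias <- paste0(bias, "_")
    neurons <- rbind(neurons,
                     data.frame(id = bias, type = "unit", threshold = 0,
                                origin = bias, role = "bias"))
    synapses <- rbind(synapses,
                      data.frame(src = bias, dst = bias, weight = 1, delay = 1))
    for (i in nz) {
      synapses <- rbind(synapses,
                        data.frame(src = bias, dst = neurons$id[i],
                                   weight = -neurons$threshold[i], delay = 1))
    }
    neurons$threshold[nz] <- 0
    seeded <- bias
  }
  rebuild_raw(raw, neurons, synapses, seeded = seeded, approx = approx)
}

#' Weight discretization: unitize synapse weights to -1, 0 or 1
#'
#' Non-integer weights are mapped to `sign(w)` when `|w| > zero_band` and
#' dropped otherwise (lossy; recorded in `approximations`).  A synapse of
#' integer magnitude `m > 1` is expanded into `m` parallel unit synapses.
#' Because parallel edges between the same pair collapse in a matrix, the
#' extra edges are carried by duplicate source units: the source neuron is
#' replicated (same inputs, same threshold), all replicas fire in lockstep
#' with the original, and each contributes one unit synapse at the original
#' delay — an exact, delay-preserving realization of "m parallel unit
#' edges".
#'
#' @param raw a [raw_network()].
#' @param zero_band non-negative real; non-integer weights with magnitude
#'   at or below this band are removed.
#' @return a [raw_network()] in which every weight is -1 or +1.
#' @export
discretize_weights <- function(raw, zero_band = 0.5) {
  stopifnot(inherits(raw, "raw_network"))
  neurons <- raw$neurons
  synapses <- raw$synapses
  approx <- NULL
  frac <- synapses$weight != round(synapses$weight)
  if (any(frac)) {
    approx <- list(list(id = NA_character_, op = "discretize_weights",
                        reason = sprintf("%d non-integer weights mapped to sign/zero (zero_band = %g)",
                                         sum(frac), zero_band)))
    w <- synapses$weight[frac]
    synapses$weight[frac] <- ifelse(abs(w) > zero_band, sign(w), 0)
  }
  synapses$weight <- round(synapses$weight)
  synapses <- synapses[synapses$weight != 0, , drop = FALSE]
  if (nrow(synapses) == 0L || all(abs(synapses$weight) <= 1)) {
    return(rebuild_raw(raw, neurons, synapses, approx = approx))
  }
  # replica count per source: enough copies to carry its largest magnitude
  reps <- vapply(neurons$id, function(id) {
    w <- abs(synapses$weight[synapses$src == id])
    max(1, w)
  }, numeric(1))
  copy_id <- function(id, q) if (q == 1L) id else sprintf("%s#%d", id, q)
  new_neurons <- neurons
  for (i in seq_len(nrow(neurons))) {
    if (reps[i] > 1) {
      for (q in 2:reps[i]) {
        new_neurons <- rbind(new_neurons,
                             data.frame(id = copy_id(neurons$id[i], q),
                                        type = neurons$type[i],
                                        threshold = neurons$threshold[i],
                                        origin = neurons$origin[i],
                                        role = "clone"))
      }
    }
  }
  rows <- vector("list", nrow(synapses))
  for (e in seq_len(nrow(synapses))) {
    u <- synapses$src[e]; v <- synapses$dst[e]
    m <- abs(synapses$weight[e]); s <- sign(synapses$weight[e])
    d <- synapses$delay[e]
    rv <- reps[match(v, neurons$id)]
    rows[[e]] <- expand.grid(q = seq_len(m), p = seq_len(rv))
    rows[[e]] <- data.frame(src = vapply(rows[[e]]$q, copy_id, "", id = u),
                            dst = vapply(rows[[e]]$p, copy_id, "", id = v),
                            weight = s, delay = d)
  }
  new_synapses <- do.call(rbind, rows)
  seeded <- unlist(lapply(raw$seeded_active, function(id) {
    i <- match(id, neurons$id)
    vapply(seq_len(reps[i]), copy_id, "", id = id)
  }))
  rebuild_raw(raw, new_neurons, new_synapses, seeded = seeded, approx = approx)
}

#' Delay unitization and matrix emission
#'
#' Requires an inhibitory-free, zero-threshold, unit-weight network.  Every
#' synapse of delay `d > 1` is replaced by a chain of `d - 1` relay units
#' joined by unit excitatory delay-1 links, the final hop carrying the
#' synapse's sign; a spike then takes exactly `d` steps from source to
#' target, as before.  The result is the square \{-1, 0, 1\} matrix
#' together with an index map from unit ids (including their role:
#' original, bias, clone or relay) to matrix rows.
#'
#' @param raw a [raw_network()] (inhibitory-free, zero thresholds, unit
#'   weights — i.e. the output of the three preceding stages).
#' @return an object of class `simplified_network`: list with `matrix`
#'   (a [connection_matrix()]), `map` (data frame `id`, `index`, `role`,
#'   `origin`, `seeded`), `approximations`.
#' @export
unitize_delays <- function(raw) {
  stopifnot(inherits(raw, "raw_network"))
  if (any(raw$neurons$type == "inhibitory")) {
    stop_param("network still contains inhibitory neurons; run eliminate_inhibitory_neurons() first")
  }
  if (any(raw$neurons$threshold != 0)) {
    stop_param("network still has nonzero thresholds; run normalize_thresholds() first")
  }
  if (nrow(raw$synapses) && any(abs(raw$synapses$weight) != 1)) {
    stop_param("network still has non-unit weights; run discretize_weights() first")
  }
  neurons <- raw$neurons
  synapses <- raw$synapses
  rows <- list()
  keep <- rep(TRUE, nrow(synapses))
  for (e in seq_len(nrow(synapses))) {
    d <- synapses$delay[e]
    if (d == 1) next
    keep[e] <- FALSE
    chain <- sprintf("%s>%s@%d.%d", synapses$src[e], synapses$dst[e], e,
                     seq_len(d - 1))
    neurons <- rbind(neurons,
                     data.frame(id = chain, type = "unit", threshold = 0,
                                origin = NA_character_, role = "relay"))
    path <- c(synapses$src[e], chain, synapses$dst[e])
    w <- c(rep(1, d - 1), synapses$weight[e])
    rows[[length(rows) + 1L]] <-
      data.frame(src = path[-length(path)], dst = path[-1L], weight = w, delay = 1)
  }
  synapses <- rbind(synapses[keep, , drop = FALSE], do.call(rbind, rows))
  ids <- neurons$id
  n <- length(ids)
  mat <- matrix(0, n, n)
  ij <- cbind(match(synapses$src, ids), match(synapses$dst, ids))
  if (anyDuplicated(ij)) stop_param("internal error: colliding unit synapses")
  mat[ij] <- synapses$weight
  map <- data.frame(id = ids, index = seq_len(n), role = neurons$role,
                    origin = neurons$origin,
                    seeded = ids %in% raw$seeded_active)
  structure(list(matrix = connection_matrix(mat, meta = list(n = n,
                   source = "simplified raw network")),
                 map = map, approximations = raw$approximations),
            class = "simplified_network")
}

#' @export
print.simplified_network <- function(x, ...) {
  cat(sprintf("<simplified_network> %d units (%d original, %d bias, %d clone, %d relay)\n",
              nrow(x$map), sum(x$map$role == "original"),
              sum(x$map$role == "bias"), sum(x$map$role == "clone"),
              sum(x$map$role == "relay")))
  if (length(x$approximations)) {
    cat("  approximate rewrites:", length(x$approximations), "\n")
  }
  invisible(x)
}

#' Full simplification pipeline
#'
#' Applies, in order: inhibitory-neuron elimination (type equivalence),
#' threshold normalization (threshold equivalence), weight discretization
#' and delay unitization, emitting the behavior-equivalent unit matrix.
#' For integer weights and thresholds (and pass-through inhibitory
#' neurons) the projection of the simplified matrix's trajectory onto the
#' original neurons equals the raw network's trajectory step for step;
#' see [simulate_simplified()].
#'
#' @inheritParams discretize_weights
#' @return a `simplified_network` (see [unitize_delays()]).
#' @export
simplify_network <- function(raw, zero_band = 0.5) {
  raw |>
    eliminate_inhibitory_neurons() |>
    normalize_thresholds() |>
    discretize_weights(zero_band = zero_band) |>
    unitize_delays()
}

#' Simulate a simplified network and project onto the original neurons
#'
#' Builds the initial unit-matrix state implied by a raw initial condition
#' (original neurons and their clones take the given values, bias units
#' start active, delay relays start silent), runs [simulate_assembly()],
#' and returns the columns of the original neurons.
#'
#' @param sn a [simplify_network()] result.
#' @param init character vector of original neuron ids active at time 0.
#' @param steps number of updates.
#' @return binary matrix of `(steps + 1)` rows, one column per original
#'   neuron (in map order).
#' @export
simulate_simplified <- function(sn, init, steps) {
  stopifnot(inherits(sn, "simplified_network"))
  init <- as.character(init)
  state <- as.numeric(!is.na(sn$map$origin) & sn$map$origin %in% init)
  state[sn$map$seeded] <- 1
  # clones of seeded units must start with their source's value
  seeded_origins <- sn$map$origin[sn$map$seeded]
  state[!is.na(sn$map$origin) & sn$map$origin %in% seeded_origins] <- 1
  raster <- simulate_assembly(sn$matrix, steps = steps, init = state)
  orig <- sn$map$index[sn$map$role == "original"]
  out <- raster$spikes[, orig, drop = FALSE]
  colnames(out) <- sn$map$id[sn$map$role == "original"]
  out
}

#' Random raw network generator
#'
#' Draws a small Dale-compliant raw network for testing the simplification
#' pipeline: excitatory neurons with integer weights, delays and
#' thresholds, plus feed-forward inhibitory interneurons.  Each inhibitory
#' neuron is a pass-through (a single excitatory input and threshold 0) so
#' the type-equivalence rewrite is exact by construction.
#'
#' @param n_exc number of excitatory neurons (>= 1).
#' @param n_inh number of inhibitory interneurons.
#' @param p_edge probability of each excitatory-to-excitatory synapse.
#' @param max_weight largest weight magnitude (integer).
#' @param max_delay largest delay.
#' @param max_threshold largest threshold.
#' @param seed integer seed.
#' @return a [raw_network()].
#' @export
random_raw_network <- function(n_exc, n_inh = 0L, p_edge = 0.3, max_weight = 3L,
                               max_delay = 3L, max_threshold = 2L, seed = NULL) {
  stopifnot(n_exc >= 1)
  with_seed(seed, {
    eids <- sprintf("e%d", seq_len(n_exc))
    iids <- if (n_inh > 0) sprintf("i%d", seq_len(n_inh)) else character()
    neurons <- data.frame(id = c(eids, iids),
                          type = c(rep("excitatory", n_exc),
                                   rep("inhibitory", n_inh)),
                          threshold = c(sample(0:max_threshold, n_exc, replace = TRUE),
                                        rep(0, n_inh)))
    syn <- list()
    for (u in eids) for (v in eids) {
      if (u != v && stats::runif(1) < p_edge) {
        syn[[length(syn) + 1L]] <- data.frame(
          src = u, dst = v, weight = sample(seq_len(max_weight), 1),
          delay = sample(seq_len(max_delay), 1))
      }
    }
    for (h in iids) {
      src <- sample(eids, 1)
      syn[[length(syn) + 1L]] <- data.frame(
        src = src, dst = h, weight = sample(seq_len(max_weight), 1),
        delay = sample(seq_len(max_delay), 1))
      targets <- eids[stats::runif(n_exc) < 0.5]
      for (v in targets) {
        syn[[length(syn) + 1L]] <- data.frame(
          src = h, dst = v, weight = -sample(seq_len(max_weight), 1),
          delay = sample(seq_len(max_delay), 1))
      }
    }
    syn <- if (length(syn)) do.call(rbind, syn) else
      data.frame(src = character(), dst = character(),
                 weight = numeric(), delay = numeric())
    raw_network(neurons, syn)
  })
}

#' Read or write a raw network as TSV tables
#'
#' A raw network is exchanged as two tab-separated tables: a neuron table
#' (`id`, `type`, `threshold`) and an edge list (`src`, `dst`, `weight`,
#' `delay`).
#'
#' @param raw a [raw_network()].
#' @param neurons_path,synapses_path file paths for the two tables.
#' @return `read_raw_network()` returns a [raw_network()];
#'   `write_raw_network()` returns invisibly.
#' @export
read_raw_network <- function(neurons_path, synapses_path) {
  neurons <- utils::read.table(neurons_path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  synapses <- utils::read.table(synapses_path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  raw_network(neurons[, c("id", "type", "threshold")], synapses)
}

#' @rdname read_raw_network
#' @export
write_raw_network <- function(raw, neurons_path, synapses_path) {
  stopifnot(inherits(raw, "raw_network"))
  utils::write.table(raw$neurons[, c("id", "type", "threshold")], neurons_path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(raw$synapses, synapses_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
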