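# Independent brute-force oracles, written as plain per-neuron loops so they
# share no code path with the package's vectorized implementation.

naive_step <- function(state, m, external = NULL) {
  n <- length(state)
  out <- numeric(n)
  for (j in seq_len(n)) {
    x <- 0
    for (i in seq_len(n)) x <- x + state[i] * m[i, j]
    if (!is.null(external)) x <- x + external[j]
    out[j] <- if (x > 0) 1 else 0
  }
  out
}

naive_trajectory <- function(m, init, steps) {
  traj <- matrix(0, steps + 1, length(init))
  traj[1, ] <- init
  for (t in seq_len(steps)) traj[t + 1, ] <- naive_step(traj[t, ], m)
  traj
}

# first revisit by linear search over the explicit state sequence
naive_cycle <- function(m, init, max_steps) {
  states <- list(init)
  state <- init
  for (t in seq_len(max_steps)) {
    state <- naive_step(state, m)
    for (s in seq_along(states)) {
      if (all(states[[s]] == state)) {
        return(list(found = TRUE, transient = s - 1L, period = t - (s - 1L)))
      }
    }
    states[[t + 1L]] <- state
  }
  list(found = FALSE)
}

# spike probabilities by direct counting over one attractor period
naive_probabilities <- function(m, init, max_steps) {
  cyc <- naive_cycle(m, init, max_steps)
  if (!cyc$found) return(NULL)
  traj <- naive_trajectory(m, init, cyc$transient + 2L * cyc$period)
  rows <- (cyc$transient + 1):(cyc$transient + cyc$period) + 1L
  colSums(traj[rows, , drop = FALSE]) / cyc$period
}

# coupled-train output by stepwise enumeration (no lcm shortcut)
naive_couple_probability <- function(pat_a, pat_b, offset, threshold) {
  horizon <- length(pat_a) * length(pat_b) * 4L
  fired <- 0L
  for (t in 0:(horizon - 1L)) {
    a <- pat_a[(t %% length(pat_a)) + 1L]
    b <- pat_b[((t + offset) %% length(pat_b)) + 1L]
    if (a + b > threshold) fired <- fired + 1L
  }
  fired / horizon
}

# exact binomial tail P(successes > n/2), the event "summed input positive"
exact_binomial_tail <- function(n, e1) {
  k <- 0:n
  sum(stats::dbinom(k[k > n / 2], n, e1))
}

random_binary_state <- function(n, p = 0.5) as.numeric(stats::runif(n) < p)
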