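test_that("networks without inhibitory neurons pass through unchanged", {
  raw <- raw_network(
    data.frame(id = c("a", "b"), type = "excitatory", threshold = 0),
    data.frame(src = "a", dst = "b", weight = 1, delay = 1))
  out <- eliminate_inhibitory_neurons(raw)
  expect_identical(out$neurons$id, raw$neurons$id)
  expect_identical(out$synapses, raw$synapses)
})

test_that("a pass-through inhibitory neuron becomes an equivalent relay chain", {
  raw <- raw_network(
    data.frame(id = c("e1", "inh", "e2"),
               type = c("excitatory", "inhibitory", "excitatory"),
               threshold = 0),
    data.frame(src = c("e1", "inh", "e2"),
               dst = c("inh", "e2", "e1"),
               weight = c(1, -1, 1), delay = c(1, 1, 1)))
  out <- eliminate_inhibitory_neurons(raw)
  expect_false(any(out$neurons$type == "inhibitory"))
  relay <- out$neurons$id[out$neurons$role == "relay"]
  expect_length(relay, 1L)
  # terminal edge negative, total path delay preserved (1 + 1)
  e_in <- out$synapses[out$synapses$dst == relay, ]
  e_out <- out$synapses[out$synapses$src == relay, ]
  expect_equal(e_out$weight, -1)
  expect_equal(e_in$delay + e_out$delay, 2)
  # trajectories of the surviving original neurons are unchanged
  y_raw <- simulate_raw(raw, "e1", 12)[, c("e1", "e2")]
  y_out <- simulate_raw(out, "e1", 12)[, c("e1", "e2")]
  expect_equal(y_out, y_raw)
})

test_that("convergent inputs on one inhibitory neuron warn and fan out", {
  raw <- raw_network(
    data.frame(id = c("x", "y", "h", "t"),
               type = c("excitatory", "excitatory", "inhibitory", "excitatory"),
               threshold = 0),
    data.frame(src = c("x", "y", "h"), dst = c("h", "h", "t"),
               weight = c(1, 1, -1), delay = 1))
  expect_warning(out <- eliminate_inhibitory_neurons(raw), "pass-through")
  # one relay chain per (input, target) pair
  expect_equal(sum(out$neurons$role == "relay"), 2L)
  expect_equal(length(out$approximations), 1L)
})

test_that("threshold normalization is behavior-preserving via the bias unit", {
  # all-zero thresholds: nothing to do, no bias unit
  raw0 <- raw_network(
    data.frame(id = "a", type = "excitatory", threshold = 0),
    data.frame(src = character(), dst = character(),
               weight = numeric(), delay = numeric()))
  expect_false(any(normalize_thresholds(raw0)$neurons$role == "bias"))

  # threshold 1 with two unit excitatory inputs: an AND gate before and after
  raw <- raw_network(
    data.frame(id = c("u", "v", "w"), type = "excitatory",
               threshold = c(0, 0, 1)),
    data.frame(src = c("u", "v"), dst = "w", weight = 1, delay = 1))
  norm <- normalize_thresholds(raw)
  expect_true(all(norm$neurons$threshold == 0))
  for (active in list(character(), "u", "v", c("u", "v"))) {
    y_raw <- simulate_raw(raw, active, 3)
    y_norm <- simulate_raw(norm, active, 3)
    expect_equal(y_norm[, c("u", "v", "w")], y_raw[, c("u", "v", "w")])
    expect_equal(unname(y_raw[2, "w"]), as.numeric(length(active) == 2))
  }

  # negative threshold: spontaneous firing every step absent inhibition
  spont <- raw_network(
    data.frame(id = "s", type = "excitatory", threshold = -1),
    data.frame(src = character(), dst = character(),
               weight = numeric(), delay = numeric()))
  ns <- normalize_thresholds(spont)
  expect_equal(ns$synapses$weight[ns$synapses$dst == "s"], 1)
  y <- simulate_raw(ns, character(), 5)
  expect_true(all(y[-1, "s"] == 1))
})

test_that("weight discretization expands magnitudes and bands out noise", {
  unitw <- raw_network(
    data.frame(id = c("a", "b"), type = "excitatory", threshold = 0),
    data.frame(src = "a", dst = "b", weight = 1, delay = 1))
  expect_identical(discretize_weights(unitw)$synapses, unitw$synapses)

  # weight 2 onto a requirement of more-than-one: still satisfied by the
  # single doubled source after expansion into two unit edges
  raw <- raw_network(
    data.frame(id = c("a", "b"), type = "excitatory", threshold = c(0, 1)),
    data.frame(src = "a", dst = "b", weight = 2, delay = 1))
  pipe <- discretize_weights(normalize_thresholds(raw))
  expect_true(all(abs(pipe$synapses$weight) == 1))
  for (active in list(character(), "a")) {
    y_raw <- simulate_raw(raw, active, 3)
    # source replicas start with their source's value, like the bias unit
    init <- pipe$neurons$id[pipe$neurons$origin %in% active]
    y_new <- simulate_raw(pipe, init, 3)
    expect_equal(y_new[, c("a", "b")], y_raw[, c("a", "b")])
  }

  # sub-band fractional weight is dropped, flagged
  frac <- raw_network(
    data.frame(id = c("a", "b"), type = "excitatory", threshold = 0),
    data.frame(src = "a", dst = "b", weight = 0.3, delay = 1))
  out <- discretize_weights(frac, zero_band = 0.5)
  expect_equal(nrow(out$synapses), 0L)
  expect_length(out$approximations, 1L)
})

test_that("delay unitization inserts exactly delay-minus-one relays", {
  raw <- raw_network(
    data.frame(id = c("a", "b"), type = "excitatory", threshold = 0),
    data.frame(src = "a", dst = "b", weight = 1, delay = 3))
  sn <- unitize_delays(raw)
  expect_equal(sum(sn$map$role == "relay"), 2L)
  d1 <- raw_network(
    data.frame(id = c("a", "b"), type = "excitatory", threshold = 0),
    data.frame(src = "a", dst = "b", weight = 1, delay = 1))
  sn1 <- unitize_delays(d1)
  expect_equal(nrow(sn1$matrix), 2L)
  expect_equal(sum(sn1$map$role == "relay"), 0L)
  # preconditions are enforced
  inh <- raw_network(data.frame(id = "h", type = "inhibitory", threshold = 0),
                     data.frame(src = character(), dst = character(),
                                weight = numeric(), delay = numeric()))
  expect_error(unitize_delays(inh), "inhibitory")
})

test_that("the full pipeline emits a valid unit matrix deterministically", {
  raw <- random_raw_network(6, n_inh = 2, seed = 77)
  sn1 <- simplify_network(raw)
  sn2 <- simplify_network(raw)
  expect_identical(unclass(sn1$matrix), unclass(sn2$matrix))
  expect_true(all(unclass(sn1$matrix) %in% c(-1, 0, 1)))
  surviving <- raw$neurons$id[raw$neurons$type != "inhibitory"]
  expect_true(all(surviving %in% sn1$map$id[sn1$map$role == "original"]))
})

test_that("simplified dynamics equal raw dynamics step for step", {
  for (k in 1:12) {
    n_exc <- 3 + (k %% 6)
    raw <- random_raw_network(n_exc, n_inh = k %% 3, seed = 800 + k)
    sn <- simplify_network(raw)
    # inhibitory neurons are rewritten away; the surviving originals must
    # evolve identically
    orig <- intersect(raw$neurons$id, sn$map$id[sn$map$role == "original"])
    init <- orig[1]
    y_raw <- simulate_raw(raw, init, 25)[, orig, drop = FALSE]
    y_simp <- simulate_simplified(sn, init, 25)[, orig, drop = FALSE]
    expect_equal(y_simp, y_raw)
  }
})

test_that("raw networks round-trip through their TSV tables", {
  raw <- random_raw_network(5, n_inh = 1, seed = 9)
  np <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_raw_network(raw, np, sp)
  back <- read_raw_network(np, sp)
  expect_equal(back$neurons[, c("id", "type", "threshold")],
               raw$neurons[, c("id", "type", "threshold")])
  expect_equal(back$synapses[order(back$synapses$src, back$synapses$dst, back$synapses$delay), ],
               raw$synapses[order(raw$synapses$src, raw$synapses$dst, raw$synapses$delay), ],
               ignore_attr = TRUE)
})

test_that("Dale sign consistency is enforced on typed neurons", {
  expect_error(raw_network(
    data.frame(id = c("a", "b"), type = c("excitatory", "excitatory"),
               threshold = 0),
    data.frame(src = "a", dst = "b", weight = -1, delay = 1)),
    "wrong sign")
  expect_error(raw_network(
    data.frame(id = "a", type = "excitatory", threshold = 0),
    data.frame(src = "a", dst = "a", weight = 1, delay = 0.5)),
    "delays")
})
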