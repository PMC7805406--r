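test_that("spike trains index their periodic pattern by phase", {
  tr <- spike_train(c(1, 0, 0, 0))
  expect_equal(tr$probability, 0.25)
  expect_equal(train_at(tr, 0:7), rep(c(1, 0, 0, 0), 2))
  sh <- spike_train(c(1, 0, 0, 0), phase = 1)
  expect_equal(train_at(sh, 0:3), c(0, 0, 0, 1))
  expect_error(spike_train(c(1, 2)), "0/1")
})

test_that("coupling the .25 and .5 trains reproduces the hand enumerations", {
  a <- spike_train(c(1, 0, 0, 0))
  b <- spike_train(c(1, 0))
  both <- couple_trains(a, b, offset = 0, threshold = 1)
  expect_equal(both$period, 4L)
  expect_equal(both$probability, 0.25)   # both required: intersection
  none <- couple_trains(a, b, offset = 1, threshold = 1)
  expect_equal(none$probability, 0)      # disjoint phases
  either <- couple_trains(a, b, offset = 0, threshold = 0)
  expect_equal(either$probability, 0.5)  # union of the phase sets
  # one-step transmission lag: output at t+1 reflects inputs at t
  expect_equal(train_at(both, 1), 1)
  expect_equal(train_at(both, 0), 0)
})

test_that("coupled output equals exhaustive enumeration for all small periods", {
  set.seed(42)
  for (ta in 2:12) {
    for (tb in c(2, 3, 5, 8, 12)) {
      pa <- as.integer(runif(ta) < 0.4)
      pb <- as.integer(runif(tb) < 0.5)
      if (!any(pa)) pa[1] <- 1L
      if (!any(pb)) pb[1] <- 1L
      for (offset in 0:(tb - 1)) {
        for (threshold in 0:2) {
          got <- couple_trains(spike_train(pa), spike_train(pb),
                               offset = offset, threshold = threshold)
          expect_equal(got$probability,
                       naive_couple_probability(pa, pb, offset, threshold))
        }
      }
    }
  }
})

test_that("the memory framework wires 2 input, 4 coupling, 1 output units", {
  g <- build_memory_framework(unit_size = 20, seed = 1)
  expect_length(g$units, 7L)
  expect_equal(lengths(g$units)[1:6], setNames(rep(20L, 6),
               c("in1", "in2", "c1", "c2", "c3", "c4")))
  expect_length(g$units$out, 1L)
  g2 <- build_memory_framework(unit_size = 20, seed = 1)
  expect_identical(unclass(g$matrix), unclass(g2$matrix))
  mat <- unclass(g$matrix)
  # only forward links: coupling blocks mutually zero, nothing re-enters inputs
  expect_true(all(mat[g$units$c1, g$units$c2] == 0))
  expect_true(all(mat[g$units$c3, g$units$in1] == 0))
  expect_true(all(mat[g$units$out, ] == 0))
})

test_that("without inter-unit links the coupling units ignore the inputs", {
  g <- build_memory_framework(unit_size = 15, seed = 3)
  cut <- unclass(g$matrix)
  for (iu in c("in1", "in2")) {
    for (cu in c("c1", "c2", "c3", "c4")) {
      cut[g$units[[iu]], g$units[[cu]]] <- 0
    }
  }
  g_cut <- g
  g_cut$matrix <- connection_matrix(cut)
  modes <- default_input_modes()
  ga <- present_and_remove(g_cut, modes$mode1, present_steps = 40)
  gb <- present_and_remove(g_cut, modes$mode2, present_steps = 40)
  cidx <- unlist(g$units[c("c1", "c2", "c3", "c4")])
  expect_identical(ga$state[cidx], gb$state[cidx])
})

test_that("presentation imprints a mode-dependent state; zero steps change nothing", {
  g <- build_memory_framework(unit_size = 20, seed = 5)
  expect_identical(present_and_remove(g, default_input_modes()$mode1, 0), g)
  modes <- default_input_modes()
  diffs <- vapply(1:5, function(s) {
    gs <- build_memory_framework(unit_size = 20, seed = 10 + s)
    g1 <- present_and_remove(gs, modes$mode1, 60)
    g2 <- present_and_remove(gs, modes$mode2, 60)
    cidx <- unlist(gs$units[c("c1", "c2", "c3", "c4")])
    sum(g1$state[cidx] != g2$state[cidx])
  }, numeric(1))
  expect_true(any(diffs > 0))
  # re-presentation of a new mode overwrites the stored phase
  g1 <- present_and_remove(g, modes$mode1, 60)
  g12 <- present_and_remove(g1, modes$mode2, 60)
  expect_false(identical(g1$state, g12$state))
})

test_that("recall probability collapses above the output in-degree", {
  g <- build_memory_framework(unit_size = 20, link_count = 5, seed = 7)
  g <- present_and_remove(g, default_input_modes()$mode1, 60)
  indeg <- sum(unclass(g$matrix)[, g$units$out] != 0)
  rep <- recall(g, schedule = c(0L, indeg + 1L), steps_per_level = 100)
  expect_equal(rep$p_out[2], 0)
  expect_gt(rep$p_out[1], 0)
  expect_error(recall(g, schedule = c(5L, 0L)), "non-decreasing")
})

test_that("distinguishability measures profile distances with closed forms", {
  r0 <- structure(list(mode_id = "a", schedule = 0:4, p_out = rep(0, 5)),
                  class = "recall_report")
  r1 <- structure(list(mode_id = "b", schedule = 0:4, p_out = rep(1, 5)),
                  class = "recall_report")
  d <- distinguishability(list(r0, r1, r0))
  expect_equal(d$distances["a", "b"], sqrt(5))
  expect_equal(d$distances[1, 3], 0)
  expect_false(d$separable)
  bad <- structure(list(mode_id = "c", schedule = 0:3, p_out = rep(0, 4)),
                   class = "recall_report")
  expect_error(distinguishability(list(r0, bad)), "mismatched")
  expect_error(distinguishability(list(r0)), "at least 2")
})
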