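cfg <- network_config()

test_that("Hebbian deltas obey the gate, the ceiling and the floor", {
  n <- 6
  exc <- matrix(0.2, n, n); diag(exc) <- 0
  inh <- matrix(0.1, n, n); diag(inh) <- 0
  y <- c(0.9, 0.4, 0.6, 0, 1, 0.5)
  d <- hebbian_deltas(y, exc, inh, cfg, Lmax = 0.4)
  gate <- pmax(y - 0.5, 0)
  # direct evaluation of the rule for an arbitrary pair (post 1, pre 2)
  expect_equal(d$exc[1, 2], 0.03 * (0.4 - 0.2) * y[2] * gate[1])
  expect_equal(d$inh[1, 2], -0.05 * 0.1 * y[2] * gate[1])
  # sub-threshold postsynaptic neurons receive no change at all
  expect_true(all(d$exc[y <= 0.5, ] == 0))
  expect_true(all(d$inh[y <= 0.5, ] == 0))
  # excitatory synapses at the ceiling stop growing
  exc2 <- exc; exc2[1, 2] <- 0.4
  d2 <- hebbian_deltas(y, exc2, inh, cfg, Lmax = 0.4)
  expect_equal(d2$exc[1, 2], 0)
  # inhibitory synapses at zero cannot become negative
  inh2 <- inh; inh2[1, 2] <- 0
  d3 <- hebbian_deltas(y, exc, inh2, cfg, Lmax = 0.4)
  expect_equal(d3$inh[1, 2], 0)
  # self entries are never modified
  expect_true(all(diag(d$exc) == 0) && all(diag(d$inh) == 0))
})

test_that("reciprocal synapses between unequally active neurons change asymmetrically", {
  # two co-active neurons, both above the gate but with different activities
  y <- c(0.9, 0.6)
  exc <- matrix(c(0, 0.2, 0.2, 0), 2, 2)
  inh <- matrix(c(0, 0.1, 0.1, 0), 2, 2)
  d <- hebbian_deltas(y, exc, inh, cfg, Lmax = 0.4)
  # synapse onto the more active neuron grows more than its reciprocal
  expect_gt(d$exc[1, 2], d$exc[2, 1])
  expect_lt(d$inh[1, 2], d$inh[2, 1]) # both negative; stronger depression
  expect_gt(d$exc[1, 2] / d$exc[2, 1],
            1 + 1e-6) # strict asymmetry, not a tie
})

test_that("normalization restores basal incoming sums and flags degeneracy", {
  set.seed(5)
  W <- matrix(runif(25), 5, 5); diag(W) <- 0
  target <- rowSums(W)
  W2 <- W * matrix(runif(25, 0.5, 2), 5, 5)
  diag(W2) <- 0
  W3 <- normalize_incoming(W2, target)
  expect_equal(rowSums(W3), target, tolerance = 1e-12)
  # proportions within a row are preserved (multiplicative rescale)
  expect_equal(W3[1, 2] / W3[1, 3], W2[1, 2] / W2[1, 3])
  # unchanged rows are returned with rescale factor 1
  expect_identical(normalize_incoming(W, target), W)
  expect_error(normalize_incoming(matrix(0, 2, 2), c(1, 1)), "degenerate")
})

test_that("potentiating one incoming synapse depresses the other incoming ones", {
  cfg_t <- tiny_cfg()
  syn <- basal_synapses(cfg_t, "dense")
  np <- cfg_t$n_azimuth_auditory
  # activity: pre neuron (10, 5) strongly active, post (12, 5) above gate
  y <- matrix(0, np, cfg_t$n_freq_auditory)
  y[11, 6] <- 1
  y[13, 6] <- 0.8
  st <- ventnet:::new_state(cfg_t)
  st$y_a <- y
  syn2 <- ventnet:::apply_plasticity(syn, st, cfg_t, layers = "auditory")
  p <- 12 + 1 + 5 * np
  h <- 10 + 1 + 5 * np
  grew <- syn2$auditory$exc[p, ] > syn$auditory$exc[p, ]
  expect_true(grew[h])
  # every other incoming excitatory synapse with positive weight shrank
  others <- setdiff(which(syn$auditory$exc[p, ] > 0), h)
  expect_true(all(syn2$auditory$exc[p, others] < syn$auditory$exc[p, others]))
  # and the incoming sum is conserved
  expect_equal(sum(syn2$auditory$exc[p, ]), syn$auditory$sum_exc[p])
})

test_that("adaptation conserves incoming sums and respects weight bounds throughout", {
  cfg_t <- tiny_cfg(n_learning_steps = 60)
  syn <- basal_synapses(cfg_t, "dense")
  stim <- tiny_bimodal(intensity = 20)
  e_v <- visual_input(stim, cfg_t)
  e_a <- auditory_input(stim, cfg_t)
  st <- ventnet:::new_state(cfg_t)
  for (k in 1:60) {
    st <- network_step(st, syn, e_v, e_a, cfg_t)
    syn <- ventnet:::apply_plasticity(syn, st, cfg_t)
    # conservation at every single learning step, both components and layers
    expect_equal(rowSums(syn$auditory$exc), syn$auditory$sum_exc,
                 tolerance = 1e-8)
    expect_equal(rowSums(syn$auditory$inh), syn$auditory$sum_inh,
                 tolerance = 1e-8)
    expect_equal(rowSums(syn$visual$exc), syn$visual$sum_exc,
                 tolerance = 1e-8)
    expect_equal(rowSums(syn$visual$inh), syn$visual$sum_inh,
                 tolerance = 1e-8)
    # bounds: excitatory within [0, Lmax], inhibitory nonnegative
    expect_true(all(syn$auditory$exc >= 0 &
                      syn$auditory$exc <= cfg_t$Lmax_a + 1e-12))
    expect_true(all(syn$auditory$inh >= 0))
    expect_true(all(syn$visual$exc >= 0 &
                      syn$visual$exc <= cfg_t$Lmax_v + 1e-12))
    expect_true(all(diag(syn$auditory$exc) == 0))
  }
  # learning actually happened
  expect_gt(sum(st$y_a > cfg_t$theta_post), 0)
})

test_that("a closed gate (theta_post = 1) leaves synapses bit-identical", {
  cfg_t <- tiny_cfg(theta_post = 1, n_learning_steps = 80)
  syn <- basal_synapses(cfg_t)
  ad <- adapt_network(syn, tiny_bimodal(intensity = 25), cfg_t)
  expect_identical(ad$synapses$auditory$M_exc, syn$auditory$M_exc)
  expect_identical(ad$synapses$auditory$rows, syn$auditory$rows)
  expect_identical(ad$synapses$visual, syn$visual)
})

test_that("adaptation is deterministic", {
  cfg_t <- tiny_cfg(n_learning_steps = 80)
  syn <- basal_synapses(cfg_t)
  ad1 <- adapt_network(syn, tiny_bimodal(), cfg_t)
  ad2 <- adapt_network(syn, tiny_bimodal(), cfg_t)
  expect_identical(ad1$synapses$auditory$M_exc, ad2$synapses$auditory$M_exc)
  expect_identical(ad1$synapses$auditory$M_inh, ad2$synapses$auditory$M_inh)
  expect_identical(ad1$synapses$visual$exc, ad2$synapses$visual$exc)
  expect_identical(ad1$final_state$y_a, ad2$final_state$y_a)
})

test_that("adaptation records provenance and a learning trace", {
  cfg_t <- tiny_cfg(n_learning_steps = 50)
  ad <- adapt_network(basal_synapses(cfg_t), tiny_bimodal(), cfg_t)
  expect_true(ad$synapses$trained)
  expect_match(ad$synapses$provenance$label, "adaptation")
  expect_equal(nrow(tidy(ad)), 50)
  g <- glance(ad)
  expect_equal(g$n_steps, 50)
  expect_gte(g$max_supra_auditory, 0)
})
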