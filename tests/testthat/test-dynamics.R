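test_that("the network image follows the activator/inhibitor balance rule", {
  # isolated node holds; one perceived activator raises by one step
  chain <- toy_chain()
  p <- default_parameters(chain)
  img <- network_image(chain, p, c(2L, 0L, 1L))
  expect_equal(unname(img), c(2L, 1L, 1L))  # A no in-edges; B raised; C held

  # strong inhibitor beats weak activator; equal weights tie and hold
  net <- logic_network(
    nodes = data.frame(name = c("up", "down", "x")),
    edges = data.frame(source = c("up", "down"), target = "x",
                       mode = c("activate", "inhibit")),
    adherence_node = "x")
  p21 <- parameter_set(net, theta = 1L, weight = c(1L, 2L))
  expect_equal(network_image(net, p21, c(2L, 2L, 2L))[["x"]], 1L)
  p11 <- parameter_set(net, theta = 1L, weight = c(1L, 1L))
  expect_equal(network_image(net, p11, c(2L, 2L, 2L))[["x"]], 2L)
  # sub-threshold sources are not perceived at all
  p_theta2 <- parameter_set(net, theta = c(2L, 2L), weight = 1L)
  expect_equal(network_image(net, p_theta2, c(1L, 1L, 0L))[["x"]], 0L)
})

test_that("the image agrees with an independent plain-loop oracle", {
  set.seed(101)
  for (rep in 1:25) {
    net <- random_network(sample(2:5, 1), n_input = sample(0:2, 1),
                          n_edges = sample(2:8, 1))
    params <- random_parameters(net)
    s <- vapply(net$nodes$n_levels, function(L) sample.int(L, 1L) - 1L,
                integer(1))
    expect_equal(unname(network_image(net, params, s)),
                 oracle_image(net, params, s))
  }
})

test_that("every node moves at most one level per synchronous step", {
  set.seed(7)
  for (rep in 1:20) {
    net <- random_network(sample(2:6, 1), n_edges = sample(3:10, 1))
    params <- random_parameters(net)
    s <- vapply(net$nodes$n_levels, function(L) sample.int(L, 1L) - 1L,
                integer(1))
    s2 <- step_synchronous(net, params, s)
    expect_true(all(abs(s2 - s) <= 1L))
    expect_true(all(s2 >= 0L & s2 <= net$nodes$n_levels - 1L))
  }
})

test_that("input-node levels are conserved along whole trajectories", {
  set.seed(8)
  net <- random_network(4, n_input = 2, n_edges = 8)
  params <- random_parameters(net)
  s0 <- c(2L, 0L, 1L, 2L, 1L, 0L)
  tr <- simulate_network(net, params, s0, max_steps = 30)
  inp <- which(net$nodes$kind == "input")
  for (j in inp) expect_true(all(tr$states[, j] == s0[j]))
})

test_that("mutual inhibition at full activation relaxes symmetrically", {
  net <- mutual_inhibition()
  p <- default_parameters(net)
  expect_equal(unname(step_synchronous(net, p, c(2L, 2L))), c(1L, 1L))
})

test_that("simulation stops as soon as a state recurs", {
  net <- self_activator()
  p <- default_parameters(net)
  # fixed point: trajectory holds the state and its repeat
  tr <- simulate_network(net, p, 2L)
  expect_true(tr$converged)
  expect_equal(nrow(tr$states), 2L)
  expect_equal(tr$attractor$period, 1L)
  # from the intermediate level the self-activator climbs then sticks: 1,2,2
  tr2 <- simulate_network(net, p, 1L)
  expect_equal(unname(tr2$states[, 1]), c(1L, 2L, 2L))
  expect_equal(unname(tr2$attractor$states[1, 1]), 2L)
  # default horizon is the 50-iteration one
  expect_equal(eval(formals(simulate_network)$max_steps), 50L)
})

test_that("exact enumeration finds fixed points, transients and full basins", {
  net <- self_activator()
  p <- default_parameters(net)
  att <- enumerate_attractors(net, p)
  expect_length(att, 2L)
  expect_equal(sort(vapply(att, function(a) a$states[1, 1], integer(1))),
               c(0L, 2L))
  # level 1 is transient and drains into the fixed point at 2
  freqs <- vapply(att, `[[`, numeric(1), "basin_frequency")
  expect_equal(sort(freqs), c(1 / 3, 2 / 3))
  expect_equal(sum(freqs), 1)

  # with no edges every state is a fixed point
  iso <- logic_network(data.frame(name = c("A", "B")),
                       data.frame(source = character(),
                                  target = character(),
                                  mode = character()), "A")
  att_iso <- enumerate_attractors(iso, default_parameters(iso))
  expect_length(att_iso, 9L)
  expect_true(all(vapply(att_iso, `[[`, integer(1), "period") == 1L))
  expect_equal(sum(vapply(att_iso, `[[`, numeric(1), "basin_frequency")), 1)

  # the cap refuses oversized state spaces with a size report
  big <- random_network(12, n_edges = 5)
  expect_error(enumerate_attractors(big, default_parameters(big),
                                    cap = 3^10), "531,441")
})

test_that("sampled attractors converge on the exact basin fractions", {
  set.seed(30)
  net <- random_network(4, n_edges = 7)
  params <- random_parameters(net)
  exact <- enumerate_attractors(net, params)
  N <- prod(net$nodes$n_levels)
  full <- sample_attractors(net, params,
                           inits = decode_all_states(net), max_steps = N)
  expect_equal(attr(full, "unconverged"), 0)
  expect_equal(vapply(full, `[[`, character(1), "id"),
               vapply(exact, `[[`, character(1), "id"))
  expect_equal(vapply(full, `[[`, numeric(1), "basin_frequency"),
               vapply(exact, `[[`, numeric(1), "basin_frequency"))
})

test_that("attractor sampling is seed-deterministic with study defaults", {
  expect_equal(eval(formals(sample_attractors)$n_inits), 1000L)
  expect_equal(eval(formals(sample_attractors)$max_steps), 50L)
  net <- toy_chain()
  params <- random_parameters(net, seed = 2)
  a1 <- sample_attractors(net, params, n_inits = 50, seed = 99)
  a2 <- sample_attractors(net, params, n_inits = 50, seed = 99)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
})

test_that("a single-basin network reports frequency one, none unconverged", {
  # one node with a strong self-inhibitor always drains to level 0
  net <- logic_network(data.frame(name = "A"),
                       data.frame(source = "A", target = "A",
                                  mode = "inhibit"), "A")
  p <- default_parameters(net)
  att <- sample_attractors(net, p, n_inits = 30, seed = 1)
  expect_length(att, 1L)
  expect_equal(att[[1]]$basin_frequency, 1)
  expect_equal(attr(att, "unconverged"), 0)
})

test_that("the asynchronous mode changes one node per step", {
  set.seed(11)
  net <- mutual_inhibition()
  p <- default_parameters(net)
  for (rep in 1:10) {
    s <- c(2L, 2L)
    s2 <- step_asynchronous(net, p, s)
    expect_lte(sum(s2 != s), 1L)
  }
})
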