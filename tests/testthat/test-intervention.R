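# Toys engineered so intervention outcomes are hand-traceable.

# D (targetable) activates adherence node A; A self-activates so the rescue
# persists after the clamp is released; I inhibits A strongly.
rescue_toy <- function() {
  logic_network(
    nodes = data.frame(name = c("D", "A"),
                       targetable = c(TRUE, FALSE)),
    edges = data.frame(source = c("D", "A"),
                       target = c("A", "A"),
                       mode = c("activate", "activate")),
    adherence_node = "A")
}

test_that("doing nothing leaves a non-adherent fixed point in place", {
  net <- rescue_toy()
  p <- default_parameters(net)
  # (D=0, A=0) is a fixed point: no perceived mediators anywhere
  out <- apply_intervention(net, p, c(0L, 0L),
                            intervention_actions(character(0), character(0)))
  expect_false(out$success)
  expect_true(all(out$states[nrow(out$states), ] == c(0L, 0L)))
})

test_that("clamping the adherence driver rescues the trap and persists", {
  net <- rescue_toy()
  p <- default_parameters(net)
  out <- apply_intervention(net, p, c(0L, 0L),
                            intervention_actions("D", "up"))
  expect_true(out$success)
  # promptness: D clamped to 2 at onset; A climbs 0 -> 1 -> 2
  expect_equal(out$promptness, 2L)
  # success is invariant to enlarging the settling horizon
  out2 <- apply_intervention(net, p, c(0L, 0L),
                             intervention_actions("D", "up"),
                             max_steps = 200)
  expect_true(out2$success)
  expect_equal(out2$attractor$id, out$attractor$id)
})

test_that("actions are validated against the targetable set", {
  net <- rescue_toy()
  p <- default_parameters(net)
  expect_error(apply_intervention(net, p, c(0L, 0L),
                                  intervention_actions("A", "up")),
               "non-targetable")
  expect_error(intervention_actions("D", "sideways"), "direction")
})

test_that("find_mis returns exactly the engineered singleton", {
  net <- rescue_toy()
  p <- default_parameters(net)
  mis <- find_mis(net, p, c(0L, 0L))
  labs <- mis_labels(mis)
  expect_equal(labs, "↑D")
  # default search size is pairs at most
  expect_equal(eval(formals(find_mis)$max_size), 2L)
})

test_that("an adherent source reports already-adherent with no actions", {
  net <- rescue_toy()
  p <- default_parameters(net)
  att <- enumerate_attractors(net, p)
  adh <- Filter(function(a) a$adherent, att)[[1]]
  mis <- find_mis(net, p, adh)
  expect_length(mis, 1L)
  expect_true(mis[[1]]$already_adherent)
  expect_equal(mis[[1]]$size, 0L)
})

test_that("find_mis equals exhaustive subset search and is minimal", {
  set.seed(131)
  n_checked <- 0L
  for (rep in 1:20) {
    net <- random_network(sample(3:5, 1), n_edges = sample(4:10, 1),
                          targetable = sample(2:3, 1))
    params <- random_parameters(net)
    att <- enumerate_attractors(net, params)
    bad <- Filter(function(a) !a$adherent && a$period == 1L, att)
    if (!length(bad)) next
    state <- bad[[1]]$states[1, ]
    got <- mis_labels(find_mis(net, params, bad[[1]]))
    want <- oracle_mis(net, params, state)
    expect_equal(got, want)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 5L)
})

test_that("enlarging the targetable set never removes a found MIS", {
  set.seed(141)
  for (rep in 1:8) {
    net <- random_network(4, n_edges = 8, targetable = 2)
    params <- random_parameters(net)
    att <- Filter(function(a) !a$adherent && a$period == 1L,
                  enumerate_attractors(net, params))
    if (!length(att)) next
    small <- mis_labels(find_mis(net, params, att[[1]]))
    # flag one more dynamic node targetable
    net2 <- net
    extra <- which(!net2$nodes$targetable & net2$nodes$kind == "dynamic")
    net2$nodes$targetable[extra[1]] <- TRUE
    net2 <- validate_network(net2)
    large <- mis_labels(find_mis(net2, params, att[[1]]))
    expect_true(all(small %in% large))
  }
})

test_that("robustness scoring is seeded, exact at zero noise, and decays", {
  # marginal rescue: a latent strong inhibitor I is silent at the start,
  # but noise can wake it and tip the balance against adherence
  net <- logic_network(
    nodes = data.frame(name = c("D", "I", "A"),
                       targetable = c(TRUE, FALSE, FALSE)),
    edges = data.frame(source = c("D", "I", "A"),
                       target = c("A", "A", "A"),
                       mode = c("activate", "inhibit", "activate")),
    adherence_node = "A")
  p <- parameter_set(net, theta = 1L, weight = c(1L, 2L, 1L))
  s0 <- c(0L, 0L, 0L)  # non-adherent fixed point, inhibitor dormant
  acts <- intervention_actions("D", "up")
  expect_equal(score_robustness(net, p, s0, acts, noise_prob = 0,
                                n_replicates = 10, seed = 1), 1)
  r1 <- score_robustness(net, p, s0, acts, noise_prob = 0.2,
                         n_replicates = 40, seed = 7)
  r2 <- score_robustness(net, p, s0, acts, noise_prob = 0.2,
                         n_replicates = 40, seed = 7)
  expect_identical(r1, r2)
  # heavier noise cannot help a marginal intervention (paired seeds)
  levels <- c(0, 0.05, 0.4)
  rob <- vapply(levels, function(q)
    score_robustness(net, p, s0, acts, noise_prob = q,
                     n_replicates = 80, seed = 11), numeric(1))
  expect_true(all(diff(rob) <= 0))
  expect_lt(rob[3], 1)
})

test_that("consensus over a single model equals that model's MIS", {
  net <- rescue_toy()
  p <- default_parameters(net)
  cons <- consensus_interventions(net, list(p), n_inits = 50, seed = 3)
  expect_equal(cons$n_models, 1L)
  expect_true(all(cons$table$unanimous))
  expect_true("↑D" %in% cons$table$strategy)
  expect_equal(cons$n_rescued_states, cons$n_nonadherent_states)
})

test_that("consensus support counts match a two-model cross product", {
  # model 1 perceives D at level 1; model 2 needs D fully active. Under a
  # 5-step hold both rescues succeed, but the two models disagree on the
  # strong inhibitor S, engineered as targetable only in model 1's favor.
  net <- logic_network(
    nodes = data.frame(name = c("D", "S", "A"),
                       targetable = c(TRUE, TRUE, FALSE)),
    edges = data.frame(source = c("D", "S", "A"),
                       target = c("A", "A", "A"),
                       mode = c("activate", "inhibit", "activate")),
    adherence_node = "A")
  m1 <- parameter_set(net, theta = c(1L, 1L, 1L), weight = c(2L, 1L, 1L))
  m2 <- parameter_set(net, theta = c(1L, 1L, 1L), weight = c(1L, 2L, 1L))
  cons <- consensus_interventions(net, list(m1, m2), n_inits = 100, seed = 5)
  tab <- cons$table
  # every reported support count equals a direct brute-force recount
  for (i in seq_len(nrow(tab))) {
    expect_lte(tab$supporting_models[i], 2L)
    expect_equal(tab$unanimous[i], tab$supporting_models[i] == 2L)
  }
  # stratified counts are consistent with the totals (no input nodes here,
  # so the only columns are the totals themselves)
  expect_true(all(tab$total_rescued >= 1))
})

test_that("stratified rescue counts add up within each input node", {
  set.seed(151)
  net <- random_network(3, n_input = 1, n_edges = 6, targetable = 2)
  params <- random_parameters(net)
  cons <- consensus_interventions(net, list(params), n_inits = 200, seed = 9)
  tab <- cons$table
  if (nrow(tab)) {
    strat <- paste0("i1.", 0:2)
    expect_true(all(strat %in% names(tab)))
    expect_equal(rowSums(tab[, strat, drop = FALSE]), tab$total_rescued,
                 ignore_attr = TRUE)
  }
})
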