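test_that("alignment error matches a hand-enumerated two-node example", {
  # A activates B (theta 1, weight 1); A has no in-edges
  net <- logic_network(
    nodes = data.frame(name = c("A", "B")),
    edges = data.frame(source = "A", target = "B", mode = "activate"),
    adherence_node = "B")
  p <- default_parameters(net)
  # observed: t1 (A=2, B=0) -> prediction t2 (A=2, B=1)
  #           t2 (A=2, B=2) -> prediction t3 (A=2, B=2) capped at max
  #           t3 (A=0, B=1)
  tr <- data.frame(
    participant_id = "p1", timepoint = 1:3,
    adherence = c("discontinued", "adherent", "discontinued"),
    A = c(2L, 2L, 0L), B = c(0L, 2L, 1L))
  ae <- alignment_error(net, p, tr, K = 1)
  # t2: |2-2| + |1-2| = 1 ; t3: |2-0| + |2-1| = 3
  expect_equal(ae$total, 4)
  expect_equal(ae$n_scored, 4L)
  expect_equal(ae$by_node$error[ae$by_node$node == "A"], 2)
  expect_equal(ae$by_node$error[ae$by_node$node == "B"], 2)
  expect_equal(ae$by_observation$error, c(1, 3))
  expect_equal(ae$n_mismatch, 3L)
  expect_equal(ae$coverage, 0.25)
})

test_that("a single discordant node carries all of the error", {
  net <- adherence_network()
  truth <- random_parameters(net, seed = 51)
  coh <- simulate_cohort(net, truth, n_participants = 4, seed = 52)
  # knock one observed dynamic level one step off at one participant's
  # final assessment (so no later prediction starts from the corrupted row)
  node <- "qol"
  p1 <- coh$participant_id[1]
  i <- which(coh$participant_id == p1 &
               coh$timepoint == max(coh$timepoint[coh$participant_id == p1]))
  coh[[node]][i] <- ifelse(coh[[node]][i] == 0L, 1L, coh[[node]][i] - 1L)
  coh$adherence <- adherence_status(coh$et_adherence, 2L)
  ae <- alignment_error(net, truth, coh, K = 1)
  expect_equal(ae$total, 1)
  expect_equal(ae$by_node$percent[ae$by_node$node == node], 100)
  expect_equal(sum(ae$by_node$error), 1)
})

test_that("both error decompositions always sum to the total", {
  set.seed(61)
  for (rep in 1:15) {
    net <- random_network(sample(2:5, 1), n_input = sample(0:2, 1),
                          n_edges = sample(2:8, 1))
    params <- random_parameters(net)
    tr <- random_trajectories(net, n_participants = 3)
    ae <- alignment_error(net, params, tr, K = sample(1:2, 1))
    expect_equal(sum(ae$by_node$error), ae$total)
    expect_equal(sum(ae$by_observation$error), ae$total)
    if (ae$total > 0) {
      expect_equal(sum(ae$by_node$percent), 100)
    }
    expect_gte(ae$coverage, 0)
    expect_lte(ae$coverage, 1)
  }
})

test_that("transition coverage is one for the generating model", {
  net <- adherence_network()
  truth <- random_parameters(net, seed = 71)
  coh <- simulate_cohort(net, truth, n_participants = 8, seed = 72)
  expect_equal(transition_coverage(net, truth, coh), 1)
  # a deliberately contrarian model scores below one
  anti <- parameter_set(net, theta = 2L, weight = 2L)
  expect_lt(transition_coverage(net, anti, coh), 1)
})

test_that("the per-node CSP equals brute-force filtering of the domain", {
  set.seed(81)
  for (rep in 1:40) {
    net <- random_network(sample(2:4, 1), n_edges = sample(1:6, 1))
    target <- sample(net$nodes$name[net$nodes$kind == "dynamic"], 1)
    n_ctx <- sample(0:5, 1)
    contexts <- lapply(seq_len(n_ctx), function(i) {
      list(start = vapply(net$nodes$n_levels,
                          function(L) sample.int(L, 1L) - 1L, integer(1)),
           observed = sample(0:2, 1))
    })
    tr <- contexts_to_trajectories(net, contexts, target)
    fitted <- fit_node_csp(net, target, tr)
    expected <- oracle_node_solutions(net, target, contexts)
    got <- fitted$solutions
    expect_equal(nrow(got), nrow(expected))
    if (nrow(expected) && ncol(expected)) {
      canon <- function(m) {
        m <- as.matrix(m); dimnames(m) <- NULL
        m[do.call(order, as.data.frame(m)), , drop = FALSE]
      }
      m <- nrow(fitted$edges)
      reord <- as.matrix(got[, c(rbind(paste0("theta.", seq_len(m)),
                                       paste0("weight.", seq_len(m))))])
      expect_equal(canon(reord), canon(expected))
    }
  }
})

test_that("CSP edge cases: forced thresholds, vacuity, contradiction", {
  # single activating in-edge; transitions pin the threshold at 2
  net <- logic_network(
    nodes = data.frame(name = c("S", "T")),
    edges = data.frame(source = "S", target = "T", mode = "activate"),
    adherence_node = "T")
  ctx <- list(list(start = c(1L, 1L), observed = 1L),   # S=1 not perceived
              list(start = c(2L, 1L), observed = 2L))   # S=2 perceived
  tr <- contexts_to_trajectories(net, ctx, "T")
  fitted <- fit_node_csp(net, "T", tr)
  expect_gt(nrow(fitted$solutions), 0)
  expect_true(all(fitted$solutions$theta.1 == 2L))

  # no scored transitions: the whole domain comes back
  tr_none <- contexts_to_trajectories(
    net, list(list(start = c(1L, 1L), observed = NA_integer_)), "T")
  vac <- fit_node_csp(net, "T", tr_none)
  expect_equal(nrow(vac$solutions), nrow(vac$assignments))
  expect_equal(nrow(vac$solutions), 4L)  # theta in {1,2} x weight in {1,2}

  # same perceived context, different outcomes: unsatisfiable
  ctx_bad <- list(list(start = c(2L, 1L), observed = 2L),
                  list(start = c(2L, 1L), observed = 0L))
  tr_bad <- contexts_to_trajectories(net, ctx_bad, "T")
  con <- fit_node_csp(net, "T", tr_bad)
  expect_equal(nrow(con$solutions), 0L)
})

test_that("parameter recovery: the true model is always among candidates", {
  net <- adherence_network()
  truth <- random_parameters(net, seed = 91)
  coh <- simulate_cohort(net, truth, n_participants = 30, seed = 92)
  fit <- fit_network(net, coh, max_models = 10)
  expect_true(contains_model(fit, truth, net))
  expect_true(all(fit$coverage == 1))
  expect_true(all(vapply(fit$models, function(m)
    transition_coverage(net, m, coh) == 1, logical(1))))
  # the candidate space shrinks (weakly) as transitions accumulate
  ids <- unique(coh$participant_id)
  sizes <- vapply(c(5, 15, 30), function(k) {
    sub <- coh[coh$participant_id %in% ids[seq_len(k)], ]
    fit_network(net, sub, max_models = 1)$n_candidates
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("max_models caps enumeration without changing the space size", {
  net <- toy_chain()
  # no data at all: every assignment is a candidate (4 per edge-bearing node)
  tr <- contexts_to_trajectories(
    net, list(list(start = c(1L, 1L, 1L), observed = NA_integer_)), "B")
  fit_all <- fit_network(net, tr, max_models = 100)
  expect_equal(fit_all$n_candidates, 16)  # 4 assignments each for B and C
  fit_cap <- fit_network(net, tr, max_models = 10)
  expect_length(fit_cap$models, 10L)
  expect_equal(fit_cap$n_candidates, 16)
  # enumeration order is deterministic
  fit_cap2 <- fit_network(net, tr, max_models = 10)
  expect_identical(lapply(fit_cap$models, as.data.frame),
                   lapply(fit_cap2$models, as.data.frame))
})

test_that("an unattainable coverage threshold reports the best achievable", {
  net <- logic_network(
    nodes = data.frame(name = c("S", "T")),
    edges = data.frame(source = "S", target = "T", mode = "activate"),
    adherence_node = "T")
  ctx_bad <- list(list(start = c(2L, 1L), observed = 2L),
                  list(start = c(2L, 1L), observed = 0L))
  tr_bad <- contexts_to_trajectories(net, ctx_bad, "T")
  fit <- fit_network(net, tr_bad, coverage_min = 0.9)
  expect_length(fit$models, 0L)
  expect_lt(fit$best_coverage, 0.9)
})

test_that("a node with injected extra noise shows the highest error", {
  net <- adherence_network()
  truth <- random_parameters(net, seed = 101)
  coh <- simulate_cohort(net, truth, n_participants = 40, seed = 102)
  set.seed(103)
  node <- "recurrence_worry"
  later <- which(coh$timepoint > 1)
  flip <- sample(later, 25)
  coh[[node]][flip] <- (coh[[node]][flip] + 1L) %% 3L
  coh$adherence <- adherence_status(coh$et_adherence, 2L)
  ae <- alignment_error(net, truth, coh, K = 1)
  expect_equal(ae$by_node$node[which.max(ae$by_node$error)], node)
})

test_that("added observation noise does not raise a fixed model's coverage", {
  net <- adherence_network()
  truth <- random_parameters(net, seed = 111)
  cov_clean <- mean(vapply(1:4, function(i) {
    coh <- simulate_cohort(net, truth, n_participants = 20, seed = 200 + i)
    transition_coverage(net, truth, coh)
  }, numeric(1)))
  cov_noisy <- mean(vapply(1:4, function(i) {
    coh <- simulate_cohort(net, truth, n_participants = 20,
                           noise_rate = 0.15, seed = 200 + i)
    transition_coverage(net, truth, coh)
  }, numeric(1)))
  expect_lte(cov_noisy, cov_clean)
})

test_that("multi-step global fitting recovers a small ground truth", {
  set.seed(121)
  net <- toy_chain()
  truth <- parameter_set(net, theta = c(2L, 1L), weight = c(1L, 2L))
  coh <- simulate_cohort(net, truth, n_participants = 12,
                         steps_between = 2L, seed = 122)
  fit2 <- fit_network(net, coh, K = 2L, coverage_min = 1)
  expect_gt(length(fit2$models), 0)
  expect_true(contains_model(fit2, truth, net) ||
                any(vapply(fit2$models, function(m)
                  transition_coverage(net, m, coh, K = 2L) == 1,
                  logical(1))))
})

test_that("candidate models round-trip through long-format TSV", {
  net <- toy_chain()
  tr <- contexts_to_trajectories(
    net, list(list(start = c(1L, 1L, 1L), observed = NA_integer_)), "B")
  fit <- fit_network(net, tr, max_models = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_models(fit, path)
  back <- read_models(path, net)
  expect_length(back, 5L)
  for (i in seq_along(back)) {
    expect_equal(align_parameters(net, back[[i]]),
                 align_parameters(net, fit$models[[i]]))
  }
})
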