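test_that("assignment scoring sums active-variable scores only", {
  inv <- small_inventory()
  tokens <- make_tokens(c("CANDIDATE_ANCHOR", "PROTEIN", "PROTEIN"))
  instance <- eventstack:::build_instance(tokens, inv)
  sc <- list(e = seq_len(nrow(instance$e_idx)),
             a = seq_len(nrow(instance$a_idx)) / 10,
             b = rep(2, nrow(instance$b_idx)))
  empty <- joint_assignment()
  expect_equal(eventstack:::score_assignment_cached(empty, instance, sc), 0)
  one <- joint_assignment(e = data.frame(i = 0L, t = "Phosphorylation"))
  k <- which(instance$e_idx$i == 0L & instance$e_idx$t == "Phosphorylation")
  expect_equal(eventstack:::score_assignment_cached(one, instance, sc), sc$e[k])
  # full assignment under all-ones scores equals the active-variable count
  sc1 <- list(e = rep(1, nrow(instance$e_idx)), a = rep(1, nrow(instance$a_idx)),
              b = rep(1, nrow(instance$b_idx)))
  y <- joint_assignment(
    e = data.frame(i = 0L, t = "Binding"),
    a = data.frame(i = c(0L, 0L), j = c(1L, 2L), r = "THEME"),
    b = data.frame(p = 1L, q = 2L))
  expect_equal(eventstack:::score_assignment_cached(y, instance, sc1), 4)
})

test_that("stacking features key on (candidate type, predicted type) with NONE for absences", {
  pred <- structure(list(system = "1P",
                         h = c(`3` = "Binding"),
                         arcs = data.frame(src = 3L, dst = 5L, role = "THEME")),
                    class = "stacked_prediction")
  f_match <- stacking_features(list(pred), 3L, "Binding")
  expect_named(f_match, "ST|S=1P|t=Binding|hS=Binding")
  f_cross <- stacking_features(list(pred), 3L, "Phosphorylation")
  expect_named(f_cross, "ST|S=1P|t=Phosphorylation|hS=Binding")
  f_none <- stacking_features(list(pred), 7L, "Binding")
  expect_named(f_none, "ST|S=1P|t=Binding|hS=NONE")
  expect_true(all(c(f_match, f_cross, f_none) == 1))
})

test_that("conjoined features double the key set when originals are retained", {
  pred <- structure(list(system = "S", h = c(`0` = "Binding"),
                         arcs = data.frame(src = integer(), dst = integer(),
                                           role = character())),
                    class = "stacked_prediction")
  base <- stats::setNames(rep(1, 4), paste0("f", 1:4))
  both <- conjoin_features(base, pred, 0L, retain = TRUE)
  expect_length(both, 8)
  only <- conjoin_features(base, pred, 0L, retain = FALSE)
  expect_length(only, 4)
  expect_false(any(names(only) %in% names(base)))
  expect_length(conjoin_features(stats::setNames(numeric(0), character(0)),
                                 pred, 0L), 0)
})

test_that("dual decomposition with an OPTIMAL certificate equals brute force on small instances", {
  set.seed(202)
  n_opt <- 0
  for (trial in 1:120) {
    ri <- random_joint_instance(sample(1:3, 1), sample(0:3, 1))
    res <- infer_dd(ri$instance, scores = ri$sc)
    bf <- brute_force_joint(ri$instance, ri$sc)
    if (res$certificate == "OPTIMAL") {
      n_opt <- n_opt + 1
      expect_equal(res$score, bf, tolerance = 1e-9)
      expect_lte(abs(res$dual_bound - res$score), 1e-9)
    } else {
      expect_lte(res$score, bf + 1e-9)
    }
    # every returned assignment satisfies all four constraints
    g <- eventstack:::assignment_to_graph(res$assignment, ri$instance$tokens)
    expect_length(check_constraints(g, ri$instance$inv), 0L)
  }
  expect_gt(n_opt, 80)
})

test_that("all-negative scores decode to the empty assignment at once", {
  ri <- random_joint_instance(2, 2)
  sc <- list(e = -abs(ri$sc$e) - 1, a = -abs(ri$sc$a) - 1,
             b = -abs(ri$sc$b) - 1)
  res <- infer_dd(ri$instance, scores = sc)
  expect_equal(res$certificate, "OPTIMAL")
  expect_equal(res$iterations, 1L)
  expect_equal(res$score, 0)
  expect_equal(nrow(res$assignment$e), 0L)
})

test_that("the best dual bound never increases across iterations", {
  set.seed(303)
  for (trial in 1:20) {
    ri <- random_joint_instance(3, 3)
    res <- infer_dd(ri$instance, scores = ri$sc)
    expect_true(all(diff(cummin(res$dual_trace)) <= 1e-12))
    expect_gte(res$dual_bound + 1e-9, res$score)
  }
})

test_that("MIRA reproduces the closed-form single-constraint update", {
  inv <- small_inventory()
  tokens <- make_tokens(c("CANDIDATE_ANCHOR", "PROTEIN"),
                        words = c("phos_1", "PROT1"))
  instance <- eventstack:::build_instance(tokens, inv)
  gold <- joint_assignment(e = data.frame(i = 0L, t = "Phosphorylation"),
                           a = data.frame(i = 0L, j = 1L, r = "THEME"))
  pred <- joint_assignment(e = data.frame(i = 0L, t = "Phosphorylation"),
                           a = data.frame(i = c(0L, 0L), j = c(1L, 1L),
                                          r = c("THEME", "CAUSE")))
  # loss = 1 (one extra CAUSE variable), margin = 0 under zero weights,
  # dphi = minus the CAUSE slot's features: tau = min(C, 1 / ||dphi||^2)
  ws <- eventstack:::new_weights()
  tau <- mira_update(ws, gold, pred, instance, C = 10)
  cause_feats <- instance$aF[[which(instance$a_idx$i == 0L &
                                    instance$a_idx$j == 1L &
                                    instance$a_idx$r == "CAUSE")]]
  expect_equal(tau, 1 / sum(cause_feats^2), tolerance = 1e-9)
  moved <- eventstack:::weights_get(ws, names(cause_feats))
  expect_equal(moved, rep(-tau, length(cause_feats)), tolerance = 1e-12)
  # with a single differing indicator feature the weight moves by exactly
  # loss / 1 (capped by C): check the capped branch too
  ws2 <- eventstack:::new_weights()
  tau2 <- mira_update(ws2, gold, pred, instance, C = 0.05)
  expect_equal(tau2, 0.05)
})

test_that("gold equal to prediction leaves weights untouched", {
  inv <- small_inventory()
  tokens <- make_tokens(c("CANDIDATE_ANCHOR", "PROTEIN"))
  instance <- eventstack:::build_instance(tokens, inv)
  y <- joint_assignment(e = data.frame(i = 0L, t = "Binding"),
                        a = data.frame(i = 0L, j = 1L, r = "THEME"))
  ws <- eventstack:::new_weights()
  expect_equal(mira_update(ws, y, y, instance), 0)
  expect_length(ls(ws$w), 0L)
})

test_that("training on a lexically separable corpus reaches F1 1.0 within 10 epochs", {
  cfg <- generator_config(n_docs = 25, groups_per_doc = 1,
                          trigger_ambiguity = 0, rho = 0,
                          multiword_trigger_rate = 0, cause_prob = 0, seed = 5)
  corpus <- generate_corpus(cfg)
  model <- train_joint(corpus, epochs = 10, C = 0.5, seed = 2)
  pred <- predict_joint(model, corpus)
  tab <- score_corpus(pred$corpus, corpus, match_policy("strict"))
  expect_equal(tab$f1[tab$category == "Overall"], 1.0)
})

test_that("predictions always satisfy the joint constraints", {
  cfg <- generator_config(n_docs = 30, seed = 77)
  corpus <- generate_corpus(cfg)
  model <- train_joint(corpus[1:10], epochs = 2, seed = 4)
  pred <- predict_joint(model, corpus)
  for (g in pred$graphs) {
    expect_length(check_constraints(g, model$inv), 0L)
  }
})

test_that("training is deterministic given the seed and fails on empty corpora", {
  cfg <- generator_config(n_docs = 8, seed = 12)
  corpus <- generate_corpus(cfg)
  m1 <- train_joint(corpus, epochs = 2, seed = 9)
  m2 <- train_joint(corpus, epochs = 2, seed = 9)
  expect_identical(eventstack:::weights_as_vector(m1$weights),
                   eventstack:::weights_as_vector(m2$weights))
  expect_error(train_joint(list()), class = "eventstack_usage_error")
})
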