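test_that("identical events match under both policies", {
  doc <- fig_example_doc()
  for (mode in c("strict", "approximate")) {
    for (ev in doc$events) {
      expect_true(events_match(ev, ev, doc, doc, match_policy(mode)))
    }
  }
})

test_that("span slack controls trigger-span tolerance", {
  gold <- fig_example_doc()
  # widen the Binding trigger one word to the left ("to binding" -> no;
  # here "inhibits binding": start moves from 38 to 29)
  pred <- gold
  k <- which(pred$triggers$id == "T5")
  pred$triggers$start[k] <- 29L
  pred$triggers$text[k] <- substring(pred$text, 30, pred$triggers$end[k])
  pred <- event_document(pred$doc_id, pred$text, pred$proteins, pred$triggers,
                         pred$events)
  bind_p <- Filter(function(e) e$type == "Binding", pred$events)[[1]]
  bind_g <- Filter(function(e) e$type == "Binding", gold$events)[[1]]
  expect_false(events_match(bind_p, bind_g, pred, gold,
                            match_policy("strict", span_slack = 0)))
  expect_true(events_match(bind_p, bind_g, pred, gold,
                           match_policy("strict", span_slack = 1)))
})

test_that("strict match implies approximate match on random event pairs", {
  set.seed(99)
  corpus <- generate_corpus(generator_config(n_docs = 40, seed = 15))
  pred <- corrupt_corpus(corpus, corruption_config(seed = 3))
  checked <- 0
  for (id in names(corpus)) {
    for (pe in pred[[id]]$events) {
      for (ge in corpus[[id]]$events) {
        s <- events_match(pe, ge, pred[[id]], corpus[[id]],
                          match_policy("strict"))
        if (s) {
          expect_true(events_match(pe, ge, pred[[id]], corpus[[id]],
                                   match_policy("approximate")))
          checked <- checked + 1
        }
      }
    }
  }
  expect_gt(checked, 10)
})

test_that("recursive matching agrees with the exhaustive bijection oracle", {
  set.seed(123)
  corpus <- generate_corpus(generator_config(
    n_docs = 200, regulation_nesting_prob = 0.6, binding_multitheme_prob = 0.6,
    cause_prob = 0.5, seed = 44))
  pred <- corrupt_corpus(corpus, corruption_config(
    anchor_miss_rate = 0.15, type_confusion_rate = 0.2, arc_miss_rate = 0.2,
    arc_add_rate = 0.15, span_jitter_rate = 0.2, seed = 45))
  n_pairs <- 0
  for (id in names(corpus)) {
    pdoc <- pred[[id]]; gdoc <- corpus[[id]]
    for (pe in pdoc$events) {
      for (ge in gdoc$events) {
        if (nrow(pe$args) > 4 || nrow(ge$args) > 4) next
        for (mode in c("strict", "approximate")) {
          pol <- match_policy(mode)
          expect_equal(events_match(pe, ge, pdoc, gdoc, pol),
                       brute_force_events_match(pe, ge, pdoc, gdoc, pol))
        }
        n_pairs <- n_pairs + 1
      }
    }
  }
  expect_gt(n_pairs, 1000)
})

test_that("approximate mode compares nested events on their THEME core only", {
  txt <- "reg bind P1 P2 C1"
  a1 <- paste0("T1\tProtein 9 11\tP1\nT2\tProtein 12 14\tP2\n",
               "T3\tProtein 15 17\tC1\n")
  gold_a2 <- paste0("T4\tRegulation 0 3\treg\nT5\tBinding 4 8\tbind\n",
                    "E1\tBinding:T5 Theme:T1 Theme2:T2\n",
                    "E2\tRegulation:T4 Theme:E1\n")
  # prediction's nested Binding misses the second THEME
  pred_a2 <- paste0("T4\tRegulation 0 3\treg\nT5\tBinding 4 8\tbind\n",
                    "E1\tBinding:T5 Theme:T1\n",
                    "E2\tRegulation:T4 Theme:E1\n")
  gold <- read_standoff("d", txt, a1, gold_a2)
  pred <- read_standoff("d", txt, a1, pred_a2)
  ge <- Filter(function(e) e$type == "Regulation", gold$events)[[1]]
  pe <- Filter(function(e) e$type == "Regulation", pred$events)[[1]]
  # the THEME sets of the nested event differ, so both policies reject;
  # but a nested CAUSE difference is forgiven only by the approximate mode
  expect_false(events_match(pe, ge, pred, gold, match_policy("approximate")))
  gold_a2c <- paste0("T4\tRegulation 0 3\treg\nT5\tRegulation 4 8\tbind\n",
                     "E1\tRegulation:T5 Theme:T1 Cause:T3\n",
                     "E2\tRegulation:T4 Theme:E1\n")
  pred_a2c <- paste0("T4\tRegulation 0 3\treg\nT5\tRegulation 4 8\tbind\n",
                     "E1\tRegulation:T5 Theme:T1\n",
                     "E2\tRegulation:T4 Theme:E1\n")
  goldc <- read_standoff("d", txt, a1, gold_a2c)
  predc <- read_standoff("d", txt, a1, pred_a2c)
  gec <- goldc$events[[which(vapply(goldc$events, `[[`, "", "trigger") == "T4")]]
  pec <- predc$events[[which(vapply(predc$events, `[[`, "", "trigger") == "T4")]]
  expect_false(events_match(pec, gec, predc, goldc, match_policy("strict")))
  expect_true(events_match(pec, gec, predc, goldc, match_policy("approximate")))
})

test_that("corpus scoring matches hand counts on the worked example", {
  gold <- list(fig1 = fig_example_doc())
  doc <- fig_example_doc()
  phos <- Filter(function(e) e$type == "Phosphorylation", doc$events)
  pred <- list(fig1 = event_document("fig1", doc$text, doc$proteins,
                                     doc$triggers[doc$triggers$id == "T3", ],
                                     phos))
  tab <- score_corpus(pred, gold, match_policy("strict"))
  overall <- tab[tab$category == "Overall", ]
  expect_equal(overall$tp, 1)
  expect_equal(overall$fn, 2)
  expect_equal(overall$precision, 1.0)
  expect_equal(overall$recall, 1 / 3)
})

test_that("perfect and empty predictions score 1 and 0", {
  corpus <- generate_corpus(generator_config(n_docs = 10, seed = 3))
  perfect <- score_corpus(corpus, corpus, match_policy("strict"))
  expect_true(all(perfect$f1[perfect$tp + perfect$fn > 0] == 1))
  empty <- lapply(corpus, function(d) event_document(d$doc_id, d$text, d$proteins))
  zero <- score_corpus(empty, corpus)
  expect_equal(zero$recall[zero$category == "Overall"], 0)
  expect_equal(zero$precision[zero$category == "Overall"], 0)
  expect_equal(zero$f1[zero$category == "Overall"], 0)
})

test_that("greedy one-to-one matching never exceeds the bipartite optimum and stays one-to-one", {
  set.seed(50)
  corpus <- generate_corpus(generator_config(n_docs = 50, seed = 21))
  pred <- corrupt_corpus(corpus, corruption_config(arc_add_rate = 0.2, seed = 8))
  pol <- match_policy("approximate")
  worse <- 0
  for (id in names(corpus)) {
    m <- eventstack:::greedy_match(pred[[id]], corpus[[id]], pol)
    expect_lte(m$tp, min(length(pred[[id]]$events), length(corpus[[id]]$events)))
    opt <- max_matching_count(pred[[id]], corpus[[id]], pol)
    expect_lte(m$tp, opt)
    if (m$tp < opt) worse <- worse + 1
  }
  # greedy may fall short of the optimum only on rare tangled match graphs
  expect_lte(worse, 3)
})
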