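test_that("the worked example projects to the expected labeled graph", {
  doc <- fig_example_doc()
  g <- events_to_graph(doc)
  # token positions: phosphorylation=1, TRAF2=3, inhibits=4, binding=5, CD40=8
  expect_equal(g$labels,
               data.frame(index = c(1L, 4L, 5L),
                          type = c("Phosphorylation", "Regulation", "Binding")))
  expect_setequal(paste(g$edges$src, g$edges$dst, g$edges$role),
                  c("1 3 THEME", "4 1 CAUSE", "4 5 THEME",
                    "5 3 THEME", "5 8 THEME"))
  expect_equal(g$binding_pairs, data.frame(p = 3L, q = 8L))
  expect_length(check_constraints(g), 0L)
})

test_that("a document with zero events yields an empty graph", {
  doc <- read_standoff("d", "STAT1 here", "T1\tProtein 0 5\tSTAT1\n", "")
  g <- events_to_graph(doc)
  expect_equal(nrow(g$labels), 0L)
  expect_equal(nrow(g$edges), 0L)
  expect_equal(nrow(g$binding_pairs), 0L)
})

test_that("a three-THEME Binding produces all unordered protein pairs", {
  txt <- "bind P1 P2 P3"
  a1 <- "T1\tProtein 5 7\tP1\nT2\tProtein 8 10\tP2\nT3\tProtein 11 13\tP3\n"
  a2 <- "T4\tBinding 0 4\tbind\nE1\tBinding:T4 Theme:T1 Theme2:T2 Theme3:T3\n"
  doc <- read_standoff("d", txt, a1, a2)
  g <- events_to_graph(doc)
  # oracle: all unordered pairs of co-THEME protein tokens
  prot_toks <- sort(g$edges$dst[g$edges$role == "THEME"])
  cmb <- t(utils::combn(prot_toks, 2))
  expect_equal(as.matrix(g$binding_pairs), cmb, ignore_attr = TRUE)
})

test_that("graph reconstruction inverts projection on the worked example", {
  doc <- fig_example_doc()
  g <- events_to_graph(doc)
  doc2 <- graph_to_events(g, doc_id = "fig1", text = doc$text,
                          proteins = doc$proteins)
  expect_length(doc2$events, 3L)
  g2 <- events_to_graph(doc2)
  expect_equal(g2$labels, g$labels)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$binding_pairs, g$binding_pairs)
})

test_that("binding splitting follows the pair relation", {
  tokens <- make_tokens(c("CANDIDATE_ANCHOR", "PROTEIN", "PROTEIN", "PROTEIN"))
  inv <- small_inventory()
  themes <- data.frame(src = 0L, dst = 1:3, role = "THEME")
  # no pairing asserted: three singleton Binding events
  g0 <- token_graph(tokens, data.frame(index = 0L, type = "Binding"), themes)
  d0 <- graph_to_events(g0, inv)
  expect_length(d0$events, 3L)
  expect_true(all(vapply(d0$events, function(e) nrow(e$args) == 1L, logical(1))))
  # full triangle: one three-THEME event (maximal clique)
  g1 <- token_graph(tokens, data.frame(index = 0L, type = "Binding"), themes,
                    data.frame(p = c(1L, 1L, 2L), q = c(2L, 3L, 3L)))
  d1 <- graph_to_events(g1, inv)
  expect_length(d1$events, 1L)
  expect_equal(nrow(d1$events[[1]]$args), 3L)
  # one pair only: a two-THEME event plus a singleton
  g2 <- token_graph(tokens, data.frame(index = 0L, type = "Binding"), themes,
                    data.frame(p = 1L, q = 2L))
  d2 <- graph_to_events(g2, inv)
  expect_setequal(vapply(d2$events, function(e) nrow(e$args), integer(1)),
                  c(2L, 1L))
})

test_that("constraint checking flags each violation type", {
  inv <- small_inventory()
  tokens <- make_tokens(c("CANDIDATE_ANCHOR", "PROTEIN", "CANDIDATE_ANCHOR",
                          "PROTEIN"))
  # (1) labeled anchor with only a CAUSE edge
  g1 <- token_graph(tokens, data.frame(index = 0L, type = "Regulation"),
                    data.frame(src = 0L, dst = 1L, role = "CAUSE"))
  expect_match(check_constraints(g1, inv), "no THEME", all = FALSE)
  # (2) CAUSE from an unlicensed label
  g2 <- token_graph(tokens, data.frame(index = 0L, type = "Phosphorylation"),
                    data.frame(src = c(0L, 0L), dst = c(1L, 3L),
                               role = c("THEME", "CAUSE")))
  expect_match(check_constraints(g2, inv), "unlicensed", all = FALSE)
  # (3) edge into an unlabeled anchor
  g3 <- token_graph(tokens, data.frame(index = 0L, type = "Regulation"),
                    data.frame(src = 0L, dst = 2L, role = "THEME"))
  expect_match(check_constraints(g3, inv), "not labeled", all = FALSE)
  # (4) binding pair with no witnessing anchor
  g4 <- token_graph(tokens, data.frame(index = 0L, type = "Regulation"),
                    data.frame(src = 0L, dst = 1L, role = "THEME"),
                    data.frame(p = 1L, q = 3L))
  expect_match(check_constraints(g4, inv), "witnessing", all = FALSE)
  # the worked example satisfies all four
  expect_length(check_constraints(events_to_graph(fig_example_doc())), 0L)
})

test_that("constraint checker agrees with brute-force quantification on random graphs", {
  inv <- small_inventory()
  set.seed(424)
  for (trial in 1:150) {
    n <- sample(3:8, 1)
    kinds <- sample(c("CANDIDATE_ANCHOR", "PROTEIN", "OTHER"), n, replace = TRUE)
    tokens <- make_tokens(kinds)
    anchors <- tokens$index[kinds == "CANDIDATE_ANCHOR"]
    prots <- tokens$index[kinds == "PROTEIN"]
    if (!length(anchors)) next
    lab_idx <- anchors[stats::runif(length(anchors)) < 0.7]
    labels <- if (length(lab_idx)) {
      data.frame(index = lab_idx,
                 type = sample(all_types(inv), length(lab_idx), replace = TRUE))
    } else NULL
    targets <- c(prots, anchors)
    edges <- NULL
    if (length(lab_idx) && length(targets)) {
      cand <- expand.grid(src = lab_idx, dst = targets,
                          role = c("THEME", "CAUSE"),
                          stringsAsFactors = FALSE)
      cand <- cand[cand$src != cand$dst, , drop = FALSE]
      edges <- cand[stats::runif(nrow(cand)) < 0.3, , drop = FALSE]
    }
    pairs <- NULL
    if (length(prots) >= 2 && stats::runif(1) < 0.5) {
      cmb <- utils::combn(prots, 2)
      pick <- sample(ncol(cmb), 1)
      pairs <- data.frame(p = cmb[1, pick], q = cmb[2, pick])
    }
    g <- token_graph(tokens, labels, edges, pairs)
    expect_equal(length(check_constraints(g, inv)) == 0L,
                 brute_force_constraint_check(g, inv))
  }
})

test_that("multiword trigger spans map to their annotated head token", {
  txt <- "acts as signal PROT1"
  tokens <- data.frame(index = 0:3, start = c(0L, 5L, 8L, 15L),
                       end = c(4L, 7L, 14L, 20L),
                       text = c("acts", "as", "signal", "PROT1"),
                       kind = c("CANDIDATE_ANCHOR", "OTHER", "OTHER", "PROTEIN"),
                       head = c(1L, 0L, 0L, 1L), sentence = 1L)
  doc <- event_document("d", txt,
    proteins = data.frame(id = "T1", type = "Protein", start = 15L, end = 20L,
                          text = "PROT1"),
    triggers = data.frame(id = "T2", type = "Gene_expression", start = 0L,
                          end = 14L, text = "acts as signal"),
    events = list(list(id = "E1", type = "Gene_expression", trigger = "T2",
                       args = data.frame(role = "THEME", target = "T1"))),
    tokens = tokens)
  g <- events_to_graph(doc)
  expect_equal(g$labels$index, 0L)  # annotated head
  # without a head annotation the last overlapping anchor-capable token wins
  tokens$head <- c(0L, 0L, 0L, 1L)
  doc$tokens <- tokens
  g2 <- events_to_graph(doc)
  expect_equal(g2$labels$index, 0L)
})
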