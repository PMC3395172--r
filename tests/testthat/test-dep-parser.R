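test_that("projection drops non-participants, keeps single heads, and roots the rest", {
  # a single event: two nodes plus the root attachment
  txt <- "phos_1 PROT1 w1"
  doc <- read_standoff("d", txt,
    "T1\tProtein 7 12\tPROT1\n",
    "T2\tPhosphorylation 0 6\tphos_1\nE1\tPhosphorylation:T2 Theme:T1\n")
  tr <- project_to_tree(doc)
  expect_equal(sort(tr$nodes$node), c(0L, 1L))  # filler word removed
  expect_equal(tr$edges$head[tr$edges$dep == 1L], 0L)
  expect_equal(tr$edges$head[tr$edges$dep == 0L], eventstack:::ROOT_NODE)
})

test_that("a node with two parents keeps the earliest head", {
  # P at token 2 is THEME of anchors at 0 and 5: projection keeps head 0
  tokens <- make_tokens(c("CANDIDATE_ANCHOR", "OTHER", "PROTEIN", "OTHER",
                          "OTHER", "CANDIDATE_ANCHOR"))
  doc <- graph_to_events(token_graph(
    tokens,
    labels = data.frame(index = c(0L, 5L),
                        type = c("Phosphorylation", "Gene_expression")),
    edges = data.frame(src = c(0L, 5L), dst = 2L, role = "THEME")),
    type_inventory("ge"))
  doc$tokens <- tokens
  tr <- project_to_tree(doc)
  expect_equal(tr$edges$head[tr$edges$dep == 2L], 0L)
  # single-head property holds (validated on construction)
  expect_s3_class(tr, "dependency_tree")
})

test_that("tree conversion inverts projection on tree-shaped documents", {
  corpus <- generate_corpus(generator_config(
    n_docs = 40, multiword_trigger_rate = 0, rho = 0,
    binding_multitheme_prob = 0, seed = 91))
  for (doc in corpus) {
    # tree-shaped: every argument has a unique parent
    g <- events_to_graph(doc)
    if (anyDuplicated(g$edges$dst)) next
    tr <- project_to_tree(doc)
    back <- tree_to_events(tr, doc$tokens, doc_id = doc$doc_id,
                           text = doc$text, proteins = doc$proteins)
    g2 <- events_to_graph(back)
    expect_equal(g2$labels, g$labels)
    expect_equal(g2$edges, g$edges)
  }
})

test_that("a Binding anchor's THEME children form one multi-THEME event", {
  tokens <- make_tokens(c("CANDIDATE_ANCHOR", "PROTEIN", "PROTEIN"))
  tr <- dependency_tree(
    data.frame(node = 0:2, kind = c("CANDIDATE_ANCHOR", "PROTEIN", "PROTEIN"),
               type = c("Binding", NA, NA)),
    data.frame(head = c(eventstack:::ROOT_NODE, 0L, 0L), dep = 0:2,
               role = c("ROOT", "THEME", "THEME")))
  doc <- tree_to_events(tr, tokens, small_inventory())
  expect_length(doc$events, 1L)
  expect_equal(nrow(doc$events[[1]]$args), 2L)
})

test_that("an anchor with only a CAUSE child emits no event", {
  tokens <- make_tokens(c("CANDIDATE_ANCHOR", "PROTEIN"))
  tr <- dependency_tree(
    data.frame(node = 0:1, kind = c("CANDIDATE_ANCHOR", "PROTEIN"),
               type = c("Regulation", NA)),
    data.frame(head = c(eventstack:::ROOT_NODE, 0L), dep = 0:1,
               role = c("ROOT", "CAUSE")))
  doc <- tree_to_events(tr, tokens, small_inventory())
  expect_length(doc$events, 0L)
})

test_that("both decoders equal brute force on random instances and nest properly", {
  set.seed(515)
  for (trial in 1:60) {
    n <- sample(2:5, 1)
    nodes <- sort(sample(0:9, n))
    scorer <- random_edge_scorer(nodes)
    tp <- decode_projective(nodes, scorer)
    tn <- decode_nonprojective(nodes, scorer)
    sp <- eventstack:::tree_score(tp, scorer)
    sn <- eventstack:::tree_score(tn, scorer)
    expect_equal(sp, brute_force_tree(nodes, scorer, projective = TRUE),
                 tolerance = 1e-9)
    expect_equal(sn, brute_force_tree(nodes, scorer, projective = FALSE),
                 tolerance = 1e-9)
    expect_gte(sn, sp - 1e-9)
    # projective output never contains crossing arcs (root drawn at the left)
    ee <- data.frame(src = tp$edges$head, dst = tp$edges$dep)
    expect_equal(crossing_count(ee), 0L)
  }
})

test_that("two-node instances decode identically under both decoders", {
  set.seed(99)
  nodes <- c(0L, 1L)
  scorer <- random_edge_scorer(nodes)
  tp <- decode_projective(nodes, scorer)
  tn <- decode_nonprojective(nodes, scorer)
  expect_equal(tp$edges, tn$edges)
})

test_that("parser training reaches perfect attachment on a separable corpus", {
  cfg <- generator_config(n_docs = 20, groups_per_doc = 1,
                          trigger_ambiguity = 0, rho = 0,
                          multiword_trigger_rate = 0, cause_prob = 0, seed = 5)
  corpus <- generate_corpus(cfg)
  for (dec in c("1p", "1n")) {
    m <- train_parser(corpus, epochs = 10, seed = 3, decoder = dec)
    accs <- vapply(corpus, function(doc) {
      gold <- project_to_tree(doc, keep_all = TRUE)
      decode <- if (dec == "1p") decode_projective else decode_nonprojective
      pred <- decode(sort(gold$nodes$node),
                     eventstack:::edge_scorer(doc$tokens, m$weights),
                     gold$nodes)
      gk <- paste(gold$edges$head, gold$edges$dep, gold$edges$role)
      pk <- paste(pred$edges$head, pred$edges$dep, pred$edges$role)
      mean(gk %in% pk)
    }, numeric(1))
    expect_equal(mean(accs), 1.0)
  }
})

test_that("zero-epoch weights decode deterministically", {
  cfg <- generator_config(n_docs = 4, seed = 3)
  corpus <- generate_corpus(cfg)
  m <- train_parser(corpus, epochs = 0, seed = 1)
  expect_length(ls(m$weights$w), 0L)
  p1 <- predict_parser(m, corpus)
  p2 <- predict_parser(m, corpus)
  expect_identical(lapply(p1$corpus, write_standoff),
                   lapply(p2$corpus, write_standoff))
})

test_that("the non-projective decoder recalls crossing-arc events the projective one cannot", {
  cfg <- generator_config(n_docs = 60, rho = 0.35, trigger_ambiguity = 0,
                          multiword_trigger_rate = 0, seed = 17)
  corpus <- generate_corpus(cfg)
  crossdocs <- names(corpus)[vapply(corpus, function(d) {
    crossing_count(events_to_graph(d)) > 0
  }, logical(1))]
  recalls <- vapply(c("1p", "1n"), function(dec) {
    m <- train_parser(corpus, epochs = 5, seed = 3, decoder = dec)
    p <- predict_parser(m, corpus[crossdocs])
    score_corpus(p$corpus, corpus[crossdocs])$recall[4]
  }, numeric(1))
  expect_gt(recalls[["1n"]], recalls[["1p"]])
})

test_that("cross-validated predictions cover every document exactly once, unseen", {
  cfg <- generator_config(n_docs = 18, trigger_ambiguity = 0,
                          multiword_trigger_rate = 0, seed = 8)
  corpus <- generate_corpus(cfg)
  sp <- stacked_predictions(corpus, n_folds = 3, seed = 2, epochs = 2)
  aud <- attr(sp, "audit")
  expect_setequal(aud$doc_id, names(corpus))
  expect_false(any(duplicated(aud$doc_id)))
  plan <- fold_plan(names(corpus), 3, seed = 2)
  for (k in seq_len(nrow(aud))) {
    expect_equal(unname(plan[aud$doc_id[k]]), aud$fold[k])
  }
  # leave-one-out boundary
  small <- corpus[1:5]
  loo <- stacked_predictions(small, n_folds = 5, seed = 1, epochs = 1)
  expect_equal(sort(attr(loo, "audit")$fold), 1:5)
  expect_error(stacked_predictions(small, n_folds = 1),
               class = "eventstack_usage_error")
})

test_that("cross-validated training predictions are weaker than self-trained ones", {
  cfg <- generator_config(n_docs = 24, trigger_ambiguity = 0.6, seed = 55)
  corpus <- generate_corpus(cfg)
  cv <- attr(stacked_predictions(corpus, n_folds = 4, seed = 3, epochs = 4),
             "corpus")
  self <- predict_parser(train_parser(corpus, epochs = 4, seed = 3), corpus)$corpus
  f_cv <- score_corpus(cv, corpus)$f1[4]
  f_self <- score_corpus(self, corpus)$f1[4]
  expect_lt(f_cv, f_self)
})

test_that("corpus merging replicates the primary corpus with unique ids", {
  corpus <- generate_corpus(generator_config(n_docs = 6, seed = 1))
  aux <- generate_corpus(generator_config(n_docs = 4, seed = 2))
  names(aux) <- paste0("aux_", names(aux))
  for (i in seq_along(aux)) aux[[i]]$doc_id <- names(aux)[i]
  plain <- merge_corpora(corpus, aux, replication = 1)
  expect_length(plain, 10L)
  tripled <- merge_corpora(corpus, aux, replication = 3)
  expect_length(tripled, 3 * 6 + 4)
  expect_false(any(duplicated(names(tripled))))
  only <- merge_corpora(corpus, list(), replication = 2)
  expect_length(only, 12L)
})
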