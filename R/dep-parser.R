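# The stacked model: events are projected onto single-head dependency trees
# over event anchors and entities, an edge-factored parser is trained with
# averaged structured-perceptron updates, and sentences are decoded either
# projectively (Eisner, "1P") or non-projectively (maximum spanning
# arborescence, "1N"). Cross-validated predictions feed the stacker.

ROOT_NODE <- -1L

#' Dependency-tree constructor
#'
#' A reduced event structure: nodes are event anchors and entity tokens
#' (token indices) plus a virtual root; every non-root node has exactly one
#' head; edges carry a role (`THEME`, `CAUSE`, or `ROOT` for attachments to
#' the virtual root).
#'
#' @param nodes data.frame with columns `node` (token index), `kind`
#'   (`PROTEIN`/`CANDIDATE_ANCHOR`), `type` (event type for anchors that
#'   anchor an event, else `NA`).
#' @param edges data.frame with columns `head` (token index or -1 for the
#'   root), `dep`, `role`.
#' @return Object of class `dependency_tree`.
#' @export
dependency_tree <- function(nodes, edges) {
  edges <- edges[order(edges$dep), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  tr <- structure(list(nodes = nodes, edges = edges), class = "dependency_tree")
  validate_tree(tr)
  tr
}

validate_tree <- function(tr) {
  deps <- tr$edges$dep
  if (anyDuplicated(deps)) stop_validation("node with two heads in dependency tree")
  if (!setequal(deps, tr$nodes$node)) {
    stop_validation("tree edges must cover every non-root node exactly once")
  }
  # acyclicity/connectedness: walk from each node to the root
  head_of <- stats::setNames(tr$edges$head, tr$edges$dep)
  for (n in tr$nodes$node) {
    seen <- integer(0); cur <- n
    while (cur != ROOT_NODE) {
      if (cur %in% seen) stop_validation("cycle in dependency tree")
      seen <- c(seen, cur)
      cur <- head_of[[as.character(cur)]]
    }
  }
  invisible(tr)
}

#' @export
print.dependency_tree <- function(x, ...) {
  cat(sprintf("<dependency_tree: %d nodes>\n", nrow(x$nodes)))
  invisible(x)
}

#' Project a document's events onto a dependency tree
#'
#' Reduces the event structure to a tree: words taking part in no event are
#' removed (unless `keep_all` retains every candidate node), multiword
#' anchors are represented by their head tokens, and nodes with several
#' parents keep only the head whose token appears earliest (ties broken by
#' role priority THEME before CAUSE). Remaining roots attach to the virtual
#' root.
#'
#' @param doc An [event_document()].
#' @param tokens Token table.
#' @param inv A [type_inventory()].
#' @param keep_all Also include candidate-anchor and protein tokens that
#'   take part in no event, attached to the virtual root (the node set the
#'   parser decodes over).
#' @return A [dependency_tree()].
#' @export
project_to_tree <- function(doc, tokens = doc$tokens,
                            inv = type_inventory("ge"), keep_all = FALSE) {
  if (is.null(tokens)) tokens <- tokens_from_text(doc)
  g <- events_to_graph(doc, tokens = tokens, inv = inv)
  participating <- sort(unique(c(g$labels$index, g$edges$dst)))
  node_idx <- if (keep_all) {
    sort(unique(c(participating,
                  tokens$index[tokens$kind %in% c("PROTEIN", "CANDIDATE_ANCHOR")])))
  } else participating
  kind <- stats::setNames(tokens$kind, tokens$index)
  lab <- stats::setNames(g$labels$type, g$labels$index)
  nodes <- data.frame(node = node_idx,
                      kind = unname(kind[as.character(node_idx)]),
                      type = unname(lab[as.character(node_idx)]),
                      stringsAsFactors = FALSE)
  # single-head reduction: earliest head token wins, THEME beats CAUSE
  role_prio <- c(THEME = 0L, CAUSE = 1L)
  ee <- g$edges
  ee <- ee[order(ee$dst, ee$src, role_prio[ee$role]), , drop = FALSE]
  ee <- ee[!duplicated(ee$dst), , drop = FALSE]
  # dropping extra parents cannot create cycles; attach parentless nodes to root
  edges <- data.frame(head = ee$src, dep = ee$dst, role = ee$role,
                      stringsAsFactors = FALSE)
  # guard against cycles possible in predicted graphs
  edges <- drop_tree_cycles(edges)
  rootless <- setdiff(node_idx, edges$dep)
  if (length(rootless)) {
    edges <- rbind(edges, data.frame(head = ROOT_NODE, dep = rootless,
                                     role = "ROOT"))
  }
  dependency_tree(nodes, edges)
}

# Remove head assignments that close cycles (keep the edge whose dep is
# smallest; deterministic).
drop_tree_cycles <- function(edges) {
  repeat {
    head_of <- stats::setNames(edges$head, edges$dep)
    bad <- NULL
    for (n in edges$dep) {
      seen <- integer(0); cur <- n
      while (cur != ROOT_NODE && cur %in% names2int(head_of)) {
        if (cur %in% seen) { bad <- max(seen); break }
        seen <- c(seen, cur)
        cur <- head_of[[as.character(cur)]]
      }
      if (!is.null(bad)) break
    }
    if (is.null(bad)) return(edges)
    edges <- edges[edges$dep != bad, , drop = FALSE]
  }
}

names2int <- function(x) as.integer(names(x))

#' Convert a dependency tree back to events
#'
#' Anchor nodes with outgoing THEME edges become events, with valences
#' enforced: a Binding anchor collects all its THEME children into one
#' event; a regulation anchor keeps its first THEME and at most one CAUSE;
#' simple anchors yield one event per THEME child. Anchors without THEME
#' children form no event, and arguments pointing at them are dropped
#' (cascading).
#'
#' @param tree A [dependency_tree()].
#' @param tokens Token table the tree was built over.
#' @param inv A [type_inventory()].
#' @param doc_id,text,proteins Document metadata (synthesized when absent).
#' @return An [event_document()].
#' @export
tree_to_events <- function(tree, tokens, inv = type_inventory("ge"),
                           doc_id = "doc", text = NULL, proteins = NULL) {
  anchors <- tree$nodes$node[tree$nodes$kind == "CANDIDATE_ANCHOR" &
                             !is.na(tree$nodes$type)]
  type_of <- stats::setNames(tree$nodes$type, tree$nodes$node)
  # order anchors bottom-up (children before parents)
  depth <- function(n) {
    d <- 0L; cur <- n
    head_of <- stats::setNames(tree$edges$head, tree$edges$dep)
    while (cur != ROOT_NODE) { cur <- head_of[[as.character(cur)]]; d <- d + 1L }
    d
  }
  anchors <- anchors[order(-vapply(anchors, depth, integer(1)), anchors)]

  labels <- list(); edges <- list(); pairs <- list()
  formed <- logical(length(anchors)); names(formed) <- anchors
  is_prot <- stats::setNames(tree$nodes$kind == "PROTEIN", tree$nodes$node)
  for (i in anchors) {
    ch <- tree$edges[tree$edges$head == i, , drop = FALSE]
    ok_child <- vapply(ch$dep, function(d) {
      is_prot[[as.character(d)]] || isTRUE(unname(formed[as.character(d)]))
    }, logical(1))
    ch <- ch[ok_child, , drop = FALSE]
    t <- type_of[[as.character(i)]]
    themes <- ch$dep[ch$role == "THEME"]
    causes <- ch$dep[ch$role == "CAUSE"]
    if (!length(themes)) next
    formed[[as.character(i)]] <- TRUE
    if (t %in% inv$binding_types) {
      # all THEME children in one event
      if (length(themes) >= 2) {
        prot_th <- themes[vapply(themes, function(d) is_prot[[as.character(d)]],
                                 logical(1))]
        if (length(prot_th) >= 2) {
          cmb <- utils::combn(sort(prot_th), 2L)
          pairs[[length(pairs) + 1L]] <- data.frame(p = cmb[1, ], q = cmb[2, ])
        }
      }
      edges[[length(edges) + 1L]] <-
        data.frame(src = i, dst = themes, role = "THEME")
    } else if (t %in% inv$regulation_types) {
      keep_t <- sort(themes)[1]
      ed <- data.frame(src = i, dst = keep_t, role = "THEME")
      if (t %in% inv$cause_licensed_types && length(causes)) {
        ed <- rbind(ed, data.frame(src = i, dst = sort(causes)[1],
                                   role = "CAUSE"))
      }
      edges[[length(edges) + 1L]] <- ed
    } else {
      edges[[length(edges) + 1L]] <-
        data.frame(src = i, dst = themes, role = "THEME")
    }
    labels[[length(labels) + 1L]] <- data.frame(index = i, type = t)
  }
  g <- token_graph(tokens, do.call(rbind, labels) %||% NULL,
                   do.call(rbind, edges) %||% NULL,
                   do.call(rbind, pairs) %||% NULL)
  graph_to_events(g, inv, doc_id = doc_id, text = text, proteins = proteins)
}

# Decoders --------------------------------------------------------------------

# Dense score lookup: list with matrix S (n+1 x n), role matrix, node ids.
# Internal indexing: position 0 = root, positions 1..n = nodes in token order.
build_score_matrices <- function(nodes, edge_scores) {
  n <- length(nodes)
  S <- matrix(-Inf, n + 1, n + 1)
  R <- matrix(NA_character_, n + 1, n + 1)
  for (d in seq_len(n)) {
    S[1, d + 1] <- edge_scores(ROOT_NODE, nodes[d], "ROOT")
    R[1, d + 1] <- "ROOT"
    for (h in seq_len(n)) {
      if (h == d) next
      best <- -Inf; br <- NA_character_
      for (r in c("THEME", "CAUSE")) {
        v <- edge_scores(nodes[h], nodes[d], r)
        if (v > best) { best <- v; br <- r }
      }
      S[h + 1, d + 1] <- best
      R[h + 1, d + 1] <- br
    }
  }
  list(S = S, R = R)
}

#' Projective decoding (Eisner's algorithm)
#'
#' Finds the maximum-total-score projective dependency tree over the given
#' nodes (first-order edge factorization). The virtual root sits left of
#' all tokens, so the output never contains crossing arcs.
#'
#' @param nodes Integer vector of node token indices, sorted.
#' @param edge_scores Function `(head, dep, role) -> numeric`; `head` is a
#'   node index or -1 for the root (role `"ROOT"`).
#' @param node_meta Optional data.frame (`node`, `kind`, `type`) carried
#'   onto the output tree.
#' @return A [dependency_tree()].
#' @export
decode_projective <- function(nodes, edge_scores, node_meta = NULL) {
  nodes <- sort(nodes)
  n <- length(nodes)
  if (n == 0L) stop_usage("no nodes to decode")
  sm <- build_score_matrices(nodes, edge_scores)
  S <- sm$S
  N <- n + 1  # positions 1..N with 1 = root

  comp <- array(-Inf, c(N, N, 2))   # [i, j, dir]: dir 1 = right (head i), 2 = left (head j)
  incomp <- array(-Inf, c(N, N, 2))
  bc <- array(NA_integer_, c(N, N, 2))  # backpointers
  bi <- array(NA_integer_, c(N, N, 2))
  for (i in seq_len(N)) comp[i, i, ] <- 0

  for (len in seq_len(N - 1)) {
    for (i in seq_len(N - len)) {
      j <- i + len
      # incomplete spans: edge between i and j
      ks <- i:(j - 1)
      vals <- comp[cbind(i, ks, 1)] + comp[cbind(ks + 1, j, 2)]
      best <- which.max(vals)
      incomp[i, j, 1] <- vals[best] + S[i, j]  # i -> j
      bi[i, j, 1] <- ks[best]
      incomp[i, j, 2] <- vals[best] + S[j, i]  # j -> i
      bi[i, j, 2] <- ks[best]
      # complete spans
      ks2 <- (i + 1):j
      vals2 <- incomp[cbind(i, ks2, 1)] + comp[cbind(ks2, j, 1)]
      b2 <- which.max(vals2)
      comp[i, j, 1] <- vals2[b2]
      bc[i, j, 1] <- ks2[b2]
      ks3 <- i:(j - 1)
      vals3 <- comp[cbind(i, ks3, 2)] + incomp[cbind(ks3, j, 2)]
      b3 <- which.max(vals3)
      comp[i, j, 2] <- vals3[b3]
      bc[i, j, 2] <- ks3[b3]
    }
  }

  heads <- integer(N)  # heads[pos] = head position (0 = none yet)
  walk_comp <- function(i, j, dir) {
    if (i == j) return(invisible())
    k <- bc[i, j, dir]
    if (dir == 1L) { walk_incomp(i, k, 1L); walk_comp(k, j, 1L) }
    else { walk_comp(i, k, 2L); walk_incomp(k, j, 2L) }
  }
  walk_incomp <- function(i, j, dir) {
    if (dir == 1L) heads[j] <<- i else heads[i] <<- j
    k <- bi[i, j, dir]
    walk_comp(i, k, 1L)
    walk_comp(k + 1L, j, 2L)
  }
  walk_comp(1L, N, 1L)

  edges <- data.frame(
    head = head_positions_to_nodes(heads[-1], nodes),
    dep = nodes,
    role = sm$R[cbind(heads[-1], 2:N)],
    stringsAsFactors = FALSE)
  finish_tree(nodes, edges, node_meta)
}

# Map internal head positions (1 = virtual root) back to token indices.
head_positions_to_nodes <- function(hpos, nodes) {
  vapply(hpos, function(h) if (h == 1L) ROOT_NODE else nodes[h - 1L],
         integer(1))
}

#' Non-projective decoding (maximum spanning arborescence)
#'
#' Chu-Liu-Edmonds search for the arborescence rooted at the virtual root
#' with the highest total edge score. The search space contains every
#' projective tree, so the returned score is always at least that of
#' [decode_projective()].
#'
#' @inheritParams decode_projective
#' @return A [dependency_tree()].
#' @export
decode_nonprojective <- function(nodes, edge_scores, node_meta = NULL) {
  nodes <- sort(nodes)
  n <- length(nodes)
  if (n == 0L) stop_usage("no nodes to decode")
  sm <- build_score_matrices(nodes, edge_scores)
  # internal: vertices 1..(n+1), vertex 1 = root
  heads <- cle(sm$S)
  edges <- data.frame(
    head = head_positions_to_nodes(heads, nodes),
    dep = nodes,
    role = sm$R[cbind(heads, seq_len(n) + 1L)],
    stringsAsFactors = FALSE)
  finish_tree(nodes, edges, node_meta)
}

# Chu-Liu-Edmonds over dense matrix S[(n+1) x (n+1)], root = vertex 1.
# Returns the head vertex of each non-root vertex (length n, for vertices
# 2..n+1).
cle <- function(S) {
  N <- nrow(S)
  verts <- seq_len(N)
  solve_rec <- function(S, verts) {
    root <- verts[1]
    others <- verts[-1]
    best_head <- vapply(others, function(d) {
      verts[which.max(S[verts, d])]
    }, integer(1))
    # detect a cycle among chosen heads
    head_map <- stats::setNames(best_head, others)
    cyc <- NULL
    for (v in others) {
      path <- integer(0); cur <- v
      while (cur != root) {
        if (cur %in% path) {
          start <- match(cur, path)
          cyc <- path[start:length(path)]
          break
        }
        path <- c(path, cur)
        cur <- head_map[[as.character(cur)]]
      }
      if (!is.null(cyc)) break
    }
    if (is.null(cyc)) {
      return(head_map)
    }
    # contract the cycle into a supernode
    cyc_score <- sum(S[cbind(head_map[as.character(cyc)], cyc)])
    super <- max(verts) + 1L
    S2 <- rbind(cbind(S, -Inf), -Inf)
    keep <- c(setdiff(verts, cyc), super)
    for (v in setdiff(verts, cyc)) {
      # into the cycle: best entry point, adjusted
      entry <- vapply(cyc, function(c_) {
        S[v, c_] - S[head_map[[as.character(c_)]], c_]
      }, numeric(1))
      S2[v, super] <- max(entry) + cyc_score
      # out of the cycle
      S2[super, v] <- max(S[cyc, v])
    }
    sub <- solve_rec(S2, c(root, setdiff(keep, root)))
    # expand
    out <- sub[names(sub) != as.character(super)]
    out <- stats::setNames(as.integer(out), names(out))
    # head of supernode: recover the entry edge
    hs <- sub[[as.character(super)]]
    entry_scores <- vapply(cyc, function(c_) {
      S[hs, c_] - S[head_map[[as.character(c_)]], c_]
    }, numeric(1))
    enter_at <- cyc[which.max(entry_scores)]
    for (c_ in cyc) {
      out[as.character(c_)] <- if (c_ == enter_at) hs
                               else head_map[[as.character(c_)]]
    }
    # children of the supernode reattach to their best cycle vertex
    for (v in names(sub)) {
      if (v == as.character(super)) next
      if (sub[[v]] == super) {
        out[[v]] <- cyc[which.max(S[cyc, as.integer(v)])]
      }
    }
    out
  }
  hm <- solve_rec(S, verts)
  vapply(as.character(seq(2L, N)), function(v) hm[[v]], integer(1))
}

finish_tree <- function(nodes, edges, node_meta) {
  meta <- if (!is.null(node_meta)) {
    node_meta[match(nodes, node_meta$node), , drop = FALSE]
  } else {
    data.frame(node = nodes, kind = "CANDIDATE_ANCHOR", type = NA_character_)
  }
  meta$node <- nodes
  dependency_tree(meta, edges)
}

tree_score <- function(tree, edge_scores) {
  sum(vapply(seq_len(nrow(tree$edges)), function(k) {
    edge_scores(tree$edges$head[k], tree$edges$dep[k], tree$edges$role[k])
  }, numeric(1)))
}

# Parser features and training -------------------------------------------------

parser_edge_features <- function(tokens, h, d, r) {
  word <- stats::setNames(tokens$text, tokens$index)
  kind <- stats::setNames(tokens$kind, tokens$index)
  dw <- word[[as.character(d)]]
  if (h == ROOT_NODE) {
    keys <- c(sprintf("P|ROOT|dw=%s", dw),
              sprintf("P|ROOT|dcls=%s", word_class(dw)),
              sprintf("P|ROOT|dk=%s", kind[[as.character(d)]]))
  } else {
    hw <- word[[as.character(h)]]
    dir <- if (d > h) "R" else "L"
    keys <- c(sprintf("P|r=%s|hw=%s|dw=%s", r, hw, dw),
              sprintf("P|r=%s|hcls=%s|dcls=%s", r, word_class(hw), word_class(dw)),
              sprintf("P|r=%s|hw=%s|dk=%s", r, hw, kind[[as.character(d)]]),
              sprintf("P|r=%s|dir=%s|dist=%s", r, dir, dist_bin(d - h)),
              sprintf("P|r=%s", r))
  }
  stats::setNames(rep(1, length(keys)), keys)
}

parser_type_features <- function(tokens, i, t) {
  w <- stats::setNames(tokens$text, tokens$index)[[as.character(i)]]
  stats::setNames(rep(1, 3), c(
    sprintf("TY|w=%s|t=%s", w, t),
    sprintf("TY|cls=%s|t=%s", word_class(w), t),
    sprintf("TY|bias|t=%s", t)))
}

edge_scorer <- function(tokens, ws) {
  function(h, d, r) weights_dot(ws, parser_edge_features(tokens, h, d, r))
}

tree_features <- function(tree, tokens) {
  fs <- lapply(seq_len(nrow(tree$edges)), function(k) {
    parser_edge_features(tokens, tree$edges$head[k], tree$edges$dep[k],
                         tree$edges$role[k])
  })
  do.call(feats_sum, c(fs, list(stats::setNames(numeric(0), character(0)))))
}

#' Train the edge-factored event parser
#'
#' Online structured learning with averaged perceptron updates against the
#' chosen decoder: each sentence is decoded with current weights and, when
#' the decoded tree differs from the gold projection, the weights move
#' along the feature difference. A local multiclass scorer for anchor
#' event types is trained alongside (tokens anchoring a gold event get
#' their type; others the `NONE` class).
#'
#' @param corpus Gold corpus with token tables.
#' @param inv A [type_inventory()].
#' @param epochs Training epochs.
#' @param seed Shuffle seed.
#' @param decoder `"1p"` (projective) or `"1n"` (non-projective).
#' @return Object of class `parser_model`.
#' @export
train_parser <- function(corpus, inv = type_inventory("ge"), epochs = 10,
                         seed = 1, decoder = c("1p", "1n")) {
  decoder <- match.arg(decoder)
  if (!length(corpus)) stop_usage("empty training corpus")
  decode <- if (decoder == "1p") decode_projective else decode_nonprojective
  data <- lapply(corpus, function(doc) {
    tokens <- doc$tokens %||% tokens_from_text(doc)
    gold <- project_to_tree(doc, tokens, inv, keep_all = TRUE)
    list(tokens = tokens, gold = gold,
         nodes = sort(gold$nodes$node), meta = gold$nodes)
  })
  ws <- new_weights(); tws <- new_weights()
  types <- c(all_types(inv), "NONE")
  step <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      for (d in sample(seq_along(data))) {
        step <- step + 1L
        item <- data[[d]]
        pred <- decode(item$nodes, edge_scorer(item$tokens, ws), item$meta)
        gk <- with(item$gold$edges, paste(head, dep, role))
        pk <- with(pred$edges, paste(head, dep, role))
        if (!setequal(gk, pk)) {
          dphi <- feats_sum(tree_features(item$gold, item$tokens),
                            feats_scale(tree_features(pred, item$tokens), -1))
          dphi <- dphi[abs(dphi) > 1e-12]
          weights_add(ws, dphi, 1, step)
        }
        # anchor type scorer
        anchors <- item$tokens$index[item$tokens$kind == "CANDIDATE_ANCHOR"]
        gold_type <- stats::setNames(item$gold$nodes$type, item$gold$nodes$node)
        for (i in anchors) {
          gt <- gold_type[as.character(i)]
          gt <- if (is.na(gt)) "NONE" else unname(gt)
          sc <- vapply(types, function(t) {
            weights_dot(tws, parser_type_features(item$tokens, i, t))
          }, numeric(1))
          pt <- types[which.max(sc)]
          if (pt != gt) {
            weights_add(tws, parser_type_features(item$tokens, i, gt), 1, step)
            weights_add(tws, parser_type_features(item$tokens, i, pt), -1, step)
          }
        }
      }
    }
  })
  structure(list(weights = weights_average(ws, max(step, 1L)),
                 type_weights = weights_average(tws, max(step, 1L)),
                 inv = inv, decoder = decoder, epochs = epochs, seed = seed),
            class = "parser_model")
}

#' @export
print.parser_model <- function(x, ...) {
  cat(sprintf("<parser_model: decoder %s, %d edge features>\n",
              toupper(x$decoder), length(ls(x$weights$w))))
  invisible(x)
}

#' Predict events with a trained parser
#'
#' Decodes each document's candidate nodes with the model's decoder,
#' assigns event types to anchors via the local type scorer, and converts
#' the decoded trees back to event documents.
#'
#' @param model A [train_parser()] model.
#' @param corpus Corpus with token tables.
#' @return A list: `corpus` (predicted documents), `trees`, and `stacked`
#'   (per-document `stacked_prediction` views for use as stacking input).
#' @export
predict_parser <- function(model, corpus) {
  decode <- if (model$decoder == "1p") decode_projective else decode_nonprojective
  types <- all_types(model$inv)
  docs <- list(); trees <- list(); stacked <- list()
  for (doc in corpus) {
    tokens <- doc$tokens %||% tokens_from_text(doc)
    nodes <- sort(tokens$index[tokens$kind %in% c("PROTEIN", "CANDIDATE_ANCHOR")])
    meta <- data.frame(node = nodes,
                       kind = stats::setNames(tokens$kind, tokens$index)[as.character(nodes)],
                       type = NA_character_, stringsAsFactors = FALSE)
    tr <- decode(nodes, edge_scorer(tokens, model$weights), meta)
    # type anchors that received THEME children
    for (k in seq_len(nrow(tr$nodes))) {
      if (tr$nodes$kind[k] != "CANDIDATE_ANCHOR") next
      i <- tr$nodes$node[k]
      if (!any(tr$edges$head == i & tr$edges$role == "THEME")) next
      sc <- vapply(types, function(t) {
        weights_dot(model$type_weights, parser_type_features(tokens, i, t))
      }, numeric(1))
      tr$nodes$type[k] <- types[which.max(sc)]
    }
    pdoc <- tree_to_events(tr, tokens, model$inv, doc_id = doc$doc_id,
                           text = doc$text, proteins = doc$proteins)
    pdoc$tokens <- tokens
    docs[[doc$doc_id]] <- pdoc
    trees[[doc$doc_id]] <- tr
    stacked[[doc$doc_id]] <- as_stacked_prediction(
      pdoc, tokens, system = toupper(model$decoder), inv = model$inv)
  }
  list(corpus = structure(docs, class = "event_corpus"), trees = trees,
       stacked = stacked)
}

# Cross-validation stacking protocol -------------------------------------------

#' Cross-validation fold plan
#'
#' Partitions doc ids into `n_folds` folds of near-equal size (differing by
#' at most one) after a seeded shuffle.
#'
#' @param doc_ids Character vector of document ids.
#' @param n_folds Number of folds (>= 2).
#' @param seed Shuffle seed.
#' @return Object of class `fold_plan`: named integer vector doc id -> fold.
#' @export
fold_plan <- function(doc_ids, n_folds, seed = 1) {
  if (n_folds < 2) stop_usage("n_folds must be >= 2")
  if (n_folds > length(doc_ids)) stop_usage("more folds than documents")
  shuffled <- with_seed(seed, sample(doc_ids))
  assignment <- stats::setNames(rep_len(seq_len(n_folds), length(shuffled)),
                                shuffled)
  structure(assignment[doc_ids], class = "fold_plan", n_folds = n_folds,
            seed = seed)
}

#' Cross-validated stacked predictions
#'
#' Produces the stacking input over training data without letting the
#' stacker see unrealistically accurate predictions: each document is
#' predicted by a parser trained on the other folds only, so training-time
#' prediction quality matches what a held-out document would receive.
#'
#' @param corpus Gold corpus.
#' @param n_folds Number of cross-validation folds.
#' @param seed Fold/shuffle seed.
#' @param inv A [type_inventory()].
#' @param decoder `"1p"` or `"1n"`.
#' @param epochs Parser training epochs per fold.
#' @return Named list doc id -> `stacked_prediction`, with attributes
#'   `audit` (data.frame doc_id, fold; every document predicted exactly
#'   once by a model that never saw it) and `corpus` (the prediction
#'   documents).
#' @export
stacked_predictions <- function(corpus, n_folds, seed = 1,
                                inv = type_inventory("ge"),
                                decoder = "1p", epochs = 5) {
  plan <- fold_plan(names(corpus), n_folds, seed)
  if (any(tabulate(plan, n_folds) == 0L)) stop_usage("fold with zero documents")
  preds <- list(); pred_docs <- list()
  audit <- data.frame(doc_id = character(), fold = integer(),
                      trained_on = integer())
  for (f in seq_len(n_folds)) {
    held <- names(plan)[plan == f]
    train_ids <- names(plan)[plan != f]
    model <- train_parser(corpus[train_ids], inv = inv, epochs = epochs,
                          seed = child_seed(seed, f), decoder = decoder)
    out <- predict_parser(model, corpus[held])
    preds[held] <- out$stacked[held]
    pred_docs[held] <- out$corpus[held]
    audit <- rbind(audit, data.frame(doc_id = held, fold = f,
                                     trained_on = length(train_ids)))
  }
  preds <- preds[names(corpus)]
  structure(preds, audit = audit,
            corpus = structure(pred_docs[names(corpus)], class = "event_corpus"))
}

#' Merge a primary and an auxiliary training corpus with replication
#'
#' Domain-adaptation corpus building: the training multiset contains the
#' auxiliary corpus once and the primary corpus `replication` times, with
#' doc ids suffixed per extra copy so ids stay unique.
#'
#' @param primary In-domain corpus (replicated).
#' @param auxiliary Out-of-domain corpus (added once); may be empty.
#' @param replication Number of primary copies (>= 1).
#' @return Combined corpus.
#' @export
merge_corpora <- function(primary, auxiliary = list(), replication = 1) {
  if (replication < 1) stop_usage("replication must be >= 1")
  out <- list()
  for (k in seq_len(replication)) {
    for (doc in primary) {
      d <- doc
      if (k > 1) d$doc_id <- sprintf("%s#%d", doc$doc_id, k)
      out[[d$doc_id]] <- d
    }
  }
  for (doc in auxiliary) {
    d <- doc
    if (!is.null(out[[d$doc_id]])) d$doc_id <- paste0(d$doc_id, "#aux")
    out[[d$doc_id]] <- d
  }
  structure(out, class = "event_corpus")
}
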