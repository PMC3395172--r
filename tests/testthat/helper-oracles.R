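# Independent brute-force oracles and small fixture builders shared by the
# test files. Oracles deliberately re-derive results by exhaustive
# enumeration rather than reusing the package's decoding logic.

small_inventory <- function() {
  type_inventory("custom",
                 simple_types = "Phosphorylation",
                 binding_types = "Binding",
                 regulation_types = "Regulation",
                 cause_licensed_types = "Regulation")
}

# Token table with the given kinds in order (one word per token).
make_tokens <- function(kinds, words = NULL) {
  n <- length(kinds)
  words <- words %||% sprintf("tok%d", seq_len(n))
  ends <- cumsum(nchar(words) + 1L) - 1L
  data.frame(index = seq_len(n) - 1L, start = ends - nchar(words), end = ends,
             text = words, kind = kinds, head = 1L, sentence = 1L,
             stringsAsFactors = FALSE)
}

# Random joint instance: kinds shuffled, random local scores per variable.
random_joint_instance <- function(n_anchors, n_prots, inv = small_inventory()) {
  kinds <- sample(c(rep("CANDIDATE_ANCHOR", n_anchors),
                    rep("PROTEIN", n_prots),
                    rep("OTHER", sample(0:2, 1))))
  instance <- eventstack:::build_instance(make_tokens(kinds), inv)
  sc <- list(e = stats::rnorm(nrow(instance$e_idx)),
             a = stats::rnorm(nrow(instance$a_idx)),
             b = stats::rnorm(max(nrow(instance$b_idx), 0)))
  list(instance = instance, sc = sc)
}

# Exhaustive maximum of s(e, a, b) over the constraint set: enumerates
# label assignments, per-anchor THEME target subsets (cross product over
# active anchors), slaves CAUSE edges (independent given labels) and pair
# variables (active iff positive-scoring and witnessed).
brute_force_joint <- function(instance, sc) {
  inv <- instance$inv
  anchors <- instance$anchors
  types <- instance$types
  label_opts <- c(list(NA_character_), as.list(types))
  grids <- do.call(expand.grid,
                   c(rep(list(seq_along(label_opts)), length(anchors)),
                     list(stringsAsFactors = FALSE)))
  best <- 0  # empty assignment is always feasible with score 0
  e_key <- paste(instance$e_idx$i, instance$e_idx$t)
  a_df <- instance$a_idx
  for (g in seq_len(nrow(grids))) {
    labs <- vapply(seq_along(anchors), function(k) {
      label_opts[[grids[g, k]]]
    }, character(1))
    active <- which(!is.na(labs))
    if (!length(active)) next
    labeled_set <- anchors[active]
    e_score <- sum(sc$e[match(paste(anchors[active], labs[active]), e_key)])

    # CAUSE edges: independent given labels
    cause_score <- 0
    ok <- TRUE
    theme_slots <- vector("list", length(active))
    for (ai in seq_along(active)) {
      i <- anchors[active[ai]]
      t <- labs[active[ai]]
      allowed <- c(instance$prots, setdiff(labeled_set, i))
      if (t %in% inv$cause_licensed_types) {
        cs <- which(a_df$i == i & a_df$r == "CAUSE" & a_df$j %in% allowed)
        cause_score <- cause_score + sum(pmax(sc$a[cs], 0))
      }
      th <- which(a_df$i == i & a_df$r == "THEME" & a_df$j %in% allowed)
      if (!length(th)) { ok <- FALSE; break }
      theme_slots[[ai]] <- th
    }
    if (!ok) next

    # nonempty THEME subsets per active anchor, as score vectors
    subset_scores <- list(); subset_targets <- list()
    for (ai in seq_along(active)) {
      th <- theme_slots[[ai]]
      m <- length(th)
      masks <- seq_len(2^m - 1)
      ssc <- vapply(masks, function(mask) {
        sum(sc$a[th[bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L]])
      }, numeric(1))
      tgt <- lapply(masks, function(mask) {
        a_df$j[th[bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L]]
      })
      subset_scores[[ai]] <- ssc
      subset_targets[[ai]] <- tgt
    }
    # cross product over active anchors
    lens <- vapply(subset_scores, length, integer(1))
    idx_grid <- do.call(expand.grid, lapply(lens, seq_len))
    total <- rep(e_score + cause_score, nrow(idx_grid))
    for (ai in seq_along(active)) {
      total <- total + subset_scores[[ai]][idx_grid[[ai]]]
    }
    # binding pair bonuses: positive-scoring witnessed pairs
    if (nrow(instance$b_idx)) {
      bind_active <- which(labs[active] %in% inv$binding_types)
      for (bk in which(sc$b > 0)) {
        p <- instance$b_idx$p[bk]; q <- instance$b_idx$q[bk]
        if (!length(bind_active)) break
        witnessed <- rep(FALSE, nrow(idx_grid))
        for (ai in bind_active) {
          has_pq <- vapply(subset_targets[[ai]], function(tg) {
            p %in% tg && q %in% tg
          }, logical(1))
          witnessed <- witnessed | has_pq[idx_grid[[ai]]]
        }
        total <- total + sc$b[bk] * as.numeric(witnessed)
      }
    }
    best <- max(best, max(total))
  }
  best
}

# Brute-force checker for the four joint constraints, by direct
# quantification over the graph (independent of check_constraints).
brute_force_constraint_check <- function(g, inv) {
  ok1 <- all(vapply(g$labels$index, function(i) {
    any(g$edges$src == i & g$edges$role == "THEME")
  }, logical(1)))
  lab <- stats::setNames(g$labels$type, g$labels$index)
  ce <- g$edges[g$edges$role == "CAUSE", , drop = FALSE]
  ok2 <- all(vapply(seq_len(nrow(ce)), function(k) {
    t <- lab[as.character(ce$src[k])]
    !is.na(t) && t %in% inv$cause_licensed_types
  }, logical(1)))
  kind <- stats::setNames(g$tokens$kind, g$tokens$index)
  anchor_targets <- g$edges$dst[kind[as.character(g$edges$dst)] == "CANDIDATE_ANCHOR"]
  ok3 <- all(anchor_targets %in% g$labels$index)
  ok4 <- all(vapply(seq_len(nrow(g$binding_pairs)), function(k) {
    p <- g$binding_pairs$p[k]; q <- g$binding_pairs$q[k]
    any(vapply(g$labels$index[g$labels$type %in% inv$binding_types],
               function(i) {
      th <- g$edges$dst[g$edges$src == i & g$edges$role == "THEME"]
      p %in% th && q %in% th
    }, logical(1)))
  }, logical(1)))
  ok1 && ok2 && ok3 && ok4
}

# Brute-force event matcher: exhaustive bijection over argument
# permutations, written independently of match_args_bijection.
brute_force_events_match <- function(pred, gold, pred_doc, gold_doc, policy) {
  pidx <- eventstack:::doc_index(pred_doc)
  gidx <- eventstack:::doc_index(gold_doc)
  rec <- function(pe, ge, nested) {
    if (pe$type != ge$type) return(FALSE)
    pt <- pidx$trig[[pe$trigger]]; gt <- gidx$trig[[ge$trigger]]
    if (!eventstack:::spans_match(pt$start, pt$end, gt$start, gt$end,
                                  policy$span_slack, gold_doc$text)) {
      return(FALSE)
    }
    pa <- pe$args; ga <- ge$args
    if (nested && policy$recursive_mode == "approximate") {
      pa <- pa[pa$role == "THEME", , drop = FALSE]
      ga <- ga[ga$role == "THEME", , drop = FALSE]
    }
    n <- nrow(pa)
    if (n != nrow(ga)) return(FALSE)
    if (n == 0) return(TRUE)
    perms <- all_permutations(n)
    for (r in seq_len(nrow(perms))) {
      perm <- perms[r, ]
      ok <- TRUE
      for (k in seq_len(n)) {
        pt_ <- pa$target[k]; gt_ <- ga$target[perm[k]]
        if (pa$role[k] != ga$role[perm[k]]) { ok <- FALSE; break }
        p_prot <- pt_ %in% names(pidx$prot)
        g_prot <- gt_ %in% names(gidx$prot)
        if (p_prot != g_prot) { ok <- FALSE; break }
        if (p_prot) {
          pp <- pidx$prot[[pt_]]; gp <- gidx$prot[[gt_]]
          if (!(pp$start == gp$start && pp$end == gp$end)) { ok <- FALSE; break }
        } else if (!rec(pidx$ev[[pt_]], gidx$ev[[gt_]], TRUE)) {
          ok <- FALSE; break
        }
      }
      if (ok) return(TRUE)
    }
    FALSE
  }
  rec(pred, gold, FALSE)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Exhaustive one-to-one matching maximum (maximum bipartite matching via
# augmenting paths) for comparison with the greedy corpus scorer.
max_matching_count <- function(pred_doc, gold_doc, policy) {
  pidx <- eventstack:::doc_index(pred_doc)
  gidx <- eventstack:::doc_index(gold_doc)
  np <- length(pidx$ev); ng <- length(gidx$ev)
  if (np == 0 || ng == 0) return(0L)
  adj <- matrix(FALSE, np, ng)
  for (i in seq_len(np)) for (j in seq_len(ng)) {
    adj[i, j] <- eventstack:::match_event_rec(pidx$ev[[i]], gidx$ev[[j]],
                                              pidx, gidx, policy,
                                              gold_doc$text, nested = FALSE)
  }
  match_g <- rep(0L, ng)
  try_kuhn <- function(i, visited) {
    for (j in which(adj[i, ])) {
      if (visited[j]) next
      visited[j] <- TRUE
      if (match_g[j] == 0L || try_kuhn(match_g[j], visited)) {
        match_g[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  count <- 0L
  for (i in seq_len(np)) {
    if (try_kuhn(i, logical(ng))) count <- count + 1L
  }
  count
}

# Brute-force maximum-score tree search used against both decoders:
# enumerates every head vector (vectorized over assignments), keeps
# arborescences (optionally only non-crossing ones, counting virtual-root
# arcs drawn from the left), and maximizes the summed best-role edge
# scores.
brute_force_tree <- function(nodes, scorer, projective = FALSE) {
  n <- length(nodes)
  # positions: 0 = root (leftmost), 1..n = nodes in order
  M <- matrix(-Inf, n + 1, n)  # [head position + 1, dep position]
  for (d in seq_len(n)) {
    M[1, d] <- scorer(-1L, nodes[d], "ROOT")
    for (h in seq_len(n)) {
      if (h == d) next
      M[h + 1, d] <- max(scorer(nodes[h], nodes[d], "THEME"),
                         scorer(nodes[h], nodes[d], "CAUSE"))
    }
  }
  H <- as.matrix(do.call(expand.grid, lapply(seq_len(n), function(d) {
    c(0L, setdiff(seq_len(n), d))
  })))
  R <- nrow(H)
  # arborescence check: iterating the head map n times must reach the root
  cur <- H
  for (step in seq_len(n)) {
    idx <- cur > 0L
    cur[idx] <- H[cbind(row(cur)[idx], cur[idx])]
  }
  ok <- rowSums(cur) == 0L
  if (projective && n >= 2) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        lo_i <- pmin(H[, i], i); hi_i <- pmax(H[, i], i)
        lo_j <- pmin(H[, j], j); hi_j <- pmax(H[, j], j)
        cross <- (lo_i < lo_j & lo_j < hi_i & hi_i < hi_j) |
                 (lo_j < lo_i & lo_i < hi_j & hi_j < hi_i)
        ok <- ok & !cross
      }
    }
  }
  score <- rowSums(matrix(M[cbind(as.vector(H) + 1L,
                                  rep(seq_len(n), each = R))], R, n))
  max(score[ok])
}

# Deterministic random edge scorer over a fixed node set.
random_edge_scorer <- function(nodes) {
  tab <- new.env(parent = emptyenv())
  for (h in c(-1L, nodes)) {
    for (d in nodes) {
      for (r in c("ROOT", "THEME", "CAUSE")) {
        tab[[paste(h, d, r)]] <- stats::rnorm(1)
      }
    }
  }
  function(h, d, r) tab[[paste(h, d, r)]] %||% -Inf
}

# Add one deliberately wrong event anchored at a decoy token: it matches
# nothing in the gold standard and (absent from both base outputs) will be
# classified NOVEL.
plant_novel_events <- function(doc) {
  decoy <- doc$tokens[doc$tokens$kind == "CANDIDATE_ANCHOR" &
                      !(doc$tokens$start %in% doc$triggers$start), , drop = FALSE]
  if (!nrow(decoy) || !nrow(doc$proteins)) return(doc)
  trig <- data.frame(id = "TNOV", type = "Gene_expression",
                     start = decoy$start[1], end = decoy$end[1],
                     text = decoy$text[1], stringsAsFactors = FALSE)
  ev <- list(id = "ENOV", type = "Gene_expression", trigger = "TNOV",
             args = data.frame(role = "THEME", target = doc$proteins$id[1]))
  event_document(doc$doc_id, doc$text, doc$proteins,
                 rbind(doc$triggers, trig), c(doc$events, list(ev)),
                 doc$extra, doc$tokens)
}

# The running example document: a phosphorylation inhibiting a binding.
fig_example_doc <- function() {
  txt <- "the phosphorylation of TRAF2 inhibits binding to the CD40 domain"
  a1 <- "T1\tProtein 23 28\tTRAF2\nT2\tProtein 53 57\tCD40\n"
  a2 <- paste0("T3\tPhosphorylation 4 19\tphosphorylation\n",
               "T4\tRegulation 29 37\tinhibits\n",
               "T5\tBinding 38 45\tbinding\n",
               "E1\tPhosphorylation:T3 Theme:T1\n",
               "E3\tBinding:T5 Theme:T1 Theme2:T2\n",
               "E2\tRegulation:T4 Theme:E3 Cause:E1\n")
  read_standoff("fig1", txt, a1, a2)
}
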