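# The joint extractor ("stacker"): binary anchor-label variables e_(i,t),
# argument variables a_(i,j,r) and Binding-pair variables b_(p,q), scored by
# sparse linear functions and decoded under four structural constraints via
# dual decomposition. Learning is 1-best MIRA with weight averaging.

#' Joint-assignment constructor
#'
#' The joint model's variable view of one sentence: active anchor labels
#' `e` (token index, type), argument arcs `a` (source, target, role) and
#' Binding pairs `b` (protein token pairs).
#'
#' @param e data.frame with columns `i`, `t`.
#' @param a data.frame with columns `i`, `j`, `r`.
#' @param b data.frame with columns `p`, `q`.
#' @return Object of class `joint_assignment`.
#' @export
joint_assignment <- function(e = NULL, a = NULL, b = NULL) {
  e <- e %||% data.frame(i = integer(), t = character())
  a <- a %||% data.frame(i = integer(), j = integer(), r = character())
  b <- b %||% data.frame(p = integer(), q = integer())
  e <- e[order(e$i, e$t), , drop = FALSE]
  a <- a[order(a$i, a$j, a$r), , drop = FALSE]
  if (nrow(b)) {
    swap <- b$p > b$q
    tmp <- b$p[swap]; b$p[swap] <- b$q[swap]; b$q[swap] <- tmp
    b <- b[order(b$p, b$q), , drop = FALSE]
  }
  rownames(e) <- rownames(a) <- rownames(b) <- NULL
  structure(list(e = e, a = a, b = b), class = "joint_assignment")
}

assignment_keys <- function(y) {
  c(sprintf("e|%d|%s", y$e$i, y$e$t),
    sprintf("a|%d|%d|%s", y$a$i, y$a$j, y$a$r),
    sprintf("b|%d|%d", y$b$p, y$b$q))
}

# Hamming loss over the three variable sets.
assignment_hamming <- function(y1, y2) {
  k1 <- assignment_keys(y1); k2 <- assignment_keys(y2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

assignment_to_graph <- function(y, tokens) {
  token_graph(tokens,
              labels = data.frame(index = y$e$i, type = y$e$t),
              edges = data.frame(src = y$a$i, dst = y$a$j, role = y$a$r),
              binding_pairs = y$b)
}

assignment_from_graph <- function(g) {
  joint_assignment(
    e = data.frame(i = g$labels$index, t = g$labels$type),
    a = data.frame(i = g$edges$src, j = g$edges$dst, r = g$edges$role),
    b = g$binding_pairs)
}

# Feature templates -----------------------------------------------------------

word_class <- function(w) gsub("[0-9]+", "", w)
dist_bin <- function(d) {
  d <- abs(d)
  if (d <= 1) "1" else if (d == 2) "2" else if (d <= 4) "3-4" else "5+"
}

#' Stacking feature indicators for an anchor-label variable
#'
#' For every stacked system `S` and candidate label `t`, emits the
#' indicator keyed by the pair (candidate label, `S`'s predicted label at
#' the token), with `NONE` encoding that `S` predicts no anchor there.
#' These features let the learner weight every (proposed, predicted) type
#' combination separately.
#'
#' @param preds List of `stacked_prediction` objects.
#' @param i Token index.
#' @param t Candidate event type.
#' @return Named numeric vector of indicator features.
#' @export
stacking_features <- function(preds, i, t) {
  keys <- vapply(preds, function(p) {
    hs <- p$h[as.character(i)]
    sprintf("ST|S=%s|t=%s|hS=%s", p$system, t,
            if (is.na(hs)) "NONE" else hs)
  }, character(1))
  stats::setNames(rep(1, length(keys)), keys)
}

# Arc-level stacking indicators: predicted role of (i, j) per system.
stacking_arc_features <- function(preds, i, j, r) {
  keys <- vapply(preds, function(p) {
    hit <- p$arcs$role[p$arcs$src == i & p$arcs$dst == j]
    sprintf("SR|S=%s|r=%s|rS=%s", p$system, r,
            if (length(hit)) hit[1] else "NONE")
  }, character(1))
  stats::setNames(rep(1, length(keys)), keys)
}

#' Conjoin base features with a stacked system's prediction
#'
#' Duplicates every base feature key with a suffix recording the stacked
#' system's predicted label at the token, so the learner can weight base
#' features differently in different stacked-prediction contexts.
#'
#' @param base Named numeric feature vector.
#' @param pred A `stacked_prediction`.
#' @param i Token index.
#' @param retain Keep the original keys alongside the conjoined ones.
#' @return Named numeric feature vector.
#' @export
conjoin_features <- function(base, pred, i, retain = TRUE) {
  if (length(base) == 0L) return(base)
  hs <- pred$h[as.character(i)]
  hs <- if (is.na(hs)) "NONE" else hs
  conj <- stats::setNames(unname(base),
                          sprintf("%s^S=%s,hS=%s", names(base), pred$system, hs))
  if (retain) c(base, conj) else conj
}

default_feature_opts <- function() {
  list(use_anchors = TRUE, use_arguments = TRUE, conjoin = FALSE,
       conjoin_retain = TRUE)
}

# Build the static per-variable feature lists for one sentence.
build_instance <- function(tokens, inv, stacked = list(),
                           opts = default_feature_opts()) {
  anchors <- tokens$index[tokens$kind == "CANDIDATE_ANCHOR"]
  prots <- tokens$index[tokens$kind == "PROTEIN"]
  types <- all_types(inv)
  word <- stats::setNames(tokens$text, tokens$index)
  kind <- stats::setNames(tokens$kind, tokens$index)

  e_idx <- expand.grid(i = anchors, t = types, stringsAsFactors = FALSE)
  e_idx <- e_idx[order(e_idx$i, e_idx$t), , drop = FALSE]
  eF <- lapply(seq_len(nrow(e_idx)), function(k) {
    i <- e_idx$i[k]; t <- e_idx$t[k]
    w <- word[[as.character(i)]]
    base <- stats::setNames(rep(1, 3), c(
      sprintf("T|w=%s|t=%s", w, t),
      sprintf("T|cls=%s|t=%s", word_class(w), t),
      sprintf("T|bias|t=%s", t)))
    f <- base
    if (length(stacked) && opts$use_anchors) {
      f <- c(f, stacking_features(stacked, i, t))
    }
    if (length(stacked) && opts$conjoin) {
      for (p in stacked) f <- conjoin_features(f, p, i, opts$conjoin_retain)
    }
    f
  })

  a_rows <- list()
  for (i in anchors) {
    for (j in c(prots, setdiff(anchors, i))) {
      for (r in c("THEME", "CAUSE")) {
        a_rows[[length(a_rows) + 1L]] <- data.frame(i = i, j = j, r = r)
      }
    }
  }
  a_idx <- do.call(rbind, a_rows) %||% data.frame(i = integer(), j = integer(),
                                                  r = character())
  aF <- lapply(seq_len(nrow(a_idx)), function(k) {
    i <- a_idx$i[k]; j <- a_idx$j[k]; r <- a_idx$r[k]
    sw <- word[[as.character(i)]]; dw <- word[[as.character(j)]]
    dk <- if (kind[[as.character(j)]] == "PROTEIN") "PROT" else "ANCH"
    dir <- if (j > i) "R" else "L"
    f <- stats::setNames(rep(1, 4), c(
      sprintf("R|r=%s|sw=%s|dk=%s", r, sw, dk),
      sprintf("R|r=%s|scls=%s|dcls=%s", r, word_class(sw), word_class(dw)),
      sprintf("R|r=%s|dir=%s|dist=%s", r, dir, dist_bin(j - i)),
      sprintf("R|r=%s|dk=%s", r, dk)))
    if (length(stacked) && opts$use_arguments) {
      f <- c(f, stacking_arc_features(stacked, i, j, r))
    }
    f
  })

  b_idx <- if (length(prots) >= 2L) {
    cmb <- utils::combn(sort(prots), 2L)
    data.frame(p = cmb[1, ], q = cmb[2, ])
  } else data.frame(p = integer(), q = integer())
  bF <- lapply(seq_len(nrow(b_idx)), function(k) {
    p <- b_idx$p[k]; q <- b_idx$q[k]
    stats::setNames(rep(1, 2), c(
      "B|bias", sprintf("B|dist=%s", dist_bin(q - p))))
  })

  list(tokens = tokens, inv = inv, anchors = anchors, prots = prots,
       types = types, e_idx = e_idx, a_idx = a_idx, b_idx = b_idx,
       eF = eF, aF = aF, bF = bF)
}

instance_scores <- function(instance, ws) {
  list(e = vapply(instance$eF, function(f) weights_dot(ws, f), numeric(1)),
       a = vapply(instance$aF, function(f) weights_dot(ws, f), numeric(1)),
       b = vapply(instance$bF, function(f) weights_dot(ws, f), numeric(1)))
}

#' Score a joint assignment
#'
#' The sum of the local scores of the active variables only:
#' `s(e, a, b) = sum s_T(i, t) + sum s_R(i, j, r) + sum s_B(p, q)`,
#' each local score the dot product of a sparse feature vector with the
#' corresponding weight block.
#'
#' @param y A [joint_assignment()].
#' @param instance Internal instance built from a sentence (token table).
#' @param ws Weights.
#' @return A single number.
#' @export
score_assignment <- function(y, instance, ws) {
  sc <- instance_scores(instance, ws)
  score_assignment_cached(y, instance, sc)
}

score_assignment_cached <- function(y, instance, sc) {
  total <- 0
  if (nrow(y$e)) {
    ek <- paste(instance$e_idx$i, instance$e_idx$t)
    total <- total + sum(sc$e[match(paste(y$e$i, y$e$t), ek)])
  }
  if (nrow(y$a)) {
    ak <- paste(instance$a_idx$i, instance$a_idx$j, instance$a_idx$r)
    total <- total + sum(sc$a[match(paste(y$a$i, y$a$j, y$a$r), ak)])
  }
  if (nrow(y$b)) {
    bk <- paste(instance$b_idx$p, instance$b_idx$q)
    total <- total + sum(sc$b[match(paste(y$b$p, y$b$q), bk)])
  }
  total
}

# Feature vector of an assignment (sum of active-variable features).
assignment_features <- function(y, instance) {
  ek <- paste(instance$e_idx$i, instance$e_idx$t)
  ak <- paste(instance$a_idx$i, instance$a_idx$j, instance$a_idx$r)
  bk <- paste(instance$b_idx$p, instance$b_idx$q)
  fs <- c(instance$eF[match(paste(y$e$i, y$e$t), ek)],
          instance$aF[match(paste(y$a$i, y$a$j, y$a$r), ak)],
          instance$bF[match(paste(y$b$p, y$b$q), bk)])
  do.call(feats_sum, c(fs, list(stats::setNames(numeric(0), character(0)))))
}

# Dual decomposition ----------------------------------------------------------

#' Joint inference by dual decomposition
#'
#' Maximizes the joint score over the constraint set by splitting the
#' problem into three subproblems — (1) best label and outgoing edges per
#' candidate anchor, (2) best label and incoming edges per token, (3) best
#' Binding pairs — coordinated by subgradient updates on the multipliers
#' tying the copies together. The anchor/argument variables are duplicated
#' between subproblems (1) and (2); the Binding witnessing constraint links
#' subproblem (3) to subproblem (1) through nonnegative multipliers. Every
#' iteration a constraint-repaired primal candidate is extracted from the
#' outgoing solution; when the best primal score meets the dual bound the
#' result is certified `OPTIMAL`, otherwise the best primal candidate seen
#' is returned with certificate `HEURISTIC`.
#'
#' @param instance Instance built from one sentence.
#' @param ws Weights.
#' @param max_iter Maximum subgradient iterations.
#' @param eta0 Initial step size; the step decays as
#'   `eta0 / (1 + number of dual increases so far)`.
#' @param scores Optional precomputed local scores (list `e`, `a`, `b`),
#'   overriding `ws`; used when decoding fixed score vectors.
#' @return A list: `assignment` (a [joint_assignment()] satisfying all
#'   constraints), `score` (its primal score), `certificate` (`"OPTIMAL"` or
#'   `"HEURISTIC"`), `dual_bound`, `iterations`, `dual_trace`.
#' @export
infer_dd <- function(instance, ws = NULL, max_iter = 100, eta0 = 1.0,
                     scores = NULL) {
  sc <- scores %||% instance_scores(instance, ws)
  nE <- nrow(instance$e_idx); nA <- nrow(instance$a_idx); nB <- nrow(instance$b_idx)
  lamE <- numeric(nE); lamA <- numeric(nA); muB <- numeric(nB)

  best_primal <- -Inf; best_y <- NULL
  best_dual <- Inf; n_incr <- 0; prev_dual <- Inf
  dual_trace <- numeric(0)

  for (iter in seq_len(max_iter)) {
    out <- solve_outgoing(instance, sc, lamE, lamA, muB)
    inc <- solve_incoming(instance, sc, lamE, lamA)
    bB <- sc$b - muB > 1e-12  # subproblem (3)
    dual <- out$value + inc$value + sum((sc$b - muB)[bB])
    dual_trace <- c(dual_trace, dual)
    if (dual < best_dual - 1e-12) best_dual <- dual
    if (is.finite(prev_dual) && dual > prev_dual + 1e-12) n_incr <- n_incr + 1
    prev_dual <- dual

    # primal candidate: repair the outgoing solution
    y <- repair_assignment(instance, sc, out)
    p <- score_assignment_cached(y, instance, sc)
    if (p > best_primal + 1e-12) { best_primal <- p; best_y <- y }

    if (best_dual - best_primal <= 1e-9) {
      return(list(assignment = best_y, score = best_primal,
                  certificate = "OPTIMAL", dual_bound = best_dual,
                  iterations = iter, dual_trace = dual_trace))
    }
    eta <- eta0 / (1 + n_incr)
    lamE <- lamE - eta * (out$e_active - inc$e_active)
    lamA <- lamA - eta * (out$a_active - inc$a_active)
    if (nB) muB <- pmax(0, muB - eta * (out$witness - as.numeric(bB)))
  }
  list(assignment = best_y, score = best_primal, certificate = "HEURISTIC",
       dual_bound = best_dual, iterations = max_iter, dual_trace = dual_trace)
}

# Subproblem (1): per candidate anchor, best label + outgoing edge set under
# constraints (1) and (2), with Binding-pair witness bonuses mu. Owns half
# of s_T and s_R plus +lambda.
solve_outgoing <- function(instance, sc, lamE, lamA, muB) {
  eS <- sc$e / 2 + lamE
  aS <- sc$a / 2 + lamA
  e_active <- numeric(length(eS)); a_active <- numeric(length(aS))
  witness <- numeric(nrow(instance$b_idx))
  total <- 0
  inv <- instance$inv
  for (i in instance$anchors) {
    slots_e <- which(instance$e_idx$i == i)
    slots_a <- which(instance$a_idx$i == i)
    best_val <- 0; best <- NULL  # label-inactive option
    for (k in slots_e) {
      t <- instance$e_idx$t[k]
      cfg <- best_outgoing_config(instance, aS, slots_a, t, muB)
      val <- eS[k] + cfg$value
      if (val > best_val + 1e-12) { best_val <- val; best <- list(k = k, cfg = cfg) }
    }
    total <- total + best_val
    if (!is.null(best)) {
      e_active[best$k] <- 1
      a_active[best$cfg$slots] <- 1
      witness[best$cfg$witness] <- 1
      }
  }
  list(value = total, e_active = e_active, a_active = a_active,
       witness = witness)
}

# Best outgoing edge set for anchor slots `slots_a` under label t:
# positive-scoring edges, at least one THEME (forced if necessary), CAUSE
# only when licensed, and exact protein-subset search for Binding labels so
# pair bonuses can pull in negative edges.
best_outgoing_config <- function(instance, aS, slots_a, t, muB) {
  inv <- instance$inv
  idx <- instance$a_idx[slots_a, , drop = FALSE]
  th <- slots_a[idx$r == "THEME"]
  ca <- slots_a[idx$r == "CAUSE"]
  chosen <- integer(0); value <- 0; wit <- integer(0)

  if (t %in% inv$cause_licensed_types && length(ca)) {
    pos <- ca[aS[ca] > 1e-12]
    chosen <- c(chosen, pos); value <- value + sum(aS[pos])
  }
  if (t %in% inv$binding_types && nrow(instance$b_idx) &&
      length(instance$prots) <= 14) {
    pth <- th[instance$a_idx$j[th] %in% instance$prots]
    oth <- setdiff(th, pth)
    pos_o <- oth[aS[oth] > 1e-12]
    sub <- best_pair_subset(instance, aS, pth, muB)
    chosen <- c(chosen, pos_o, sub$slots)
    value <- value + sum(aS[pos_o]) + sub$value
    wit <- sub$witness
  } else {
    pos_t <- th[aS[th] > 1e-12]
    chosen <- c(chosen, pos_t); value <- value + sum(aS[pos_t])
  }
  if (!any(chosen %in% th)) {  # constraint (1): force best THEME
    if (!length(th)) return(list(value = -Inf, slots = integer(0),
                                 witness = integer(0)))
    k <- th[which.max(aS[th])]
    chosen <- c(chosen, k); value <- value + aS[k]
  }
  list(value = value, slots = chosen, witness = wit)
}

# Exact search over protein-THEME subsets of one Binding anchor, scoring
# edge weights plus the mu bonus of every pair inside the subset.
best_pair_subset <- function(instance, aS, pth, muB) {
  if (!length(pth)) return(list(value = 0, slots = integer(0), witness = integer(0)))
  prots <- instance$a_idx$j[pth]
  n <- length(pth)
  pair_bonus <- matrix(0, n, n)
  pair_slot <- matrix(NA_integer_, n, n)
  if (nrow(instance$b_idx)) {
    for (u in seq_len(n - 1)) {
      for (v in (u + 1):n) {
        p <- min(prots[u], prots[v]); q <- max(prots[u], prots[v])
        s <- which(instance$b_idx$p == p & instance$b_idx$q == q)
        if (length(s)) { pair_bonus[u, v] <- muB[s]; pair_slot[u, v] <- s }
      }
    }
  }
  best_val <- 0; best_set <- integer(0)
  for (mask in seq_len(2^n) - 1L) {
    members <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    val <- sum(aS[pth[members]])
    if (length(members) >= 2) {
      for (u in members) for (v in members) if (u < v) val <- val + pair_bonus[u, v]
    }
    if (val > best_val + 1e-12) { best_val <- val; best_set <- members }
  }
  wit <- integer(0)
  if (length(best_set) >= 2) {
    for (u in best_set) for (v in best_set) {
      if (u < v && !is.na(pair_slot[u, v])) wit <- c(wit, pair_slot[u, v])
    }
  }
  list(value = best_val, slots = pth[best_set], witness = wit)
}

# Subproblem (2): per token, best label + incoming edge set under
# constraint (3). Owns the other half of s_T and s_R, minus lambda.
solve_incoming <- function(instance, sc, lamE, lamA) {
  eS <- sc$e / 2 - lamE
  aS <- sc$a / 2 - lamA
  e_active <- numeric(length(eS)); a_active <- numeric(length(aS))
  total <- 0
  all_targets <- unique(instance$a_idx$j)
  for (j in all_targets) {
    slots_in <- which(instance$a_idx$j == j)
    pos <- slots_in[aS[slots_in] > 1e-12]
    pos_val <- sum(aS[pos])
    if (j %in% instance$anchors) {
      slots_e <- which(instance$e_idx$i == j)
      k <- slots_e[which.max(eS[slots_e])]
      lab_val <- eS[k] + pos_val
      if (lab_val > 1e-12) {
        total <- total + lab_val
        e_active[k] <- 1
        a_active[pos] <- 1
      }  # else: unlabeled, no incoming edges (constraint 3)
    } else {
      total <- total + pos_val
      a_active[pos] <- 1
    }
  }
  # anchors that are never edge targets can still carry a positive label
  for (j in setdiff(instance$anchors, all_targets)) {
    slots_e <- which(instance$e_idx$i == j)
    k <- slots_e[which.max(eS[slots_e])]
    if (eS[k] > 1e-12) { total <- total + eS[k]; e_active[k] <- 1 }
  }
  list(value = total, e_active = e_active, a_active = a_active)
}

# Turn the outgoing solution into a feasible assignment: drop edges into
# unlabeled anchors, re-force THEMEs, slave the pair variables to the
# witnessed pairs with positive score.
repair_assignment <- function(instance, sc, out) {
  e <- instance$e_idx[out$e_active > 0, , drop = FALSE]
  a <- instance$a_idx[out$a_active > 0, , drop = FALSE]
  labeled <- e$i
  keep <- a$j %in% c(instance$prots, labeled)
  a <- a[keep, , drop = FALSE]
  # re-establish constraint (1) after dropping
  keep_e <- rep(TRUE, nrow(e))
  for (k in seq_len(nrow(e))) {
    i <- e$i[k]
    if (any(a$i == i & a$r == "THEME")) next
    cand <- which(instance$a_idx$i == i & instance$a_idx$r == "THEME" &
                  instance$a_idx$j %in% c(instance$prots, setdiff(labeled, i)))
    if (!length(cand)) {
      keep_e[k] <- FALSE
      a <- a[a$i != i, , drop = FALSE]
    } else {
      s <- cand[which.max(sc$a[cand])]
      a <- rbind(a, instance$a_idx[s, , drop = FALSE])
    }
  }
  e <- e[keep_e, , drop = FALSE]
  # a second pass in case a dropped label invalidated edges into it
  if (!all(keep_e)) {
    labeled <- e$i
    a <- a[a$j %in% c(instance$prots, labeled), , drop = FALSE]
  }
  b <- slave_pairs(instance, sc, e, a)
  joint_assignment(e, a, b)
}

# b_(p,q) active iff positive-scoring and witnessed by a Binding anchor
# with THEME edges to both endpoints.
slave_pairs <- function(instance, sc, e, a) {
  if (!nrow(instance$b_idx)) return(NULL)
  inv <- instance$inv
  bind_anchors <- e$i[e$t %in% inv$binding_types]
  active <- logical(nrow(instance$b_idx))
  for (k in which(sc$b > 1e-12)) {
    p <- instance$b_idx$p[k]; q <- instance$b_idx$q[k]
    active[k] <- any(vapply(bind_anchors, function(i) {
      th <- a$j[a$i == i & a$r == "THEME"]
      p %in% th && q %in% th
    }, logical(1)))
  }
  instance$b_idx[active, , drop = FALSE]
}

# MIRA ------------------------------------------------------------------------

#' One MIRA update
#'
#' If the gold assignment already beats the prediction by the Hamming loss,
#' the weights are unchanged; otherwise the weights move along the feature
#' difference by `tau = min(C, (loss - margin) / ||dphi||^2)`, the minimal
#' change enforcing the loss-scaled margin for this single constraint.
#'
#' @param ws Weights (modified in place).
#' @param gold,pred [joint_assignment()]s; `pred` should be the current
#'   argmax.
#' @param instance The sentence instance.
#' @param C Aggressiveness cap.
#' @param step Online step counter (for weight averaging).
#' @return The applied `tau` (0 when no update), invisibly in `ws`.
#' @export
mira_update <- function(ws, gold, pred, instance, C = 0.1, step = 1) {
  loss <- assignment_hamming(gold, pred)
  if (loss == 0) return(0)
  sc <- instance_scores(instance, ws)
  margin <- score_assignment_cached(gold, instance, sc) -
    score_assignment_cached(pred, instance, sc)
  if (margin >= loss) return(0)
  dphi <- feats_sum(assignment_features(gold, instance),
                    feats_scale(assignment_features(pred, instance), -1))
  dphi <- dphi[abs(dphi) > 1e-12]
  nrm2 <- sum(dphi^2)
  if (nrm2 == 0) {
    warning("MIRA: zero feature difference with positive loss; skipping update")
    return(0)
  }
  tau <- min(C, (loss - margin) / nrm2)
  weights_add(ws, dphi, tau, step)
  tau
}

# Training / prediction --------------------------------------------------------

#' Train the joint model with MIRA
#'
#' Iterates over the corpus in a seeded shuffled order, comparing the gold
#' assignment of each sentence with the current dual-decomposition argmax
#' and applying MIRA updates; returns averaged weights.
#'
#' @param corpus Gold corpus (documents with token tables).
#' @param stacked Optional stacked predictions: a named list mapping doc id
#'   to a list of `stacked_prediction` objects (empty = no stacking).
#' @param inv A [type_inventory()].
#' @param epochs Training epochs.
#' @param C MIRA aggressiveness cap.
#' @param seed Shuffle seed.
#' @param feature_opts Feature-template switches (`use_anchors`,
#'   `use_arguments`, `conjoin`, `conjoin_retain`) for stacking ablations.
#' @param max_iter Dual-decomposition iteration cap during training.
#' @return Object of class `joint_model` holding averaged weights.
#' @export
train_joint <- function(corpus, stacked = NULL, inv = type_inventory("ge"),
                        epochs = 10, C = 0.1, seed = 1,
                        feature_opts = default_feature_opts(),
                        max_iter = 25) {
  if (!length(corpus)) stop_usage("empty training corpus")
  instances <- lapply(corpus, function(doc) {
    build_instance(doc$tokens %||% tokens_from_text(doc), inv,
                   stacked[[doc$doc_id]] %||% list(), feature_opts)
  })
  golds <- lapply(corpus, function(doc) {
    assignment_from_graph(events_to_graph(doc, inv = inv))
  })
  ws <- new_weights()
  step <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      for (d in sample(seq_along(corpus))) {
        step <- step + 1L
        pred <- infer_dd(instances[[d]], ws, max_iter = max_iter)$assignment
        mira_update(ws, golds[[d]], pred, instances[[d]], C = C, step = step)
      }
    }
  })
  structure(list(weights = weights_average(ws, max(step, 1L)), raw = ws,
                 inv = inv, feature_opts = feature_opts, epochs = epochs,
                 C = C, seed = seed),
            class = "joint_model")
}

#' @export
print.joint_model <- function(x, ...) {
  cat(sprintf("<joint_model: %d features, %d epochs, C=%g>\n",
              length(ls(x$weights$w)), x$epochs, x$C))
  invisible(x)
}

#' Predict events with a trained joint model
#'
#' Runs dual-decomposition inference per document and converts each decoded
#' assignment into an event document.
#'
#' @param model A [train_joint()] model.
#' @param corpus Corpus of documents (token tables required; gold events,
#'   if present, are ignored).
#' @param stacked Optional stacked predictions keyed by doc id.
#' @param max_iter Dual-decomposition iteration cap.
#' @return A list: `corpus` (predicted event documents), `graphs` (decoded
#'   token graphs), `certificates` (per-document inference certificates).
#' @export
predict_joint <- function(model, corpus, stacked = NULL, max_iter = 100) {
  graphs <- list(); docs <- list(); certs <- character()
  for (doc in corpus) {
    tokens <- doc$tokens %||% tokens_from_text(doc)
    instance <- build_instance(tokens, model$inv,
                               stacked[[doc$doc_id]] %||% list(),
                               model$feature_opts)
    res <- infer_dd(instance, model$weights, max_iter = max_iter)
    g <- assignment_to_graph(res$assignment, tokens)
    graphs[[doc$doc_id]] <- g
    certs[doc$doc_id] <- res$certificate
    docs[[doc$doc_id]] <- graph_to_events(g, model$inv, doc_id = doc$doc_id,
                                          text = doc$text,
                                          proteins = doc$proteins)
    docs[[doc$doc_id]]$tokens <- tokens
  }
  list(corpus = structure(docs, class = "event_corpus"), graphs = graphs,
       certificates = certs)
}
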