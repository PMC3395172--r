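#' Event type inventory
#'
#' Groups event types by their argument valence: *simple* types take exactly
#' one THEME; *Binding* may take several THEMEs; *regulation* types take one
#' THEME (possibly another event) and at most one CAUSE. Only cause-licensed
#' types (the regulation family, plus Catalysis in the epigenetics setting)
#' may carry CAUSE arguments.
#'
#' @param preset One of `"ge"` (Genia-like), `"epi"` (epigenetics-like) or
#'   `"id"` (infectious-diseases-like), or `"custom"` with explicit sets.
#' @param simple_types,binding_types,regulation_types,cause_licensed_types
#'   Character vectors for `preset = "custom"`.
#' @return An object of class `type_inventory`.
#' @export
type_inventory <- function(preset = c("ge", "id", "epi", "custom"),
                           simple_types = NULL, binding_types = NULL,
                           regulation_types = NULL,
                           cause_licensed_types = NULL) {
  preset <- match.arg(preset)
  inv <- switch(preset,
    ge = , id = list(
      simple_types = c("Gene_expression", "Transcription", "Localization",
                       "Catabolism", "Phosphorylation"),
      binding_types = "Binding",
      regulation_types = c("Regulation", "Positive_regulation",
                           "Negative_regulation"),
      cause_licensed_types = c("Regulation", "Positive_regulation",
                               "Negative_regulation")),
    epi = list(
      simple_types = c("Phosphorylation", "Methylation", "Acetylation",
                       "Ubiquitination", "Glycosylation"),
      binding_types = character(),
      regulation_types = "Catalysis",
      cause_licensed_types = "Catalysis"),
    custom = list(simple_types = simple_types %||% character(),
                  binding_types = binding_types %||% character(),
                  regulation_types = regulation_types %||% character(),
                  cause_licensed_types = cause_licensed_types %||% character())
  )
  extra <- setdiff(inv$cause_licensed_types,
                   c(inv$regulation_types, "Catalysis"))
  if (length(extra)) {
    stop_validation("cause-licensed types must be regulation types or Catalysis: %s",
                    paste(extra, collapse = ", "))
  }
  if (anyDuplicated(c(inv$simple_types, inv$binding_types, inv$regulation_types))) {
    stop_validation("type inventory classes must be disjoint")
  }
  structure(inv, class = "type_inventory")
}

all_types <- function(inv) {
  c(inv$simple_types, inv$binding_types, inv$regulation_types)
}

#' Category of an event type
#'
#' @param type Event type label(s).
#' @param inv A [type_inventory()].
#' @return `"Simple"`, `"Binding"` or `"Regulation"` per type.
#' @export
event_category <- function(type, inv) {
  out <- rep(NA_character_, length(type))
  out[type %in% inv$simple_types] <- "Simple"
  out[type %in% inv$binding_types] <- "Binding"
  out[type %in% inv$regulation_types] <- "Regulation"
  out
}

# Token graphs ---------------------------------------------------------------

#' Construct a labeled token graph
#'
#' The token-graph view of a document's events: vertices are tokens, active
#' anchors carry an event-type label, role-labeled edges connect anchors to
#' their arguments, and unordered protein-token pairs record which proteins
#' take part in the same Binding event.
#'
#' @param tokens Token table (see [read_token_table()]).
#' @param labels data.frame with columns `index` (token index) and `type`.
#' @param edges data.frame with columns `src`, `dst` (token indices) and
#'   `role` (`"THEME"` / `"CAUSE"`).
#' @param binding_pairs data.frame with columns `p`, `q` (protein token
#'   indices, stored with `p < q`).
#' @return Object of class `token_graph`.
#' @export
token_graph <- function(tokens, labels = NULL, edges = NULL, binding_pairs = NULL) {
  labels <- labels %||% data.frame(index = integer(), type = character())
  edges <- edges %||% data.frame(src = integer(), dst = integer(), role = character())
  bp <- binding_pairs %||% data.frame(p = integer(), q = integer())
  if (nrow(bp)) {
    swap <- bp$p > bp$q
    tmp <- bp$p[swap]; bp$p[swap] <- bp$q[swap]; bp$q[swap] <- tmp
    bp <- unique(bp)
  }
  labels <- labels[order(labels$index), , drop = FALSE]
  edges <- edges[order(edges$src, edges$dst, edges$role), , drop = FALSE]
  rownames(labels) <- rownames(edges) <- rownames(bp) <- NULL
  structure(list(tokens = tokens, labels = labels, edges = edges,
                 binding_pairs = bp), class = "token_graph")
}

#' @export
print.token_graph <- function(x, ...) {
  cat(sprintf("<token_graph: %d tokens, %d labeled anchors, %d edges, %d binding pairs>\n",
              nrow(x$tokens), nrow(x$labels), nrow(x$edges), nrow(x$binding_pairs)))
  invisible(x)
}

# Validate structural (non-constraint) invariants of a token graph.
validate_token_graph <- function(g) {
  kind <- stats::setNames(g$tokens$kind, g$tokens$index)
  lab_idx <- g$labels$index
  if (any(kind[as.character(lab_idx)] != "CANDIDATE_ANCHOR")) {
    stop_validation("labels on non-anchor tokens")
  }
  if (anyDuplicated(lab_idx)) stop_validation("token labeled twice")
  if (nrow(g$edges)) {
    if (!all(g$edges$src %in% lab_idx)) {
      stop_validation("edge source is not a labeled anchor")
    }
    dk <- kind[as.character(g$edges$dst)]
    if (!all(dk %in% c("PROTEIN", "CANDIDATE_ANCHOR"))) {
      stop_validation("edge target must be a protein or candidate anchor token")
    }
  }
  if (nrow(g$binding_pairs)) {
    pk <- kind[as.character(c(g$binding_pairs$p, g$binding_pairs$q))]
    if (!all(pk == "PROTEIN")) stop_validation("binding pairs must join protein tokens")
  }
  invisible(g)
}

# Map an annotation span to its head token: the annotated head token
# overlapping the span if one exists; otherwise the last overlapping
# candidate-anchor or protein token, falling back to the last overlapping
# token.
span_head_token <- function(tokens, start, end) {
  ov <- which(tokens$start < end & tokens$end > start)
  if (!length(ov)) {
    stop_validation("span [%d,%d) does not overlap any token", start, end)
  }
  heads <- ov[tokens$head[ov] == 1L]
  if (!length(heads)) heads <- ov[tokens$kind[ov] != "OTHER"]
  idx <- if (length(heads)) heads[length(heads)] else ov[length(ov)]
  tokens$index[idx]
}

#' Project a document's events onto a labeled token graph
#'
#' Each event trigger labels its head token with the event type; each
#' argument contributes a role-labeled edge from the trigger's token to the
#' argument's head token (the argument event's trigger token when the
#' argument is an event); every unordered pair of proteins appearing as
#' THEMEs of one Binding event is recorded as a binding pair.
#'
#' @param doc A validated [event_document()].
#' @param tokens Token table; defaults to `doc$tokens`.
#' @param inv A [type_inventory()].
#' @return A [token_graph()].
#' @export
events_to_graph <- function(doc, tokens = doc$tokens, inv = type_inventory("ge")) {
  if (is.null(tokens)) tokens <- tokens_from_text(doc)
  head_of <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(doc$proteins))) {
    head_of[[doc$proteins$id[i]]] <-
      span_head_token(tokens, doc$proteins$start[i], doc$proteins$end[i])
  }
  for (i in seq_len(nrow(doc$triggers))) {
    head_of[[doc$triggers$id[i]]] <-
      span_head_token(tokens, doc$triggers$start[i], doc$triggers$end[i])
  }
  ev_trigger <- stats::setNames(vapply(doc$events, `[[`, "", "trigger"),
                                vapply(doc$events, `[[`, "", "id"))
  target_token <- function(id) {
    if (!is.null(head_of[[id]])) head_of[[id]] else head_of[[ev_trigger[[id]]]]
  }
  labels <- list(); edges <- list(); pairs <- list()
  for (ev in doc$events) {
    ti <- head_of[[ev$trigger]]
    labels[[length(labels) + 1L]] <- data.frame(index = ti, type = ev$type)
    if (nrow(ev$args)) {
      dst <- vapply(ev$args$target, target_token, integer(1))
      edges[[length(edges) + 1L]] <-
        data.frame(src = ti, dst = unname(dst), role = ev$args$role)
      if (ev$type %in% inv$binding_types) {
        prot_th <- unname(dst[ev$args$role == "THEME" &
                              ev$args$target %in% doc$proteins$id])
        if (length(prot_th) >= 2L) {
          cmb <- utils::combn(sort(unique(prot_th)), 2L)
          pairs[[length(pairs) + 1L]] <- data.frame(p = cmb[1, ], q = cmb[2, ])
        }
      }
    }
  }
  labels <- unique(do.call(rbind, labels) %||% data.frame(index = integer(), type = character()))
  if (anyDuplicated(labels$index)) {
    stop_validation("document %s: trigger token %d labeled with two types",
                    doc$doc_id, labels$index[duplicated(labels$index)][1])
  }
  g <- token_graph(tokens, labels,
                   unique(do.call(rbind, edges) %||% NULL),
                   do.call(rbind, pairs) %||% NULL)
  validate_token_graph(g)
  g
}

#' Check the joint model's structural constraints
#'
#' A labeled token graph is a well-formed event structure iff (1) every
#' labeled anchor has at least one outgoing THEME edge; (2) CAUSE edges
#' originate only from cause-licensed anchor labels; (3) every edge target
#' that is a candidate-anchor token is itself labeled; and (4) every binding
#' pair `{p, q}` is witnessed by some Binding-labeled anchor with THEME
#' edges to both `p` and `q`.
#'
#' @param g A [token_graph()].
#' @param inv A [type_inventory()].
#' @return Character vector of violation descriptions; empty when valid.
#' @export
check_constraints <- function(g, inv = type_inventory("ge")) {
  out <- character()
  lab <- stats::setNames(g$labels$type, g$labels$index)
  kind <- stats::setNames(g$tokens$kind, g$tokens$index)
  for (i in g$labels$index) {
    th <- g$edges$src == i & g$edges$role == "THEME"
    if (!any(th)) {
      out <- c(out, sprintf("anchor %d (%s) has no THEME argument", i,
                            lab[[as.character(i)]]))
    }
  }
  ce <- g$edges[g$edges$role == "CAUSE", , drop = FALSE]
  for (k in seq_len(nrow(ce))) {
    t <- lab[[as.character(ce$src[k])]] %||% NA_character_
    if (is.na(t) || !t %in% inv$cause_licensed_types) {
      out <- c(out, sprintf("CAUSE edge from anchor %d with unlicensed label %s",
                            ce$src[k], t))
    }
  }
  anchor_dst <- g$edges$dst[kind[as.character(g$edges$dst)] == "CANDIDATE_ANCHOR"]
  for (j in unique(anchor_dst)) {
    if (!j %in% g$labels$index) {
      out <- c(out, sprintf("argument anchor %d is not labeled", j))
    }
  }
  bind_anchors <- g$labels$index[g$labels$type %in% inv$binding_types]
  for (k in seq_len(nrow(g$binding_pairs))) {
    p <- g$binding_pairs$p[k]; q <- g$binding_pairs$q[k]
    witnessed <- any(vapply(bind_anchors, function(i) {
      th <- g$edges$dst[g$edges$src == i & g$edges$role == "THEME"]
      p %in% th && q %in% th
    }, logical(1)))
    if (!witnessed) {
      out <- c(out, sprintf("binding pair {%d,%d} has no witnessing Binding anchor",
                            p, q))
    }
  }
  out
}

# Remove anchor-anchor edges that close cycles so the reconstructed events
# are acyclic; drops the cycle edge with the largest (src, dst), which keeps
# the earliest-introduced dependency. Rarely triggered: gold graphs are
# acyclic by construction and predicted cycles are uncommon.
break_anchor_cycles <- function(edges, anchor_idx) {
  repeat {
    ee <- edges[edges$src %in% anchor_idx & edges$dst %in% anchor_idx, , drop = FALSE]
    back <- find_back_edge(sort(anchor_idx), ee)
    if (is.null(back)) return(edges)
    keep <- !(edges$src == back[1] & edges$dst == back[2])
    edges <- edges[keep, , drop = FALSE]
  }
}

# First back edge found by DFS over sorted nodes/neighbors, or NULL if acyclic.
find_back_edge <- function(nodes, ee) {
  state <- stats::setNames(integer(length(nodes)), nodes)
  back <- NULL
  visit <- function(i) {
    if (!is.null(back)) return()
    state[[as.character(i)]] <<- 1L
    for (j in sort(ee$dst[ee$src == i])) {
      if (!is.null(back)) return()
      sj <- state[[as.character(j)]]
      if (sj == 1L) { back <<- c(i, j); return() }
      if (sj == 0L) visit(j)
    }
    state[[as.character(i)]] <<- 2L
  }
  for (i in nodes) if (state[[as.character(i)]] == 0L) visit(i)
  back
}

#' Reconstruct events from a labeled token graph
#'
#' The inverse of [events_to_graph()] on graphs produced from valid
#' documents. Each labeled anchor yields one event per outgoing THEME edge
#' (simple and regulation types; CAUSE edges are distributed round-robin
#' over a regulation anchor's events), while a Binding anchor's protein
#' THEME targets are grouped into events by the maximal cliques of the
#' binding-pair relation (singleton events for unpaired targets). Cycles
#' among anchor-anchor edges are broken deterministically before
#' reconstruction.
#'
#' @param g A [token_graph()] passing [check_constraints()].
#' @param inv A [type_inventory()].
#' @param doc_id,text,proteins Optional document metadata to carry over;
#'   synthesized from the token table when absent.
#' @return An [event_document()].
#' @export
graph_to_events <- function(g, inv = type_inventory("ge"), doc_id = "doc",
                            text = NULL, proteins = NULL) {
  violations <- check_constraints(g, inv)
  if (length(violations)) {
    stop_validation("constraint-violating graph: %s",
                    paste(violations, collapse = "; "))
  }
  validate_token_graph(g)
  tokens <- g$tokens
  if (is.null(text)) {
    n <- max(tokens$end)
    chars <- rep(" ", n)
    for (i in seq_len(nrow(tokens))) {
      s <- tokens$start[i]; e <- tokens$end[i]
      chars[(s + 1):e] <- strsplit(tokens$text[i], "")[[1]]
    }
    text <- paste(chars, collapse = "")
  }
  tok_row <- function(i) tokens[tokens$index == i, , drop = FALSE]
  if (is.null(proteins)) {
    pt <- tokens[tokens$kind == "PROTEIN", , drop = FALSE]
    proteins <- data.frame(id = sprintf("T%d", seq_len(nrow(pt))),
                           type = "Protein", start = pt$start, end = pt$end,
                           text = pt$text, stringsAsFactors = FALSE)
  }
  prot_id_of_token <- stats::setNames(
    proteins$id,
    vapply(seq_len(nrow(proteins)), function(i) {
      span_head_token(tokens, proteins$start[i], proteins$end[i])
    }, integer(1)))

  lab <- g$labels
  edges <- break_anchor_cycles(g$edges, lab$index)
  # cycle breaking can strip an anchor's last THEME edge; cascade-drop such
  # anchors (and edges pointing at them) so reconstruction stays well-formed
  repeat {
    has_theme <- vapply(lab$index, function(i) {
      any(edges$src == i & edges$role == "THEME")
    }, logical(1))
    if (all(has_theme)) break
    lab <- lab[has_theme, , drop = FALSE]
    kind_of <- stats::setNames(tokens$kind, tokens$index)
    keep_e <- edges$src %in% lab$index &
      (kind_of[as.character(edges$dst)] == "PROTEIN" |
         edges$dst %in% lab$index)
    edges <- edges[keep_e, , drop = FALSE]
  }

  # triggers: one per labeled anchor, spanning the head token
  triggers <- do.call(rbind, lapply(seq_len(nrow(lab)), function(k) {
    tr <- tok_row(lab$index[k])
    data.frame(id = sprintf("TR%d", k), type = lab$type[k], start = tr$start,
               end = tr$end, text = tr$text, stringsAsFactors = FALSE)
  })) %||% empty_mentions()
  trig_id_of_anchor <- stats::setNames(triggers$id, lab$index)

  # order anchors so argument anchors are processed first
  anchor_order <- order_anchors(lab$index, edges)
  events_at <- stats::setNames(vector("list", nrow(lab)), as.character(lab$index))
  events <- list(); ev_n <- 0L
  new_event <- function(type, trig, themes, causes = character()) {
    ev_n <<- ev_n + 1L
    args <- data.frame(role = c(rep("THEME", length(themes)),
                                rep("CAUSE", length(causes))),
                       target = c(themes, causes), stringsAsFactors = FALSE)
    list(id = sprintf("E%d", ev_n), type = type, trig = trig, args = args)
  }
  target_id <- function(j) {
    cj <- as.character(j)
    pid <- prot_id_of_token[cj]
    if (!is.na(pid)) unname(pid)
    else events_at[[cj]][[1]]$id  # first event reconstructed at that anchor
  }
  for (i in anchor_order) {
    ci <- as.character(i)
    t <- lab$type[lab$index == i]
    out_th <- edges$dst[edges$src == i & edges$role == "THEME"]
    out_ca <- edges$dst[edges$src == i & edges$role == "CAUSE"]
    made <- list()
    if (t %in% inv$binding_types) {
      prot_th <- sort(out_th[!is.na(prot_id_of_token[as.character(out_th)])])
      other_th <- sort(setdiff(out_th, prot_th))
      groups <- binding_groups(prot_th, g$binding_pairs)
      for (grp in groups) {
        made[[length(made) + 1L]] <- new_event(
          t, trig_id_of_anchor[[ci]],
          vapply(grp, target_id, character(1)))
      }
      for (j in other_th) {
        made[[length(made) + 1L]] <- new_event(t, trig_id_of_anchor[[ci]],
                                               target_id(j))
      }
    } else {
      themes <- sort(out_th)
      causes <- sort(out_ca)
      if (!t %in% inv$cause_licensed_types) causes <- integer(0)
      n_ev <- max(length(themes), if (length(causes)) length(causes) else 0L, 1L)
      for (k in seq_len(max(length(themes), length(causes)))) {
        th <- themes[[min(k, length(themes))]]
        ca <- if (k <= length(causes)) causes[[k]] else NULL
        made[[length(made) + 1L]] <- new_event(
          t, trig_id_of_anchor[[ci]], target_id(th),
          if (is.null(ca)) character() else target_id(ca))
      }
    }
    events_at[[ci]] <- made
    events <- c(events, made)
  }
  events <- lapply(events, function(ev) {
    list(id = ev$id, type = ev$type, trigger = ev$trig, args = ev$args)
  })
  event_document(doc_id, text, proteins, triggers, events)
}

# Topological-ish ordering of anchors: arguments before their users.
order_anchors <- function(anchor_idx, edges) {
  if (!length(anchor_idx)) return(integer(0))
  ee <- edges[edges$src %in% anchor_idx & edges$dst %in% anchor_idx, , drop = FALSE]
  remaining <- sort(anchor_idx)
  out <- integer(0)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i) {
      !any(ee$src == i & ee$dst %in% remaining & ee$dst != i)
    }, logical(1))]
    if (!length(ready)) ready <- remaining[1]  # defensive; cycles are pre-broken
    out <- c(out, ready)
    remaining <- setdiff(remaining, ready)
  }
  out
}

# Group a Binding anchor's protein THEME targets into events: maximal
# cliques of the binding-pair relation restricted to those targets, plus
# singletons for unpaired targets.
binding_groups <- function(prot_tokens, binding_pairs) {
  if (!length(prot_tokens)) return(list())
  bp <- binding_pairs[binding_pairs$p %in% prot_tokens &
                      binding_pairs$q %in% prot_tokens, , drop = FALSE]
  if (!nrow(bp)) return(as.list(sort(prot_tokens)))
  gr <- igraph::graph_from_data_frame(
    data.frame(from = as.character(bp$p), to = as.character(bp$q)),
    directed = FALSE,
    vertices = data.frame(name = as.character(sort(unique(prot_tokens)))))
  cl <- igraph::max_cliques(gr, min = 1)
  groups <- lapply(cl, function(v) sort(as.integer(igraph::as_ids(v))))
  groups <- groups[order(vapply(groups, `[`, integer(1), 1),
                         -vapply(groups, length, integer(1)))]
  groups
}
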