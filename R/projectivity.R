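#' Count crossing edges in a token graph
#'
#' Non-projectivity of a graph is the number of crossing edge pairs: two
#' edges drawn as arcs over the token order cross iff their index intervals
#' properly interleave, `min(a) < min(c) < max(a) < max(c)`. Edge direction
#' and labels are irrelevant; self-loops and edge pairs sharing an endpoint
#' never cross. A graph is projective iff the count is 0. Multi-sentence
#' documents are scored per sentence and summed (edges never span
#' sentences).
#'
#' @param g A [token_graph()], or a data.frame of edges with columns
#'   `src`, `dst` (and optionally `sentence`).
#' @return Non-negative integer: the number of crossing edge pairs.
#' @export
crossing_count <- function(g) {
  edges <- if (inherits(g, "token_graph")) g$edges else g
  if (is.null(edges) || nrow(edges) < 2L) return(0L)
  sent <- if (!is.null(edges$sentence)) {
    edges$sentence
  } else if (inherits(g, "token_graph") && !is.null(g$tokens$sentence)) {
    stats::setNames(g$tokens$sentence, g$tokens$index)[as.character(edges$src)]
  } else rep(1L, nrow(edges))
  total <- 0L
  for (s in unique(sent)) {
    ee <- edges[sent == s, , drop = FALSE]
    lo <- pmin(ee$src, ee$dst)
    hi <- pmax(ee$src, ee$dst)
    n <- nrow(ee)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        a <- c(lo[i], hi[i]); b <- c(lo[j], hi[j])
        if (a[1] > b[1]) { tmp <- a; a <- b; b <- tmp }
        if (a[1] < b[1] && b[1] < a[2] && a[2] < b[2]) total <- total + 1L
      }
    }
  }
  total
}

#' Corpus-level projectivity report
#'
#' Summarizes how non-projective a corpus is: per document the number of
#' crossing arcs, and at corpus level the fraction of documents with at
#' least one crossing arc, the fraction of sentences with one, and the
#' fraction of dependencies (edges) involved in at least one crossing.
#'
#' @param graphs Named list of [token_graph()]s (one per document).
#' @return A list with `per_document` (data.frame `doc_id`, `crossings`) and
#'   `corpus` (named numeric vector of fractions).
#' @export
projectivity_report <- function(graphs) {
  per_doc <- data.frame(
    doc_id = names(graphs),
    crossings = vapply(graphs, crossing_count, integer(1)),
    stringsAsFactors = FALSE)
  n_sent <- 0L; n_sent_cross <- 0L; n_dep <- 0L; n_dep_cross <- 0L
  for (g in graphs) {
    edges <- g$edges
    sent <- if (!is.null(g$tokens$sentence)) {
      stats::setNames(g$tokens$sentence, g$tokens$index)[as.character(edges$src)]
    } else rep(1L, nrow(edges))
    sents <- if (!is.null(g$tokens$sentence)) unique(g$tokens$sentence) else 1L
    n_sent <- n_sent + length(sents)
    n_dep <- n_dep + nrow(edges)
    for (s in sents) {
      ee <- edges[sent == s, , drop = FALSE]
      if (!nrow(ee)) next
      crossed <- edge_cross_flags(ee)
      if (any(crossed)) n_sent_cross <- n_sent_cross + 1L
      n_dep_cross <- n_dep_cross + sum(crossed)
    }
  }
  list(per_document = per_doc,
       corpus = c(doc_fraction = mean(per_doc$crossings > 0),
                  sentence_fraction = if (n_sent) n_sent_cross / n_sent else 0,
                  dependency_fraction = if (n_dep) n_dep_cross / n_dep else 0))
}

# Logical flag per edge: does it cross any other edge in the set?
edge_cross_flags <- function(ee) {
  n <- nrow(ee)
  lo <- pmin(ee$src, ee$dst); hi <- pmax(ee$src, ee$dst)
  flags <- logical(n)
  if (n < 2L) return(flags)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- c(lo[i], hi[i]); b <- c(lo[j], hi[j])
      if (a[1] > b[1]) { tmp <- a; a <- b; b <- tmp }
      if (a[1] < b[1] && b[1] < a[2] && a[2] < b[2]) flags[i] <- flags[j] <- TRUE
    }
  }
  flags
}

#' Document-wise accuracy differences split by gold projectivity
#'
#' For two prediction corpora, computes per document the difference in the
#' number of predicted events matched with gold (model A minus model B),
#' and partitions documents into projective (zero gold crossing arcs) and
#' non-projective. Positive differences mean A outperformed B on that
#' document.
#'
#' @param pred_a,pred_b Prediction corpora (named lists of
#'   [event_document()]s).
#' @param gold Gold corpus.
#' @param policy A [match_policy()].
#' @param inv A [type_inventory()].
#' @return A list with `per_document` (data.frame `doc_id`, `gold_crossings`,
#'   `projective`, `matched_a`, `matched_b`, `diff`) and `summary`
#'   (data.frame of median and quartiles per partition).
#' @export
document_accuracy_diff <- function(pred_a, pred_b, gold,
                                   policy = match_policy("approximate"),
                                   inv = type_inventory("ge")) {
  ids <- names(gold)
  if (!setequal(ids, names(pred_a)) || !setequal(ids, names(pred_b))) {
    stop_validation("corpora do not share doc_ids")
  }
  rows <- lapply(ids, function(id) {
    gx <- events_to_graph(gold[[id]], inv = inv)
    cr <- crossing_count(gx)
    ma <- matched_event_count(pred_a[[id]], gold[[id]], policy)
    mb <- matched_event_count(pred_b[[id]], gold[[id]], policy)
    data.frame(doc_id = id, gold_crossings = cr, projective = cr == 0L,
               matched_a = ma, matched_b = mb, diff = ma - mb,
               stringsAsFactors = FALSE)
  })
  per_doc <- do.call(rbind, rows)
  summarize <- function(x) {
    if (!length(x)) return(c(n = 0, q25 = NA, median = NA, q75 = NA))
    c(n = length(x), q25 = unname(stats::quantile(x, 0.25)),
      median = stats::median(x), q75 = unname(stats::quantile(x, 0.75)))
  }
  summary <- rbind(
    data.frame(partition = "projective",
               t(summarize(per_doc$diff[per_doc$projective]))),
    data.frame(partition = "non_projective",
               t(summarize(per_doc$diff[!per_doc$projective]))))
  list(per_document = per_doc, summary = summary)
}
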