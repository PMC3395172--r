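#' Event matching policy
#'
#' Controls event equality testing. `"strict"` requires exact trigger spans
#' and full role-for-role argument agreement at every nesting level (the
#' non-approximate recursive rules). `"approximate"` allows the predicted
#' trigger span to deviate by `span_slack` words (default 1, the shared
#' task's approximate-span relaxation: the predicted span must lie within
#' the gold span extended by that many words on each side) and compares
#' nested event arguments on their core only — type, trigger and THEME
#' arguments — ignoring nested CAUSE arguments.
#'
#' @param recursive_mode `"strict"` or `"approximate"`.
#' @param span_slack Words of trigger-span slack; defaults to 0 for strict
#'   and 1 for approximate.
#' @return An object of class `match_policy`.
#' @export
match_policy <- function(recursive_mode = c("approximate", "strict"),
                         span_slack = NULL) {
  recursive_mode <- match.arg(recursive_mode)
  span_slack <- span_slack %||% if (recursive_mode == "strict") 0L else 1L
  if (span_slack < 0L) stop_validation("span_slack must be >= 0")
  structure(list(recursive_mode = recursive_mode,
                 span_slack = as.integer(span_slack)),
            class = "match_policy")
}

# Word spans (start, end half-open) of a document text.
word_spans <- function(text) {
  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(), end = integer()))
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

# Does the predicted span match the gold span under `slack` words of slack?
spans_match <- function(p_start, p_end, g_start, g_end, slack, gold_text) {
  if (slack == 0L) return(p_start == g_start && p_end == g_end)
  ws <- word_spans(gold_text)
  lo <- g_start; hi <- g_end
  left <- ws$start[ws$end <= g_start]
  right <- ws$end[ws$start >= g_end]
  if (length(left)) lo <- rev(left)[min(slack, length(left))]
  if (length(right)) hi <- right[min(slack, length(right))]
  p_start >= lo && p_end <= hi && p_end > p_start
}

doc_index <- function(doc) {
  list(
    prot = stats::setNames(split(doc$proteins, seq_len(nrow(doc$proteins))),
                           doc$proteins$id),
    trig = stats::setNames(split(doc$triggers, seq_len(nrow(doc$triggers))),
                           doc$triggers$id),
    ev = stats::setNames(doc$events, vapply(doc$events, `[[`, "", "id")))
}

#' Test whether a predicted event matches a gold event
#'
#' Events match when their types are equal, their trigger spans agree within
#' the policy's span slack, and their arguments can be put in a role-for-role
#' bijection: protein arguments match when they denote the same mention
#' (same span), event arguments match recursively. Under the approximate
#' policy, nested event arguments are compared on type, trigger and THEME
#' arguments only.
#'
#' @param pred,gold Event records (elements of `doc$events`) or event ids.
#' @param pred_doc,gold_doc The documents the two events live in.
#' @param policy A [match_policy()].
#' @return `TRUE` or `FALSE`.
#' @export
events_match <- function(pred, gold, pred_doc, gold_doc,
                         policy = match_policy("approximate")) {
  pidx <- doc_index(pred_doc); gidx <- doc_index(gold_doc)
  if (is.character(pred)) pred <- pidx$ev[[pred]]
  if (is.character(gold)) gold <- gidx$ev[[gold]]
  match_event_rec(pred, gold, pidx, gidx, policy, gold_doc$text, nested = FALSE)
}

match_event_rec <- function(pe, ge, pidx, gidx, policy, gold_text, nested) {
  if (pe$type != ge$type) return(FALSE)
  pt <- pidx$trig[[pe$trigger]]; gt <- gidx$trig[[ge$trigger]]
  if (!spans_match(pt$start, pt$end, gt$start, gt$end, policy$span_slack,
                   gold_text)) {
    return(FALSE)
  }
  pa <- pe$args; ga <- ge$args
  if (nested && policy$recursive_mode == "approximate") {
    pa <- pa[pa$role == "THEME", , drop = FALSE]
    ga <- ga[ga$role == "THEME", , drop = FALSE]
  }
  if (nrow(pa) != nrow(ga)) return(FALSE)
  match_args_bijection(pa, ga, pidx, gidx, policy, gold_text)
}

# Backtracking search for a role-preserving bijection between argument sets.
match_args_bijection <- function(pa, ga, pidx, gidx, policy, gold_text) {
  n <- nrow(pa)
  if (n == 0L) return(TRUE)
  used <- logical(n)
  arg_ok <- function(pt, gt, role_p, role_g) {
    if (role_p != role_g) return(FALSE)
    p_is_prot <- pt %in% names(pidx$prot)
    g_is_prot <- gt %in% names(gidx$prot)
    if (p_is_prot != g_is_prot) return(FALSE)
    if (p_is_prot) {
      pp <- pidx$prot[[pt]]; gp <- gidx$prot[[gt]]
      return(pp$start == gp$start && pp$end == gp$end)
    }
    match_event_rec(pidx$ev[[pt]], gidx$ev[[gt]], pidx, gidx, policy,
                    gold_text, nested = TRUE)
  }
  assign_next <- function(i) {
    if (i > n) return(TRUE)
    for (j in which(!used)) {
      if (arg_ok(pa$target[i], ga$target[j], pa$role[i], ga$role[j])) {
        used[j] <<- TRUE
        if (assign_next(i + 1L)) return(TRUE)
        used[j] <<- FALSE
      }
    }
    FALSE
  }
  assign_next(1L)
}

# Number of predicted events matched one-to-one with gold (greedy order).
matched_event_count <- function(pred_doc, gold_doc, policy) {
  greedy_match(pred_doc, gold_doc, policy)$tp
}

# Greedy one-to-one matching within a document: predictions in serialization
# order, each consuming the first unconsumed matching gold event.
greedy_match <- function(pred_doc, gold_doc, policy) {
  pidx <- doc_index(pred_doc); gidx <- doc_index(gold_doc)
  gold_ids <- names(gidx$ev)
  consumed <- logical(length(gold_ids))
  pred_hit <- logical(length(pidx$ev))
  pair_of <- stats::setNames(rep(NA_character_, length(pidx$ev)), names(pidx$ev))
  for (i in seq_along(pidx$ev)) {
    for (j in seq_along(gold_ids)) {
      if (consumed[j]) next
      if (match_event_rec(pidx$ev[[i]], gidx$ev[[j]], pidx, gidx, policy,
                          gold_doc$text, nested = FALSE)) {
        consumed[j] <- TRUE
        pred_hit[i] <- TRUE
        pair_of[i] <- gold_ids[j]
        break
      }
    }
  }
  list(tp = sum(pred_hit), pred_hit = pred_hit, gold_hit = consumed,
       pred_ids = names(pidx$ev), gold_ids = gold_ids, pair_of = pair_of)
}

prf_row <- function(tp, fp, fn) {
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (recall + precision > 0) 2 * recall * precision / (recall + precision) else 0
  data.frame(tp = tp, fp = fp, fn = fn, recall = recall,
             precision = precision, f1 = f1)
}

#' Score a prediction corpus against gold
#'
#' Events are matched greedily one-to-one within each document (each gold
#' event consumed at most once) and counts are aggregated micro-style
#' across documents, overall and per event category (Simple, Binding,
#' Regulation). True/false positives are categorized by the predicted
#' event's type, false negatives by the gold event's type.
#'
#' @param pred,gold Corpora (named lists of [event_document()]s sharing
#'   doc ids).
#' @param policy A [match_policy()].
#' @param inv A [type_inventory()].
#' @return data.frame with one row per category plus `"Overall"`, columns
#'   `tp`, `fp`, `fn`, `recall`, `precision`, `f1`.
#' @export
score_corpus <- function(pred, gold, policy = match_policy("approximate"),
                         inv = type_inventory("ge")) {
  if (!all(names(pred) %in% names(gold))) {
    stop_validation("prediction corpus contains doc_ids absent from gold")
  }
  cats <- c("Simple", "Binding", "Regulation")
  tp <- fp <- fn <- stats::setNames(numeric(length(cats)), cats)
  for (id in names(gold)) {
    pdoc <- pred[[id]] %||% event_document(id, gold[[id]]$text)
    m <- greedy_match(pdoc, gold[[id]], policy)
    pred_cat <- event_category(vapply(pdoc$events, `[[`, "", "type"), inv)
    gold_cat <- event_category(vapply(gold[[id]]$events, `[[`, "", "type"), inv)
    for (c_ in cats) {
      tp[c_] <- tp[c_] + sum(m$pred_hit & pred_cat == c_, na.rm = TRUE)
      fp[c_] <- fp[c_] + sum(!m$pred_hit & pred_cat == c_, na.rm = TRUE)
      fn[c_] <- fn[c_] + sum(!m$gold_hit & gold_cat == c_, na.rm = TRUE)
    }
  }
  rows <- do.call(rbind, lapply(cats, function(c_) {
    cbind(category = c_, prf_row(tp[[c_]], fp[[c_]], fn[[c_]]))
  }))
  overall <- cbind(category = "Overall", prf_row(sum(tp), sum(fp), sum(fn)))
  out <- rbind(rows, overall)
  rownames(out) <- NULL
  out
}
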