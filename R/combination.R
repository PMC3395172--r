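# Set-theoretic model combination, event-origin analysis and novel-event
# filtering. Corpora are named lists of event_documents sharing doc ids;
# event equality is always equality-under-matching for a given policy.

check_shared_ids <- function(...) {
  corpora <- list(...)
  ids <- names(corpora[[1]])
  for (cp in corpora[-1]) {
    if (!setequal(ids, names(cp))) stop_validation("corpora do not share doc_ids")
  }
  ids
}

# Drop the given event ids from a document, cascading to events whose
# arguments reference a dropped event, then prune unused triggers.
drop_events <- function(doc, drop_ids) {
  repeat {
    keep <- vapply(doc$events, function(ev) !(ev$id %in% drop_ids), logical(1))
    newly <- vapply(doc$events[keep], function(ev) {
      any(ev$args$target %in% drop_ids)
    }, logical(1))
    if (!any(newly)) {
      doc$events <- doc$events[keep]
      break
    }
    drop_ids <- c(drop_ids, vapply(doc$events[keep][newly], `[[`, "", "id"))
  }
  used_trig <- unique(vapply(doc$events, `[[`, "", "trigger"))
  doc$triggers <- doc$triggers[doc$triggers$id %in% used_trig, , drop = FALSE]
  event_document(doc$doc_id, doc$text, doc$proteins, doc$triggers, doc$events,
                 doc$extra, doc$tokens)
}

#' Union of two prediction corpora
#'
#' Per document, keeps all events of `a` plus every event of `b` that has no
#' match in `a` (greedy one-to-one matching under `policy`); matched
#' duplicates keep `a`'s serialization. Imported events bring their triggers
#' and unmatched nested arguments along transitively; nested arguments that
#' match an event of `a` are remapped onto `a`'s version.
#'
#' @param a,b Corpora (named lists of [event_document()]s).
#' @param policy A [match_policy()].
#' @return The combined corpus.
#' @export
combine_union <- function(a, b, policy = match_policy("approximate")) {
  ids <- check_shared_ids(a, b)
  out <- lapply(ids, function(id) union_doc(a[[id]], b[[id]], policy))
  names(out) <- ids
  structure(out, class = "event_corpus")
}

union_doc <- function(da, db, policy) {
  m <- greedy_match(db, da, policy)  # match b's events against a's
  import_ids <- names(m$pair_of)[is.na(m$pair_of)]
  if (!length(import_ids)) return(da)
  bidx <- doc_index(db)

  triggers <- da$triggers
  trig_remap <- character()
  ensure_trigger <- function(tid) {
    if (!is.null(trig_remap[tid]) && !is.na(trig_remap[tid])) {
      return(trig_remap[[tid]])
    }
    bt <- bidx$trig[[tid]]
    hit <- which(triggers$start == bt$start & triggers$end == bt$end &
                 triggers$type == bt$type)
    new_id <- if (length(hit)) {
      triggers$id[hit[1]]
    } else {
      nid <- sprintf("UT%d", nrow(triggers) + 1L)
      triggers <<- rbind(triggers,
                         data.frame(id = nid, type = bt$type, start = bt$start,
                                    end = bt$end, text = bt$text))
      nid
    }
    trig_remap[tid] <<- new_id
    new_id
  }

  ev_remap <- m$pair_of  # b event id -> a event id (NA if imported)
  prot_remap <- stats::setNames(
    da$proteins$id[match(paste(db$proteins$start, db$proteins$end),
                         paste(da$proteins$start, da$proteins$end))],
    db$proteins$id)
  # import in topological order so nested arguments are available
  topo <- event_topo_order(db$events)
  imported <- list()
  k <- 0L
  for (i in topo) {
    ev <- db$events[[i]]
    if (!is.na(ev_remap[[ev$id]])) next
    if (!ev$id %in% import_ids) next
    k <- k + 1L
    new_id <- sprintf("U%d", length(da$events) + k)
    args <- ev$args
    for (r in seq_len(nrow(args))) {
      tgt <- args$target[r]
      if (tgt %in% names(prot_remap)) {
        mapped <- prot_remap[[tgt]]
        if (is.na(mapped)) stop_validation("union: protein %s of %s not in base corpus",
                                           tgt, db$doc_id)
        args$target[r] <- mapped
      } else {
        mapped <- ev_remap[[tgt]]
        if (is.na(mapped)) stop_validation("union: nested argument %s not importable", tgt)
        args$target[r] <- mapped
      }
    }
    imported[[length(imported) + 1L]] <-
      list(id = new_id, type = ev$type, trigger = ensure_trigger(ev$trigger),
           args = args)
    ev_remap[ev$id] <- new_id
  }
  event_document(da$doc_id, da$text, da$proteins, triggers,
                 c(da$events, imported), da$extra, da$tokens)
}

#' Intersection of two prediction corpora
#'
#' Per document, keeps the events of `a` that match some event of `b`
#' (greedy one-to-one), closed under argument reference: a kept event whose
#' nested event argument was dropped is dropped too, recursively.
#'
#' @inheritParams combine_union
#' @return The combined corpus.
#' @export
combine_intersection <- function(a, b, policy = match_policy("approximate")) {
  ids <- check_shared_ids(a, b)
  out <- lapply(ids, function(id) {
    da <- a[[id]]
    m <- greedy_match(da, b[[id]], policy)
    drop_ids <- names(m$pair_of)[is.na(m$pair_of)]
    drop_events(da, drop_ids)
  })
  names(out) <- ids
  structure(out, class = "event_corpus")
}

#' Classify the origin of each combined-output event
#'
#' Places every event of the combined (`final`) output in exactly one of
#' four classes by matching it against the two base models' standalone
#' outputs: `BOTH` (matched in both), `ONLY_STACKER` (only in the stacking
#' model's own output), `ONLY_STACKED` (only in the stacked model's
#' output), or `NOVEL` (matched in neither). Matching uses containment
#' (an event may match any event of a base output), with the strict
#' recursive policy by default. Defining novel events against the union of
#' the base outputs makes the four classes a partition of `final`.
#'
#' @param final Combined-output corpus.
#' @param stacker_alone Standalone output of the stacking model.
#' @param stacked_alone Standalone output of the stacked model.
#' @param policy A [match_policy()]; strict, slack 0 by default.
#' @return data.frame with columns `doc_id`, `event_id`, `origin`.
#' @export
classify_origins <- function(final, stacker_alone, stacked_alone,
                             policy = match_policy("strict")) {
  ids <- check_shared_ids(final, stacker_alone, stacked_alone)
  rows <- lapply(ids, function(id) {
    fdoc <- final[[id]]
    if (!length(fdoc$events)) return(NULL)
    in_stacker <- match_any_flags(fdoc, stacker_alone[[id]], policy)
    in_stacked <- match_any_flags(fdoc, stacked_alone[[id]], policy)
    origin <- ifelse(in_stacker & in_stacked, "BOTH",
              ifelse(in_stacker, "ONLY_STACKER",
              ifelse(in_stacked, "ONLY_STACKED", "NOVEL")))
    data.frame(doc_id = id,
               event_id = vapply(fdoc$events, `[[`, "", "id"),
               origin = origin, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(doc_id = character(), event_id = character(),
               origin = character())
  rownames(out) <- NULL
  out
}

# For each event of doc: does it match ANY event of other (containment)?
match_any_flags <- function(doc, other, policy) {
  pidx <- doc_index(doc); oidx <- doc_index(other)
  vapply(doc$events, function(ev) {
    any(vapply(other$events, function(oe) {
      match_event_rec(ev, oe, pidx, oidx, policy, other$text, nested = FALSE)
    }, logical(1)))
  }, logical(1))
}

#' Remove novel events from a combined output
#'
#' Drops every event classified `NOVEL` by [classify_origins()] — events
#' the combination produced that neither base model proposed — closed under
#' argument reference (events depending on a removed event are removed
#' too). Novel events tend to have very low precision, so removal trades a
#' little recall for precision.
#'
#' @inheritParams classify_origins
#' @return The filtered corpus.
#' @export
remove_novel <- function(final, stacker_alone, stacked_alone,
                         policy = match_policy("strict")) {
  origins <- classify_origins(final, stacker_alone, stacked_alone, policy)
  out <- lapply(names(final), function(id) {
    drop <- origins$event_id[origins$doc_id == id & origins$origin == "NOVEL"]
    if (!length(drop)) final[[id]] else drop_events(final[[id]], drop)
  })
  names(out) <- names(final)
  structure(out, class = "event_corpus")
}

#' Tabulate origin classes by event type and correctness
#'
#' @param origins Output of [classify_origins()].
#' @param final The combined corpus the origins were computed on.
#' @param gold Optional gold corpus; when supplied each event is also
#'   marked correct/incorrect under `gold_policy`.
#' @param gold_policy Policy for correctness matching.
#' @return data.frame of counts by `origin`, `type` (and `correct`).
#' @export
origin_table <- function(origins, final, gold = NULL,
                         gold_policy = match_policy("approximate")) {
  if (!nrow(origins)) {
    return(data.frame(origin = character(), type = character(), n = integer()))
  }
  type_of <- function(doc_id, event_id) {
    evs <- final[[doc_id]]$events
    evs[[which(vapply(evs, `[[`, "", "id") == event_id)]]$type
  }
  origins$type <- mapply(type_of, origins$doc_id, origins$event_id)
  if (!is.null(gold)) {
    flags <- unlist(lapply(names(final), function(id) {
      stats::setNames(match_any_flags(final[[id]], gold[[id]], gold_policy),
                      paste(id, vapply(final[[id]]$events, `[[`, "", "id")))
    }))
    origins$correct <- flags[paste(origins$doc_id, origins$event_id)]
    out <- stats::aggregate(list(n = origins$origin),
                            by = origins[, c("origin", "type", "correct")],
                            FUN = length)
  } else {
    out <- stats::aggregate(list(n = origins$origin),
                            by = origins[, c("origin", "type")], FUN = length)
  }
  out[order(out$origin, out$type), , drop = FALSE]
}
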