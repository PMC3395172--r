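#' Synthetic corpus generator configuration
#'
#' The generator emits standoff corpora with the structural properties the
#' extractors exploit: a Genia-like event-type mix, regulation nesting,
#' multi-THEME bindings, and a controllable rate of non-projective
#' documents, injected via the canonical interleaving pattern (a regulation
#' whose CAUSE arc crosses a binding's THEME arc). Text is synthetic token
#' strings joined by single spaces so all offset arithmetic is exercised
#' without NLP preprocessing.
#'
#' @param n_docs Number of documents.
#' @param tokens_per_sentence Approximate sentence length in tokens; filler
#'   words pad each sentence toward this target.
#' @param n_protein_names,triggers_per_type,n_filler,n_ambiguous_triggers
#'   Vocabulary sizes.
#' @param type_distribution Named probability vector over event types of the
#'   inventory; defaults to a Genia-like mix dominated by Gene_expression.
#' @param groups_per_doc Probability vector over 1..k top-level event groups
#'   per document.
#' @param regulation_nesting_prob Probability a regulation's THEME is a
#'   nested event rather than a protein (nesting depth capped at 2).
#' @param binding_multitheme_prob Probability a Binding takes two THEMEs.
#' @param cause_prob Probability a regulation carries a CAUSE argument.
#' @param rho Non-projectivity injection rate: probability a document
#'   receives one crossing-arc motif.
#' @param trigger_ambiguity Probability a trigger word is drawn from a
#'   shared pool used by all event types (lexically uninformative for the
#'   type) instead of the type's own vocabulary. 0 yields a lexically
#'   separable corpus.
#' @param decoy_anchor_rate Probability a document contains a decoy
#'   candidate-anchor token that anchors no event.
#' @param multiword_trigger_rate Probability a trigger span covers two
#'   tokens (head annotated on the final token).
#' @param inv A [type_inventory()].
#' @param seed RNG seed; the same seed yields a byte-identical corpus.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_docs = 100, tokens_per_sentence = 15,
                             n_protein_names = 40, triggers_per_type = 5,
                             n_filler = 30, n_ambiguous_triggers = 6,
                             type_distribution = NULL,
                             groups_per_doc = c(0.4, 0.4, 0.2),
                             regulation_nesting_prob = 0.35,
                             binding_multitheme_prob = 0.4,
                             cause_prob = 0.3, rho = 0.2,
                             trigger_ambiguity = 0.25,
                             decoy_anchor_rate = 0.3,
                             multiword_trigger_rate = 0.15,
                             inv = type_inventory("ge"), seed = 1) {
  type_distribution <- type_distribution %||% c(
    Gene_expression = 0.30, Transcription = 0.08, Localization = 0.05,
    Catabolism = 0.02, Phosphorylation = 0.10, Binding = 0.15,
    Regulation = 0.10, Positive_regulation = 0.12, Negative_regulation = 0.08)
  probs <- c(regulation_nesting_prob, binding_multitheme_prob, cause_prob,
             rho, trigger_ambiguity, decoy_anchor_rate, multiword_trigger_rate)
  if (any(probs < 0 | probs > 1)) stop_validation("probabilities must lie in [0,1]")
  if (abs(sum(type_distribution) - 1) > 1e-8) {
    stop_validation("type_distribution must sum to 1")
  }
  if (!all(names(type_distribution) %in% all_types(inv))) {
    stop_validation("type_distribution names must be inventory types")
  }
  if (rho > 0 && tokens_per_sentence < 5) {
    stop_validation("rho > 0 needs at least 5 tokens per sentence")
  }
  structure(list(n_docs = n_docs, tokens_per_sentence = tokens_per_sentence,
                 n_protein_names = n_protein_names,
                 triggers_per_type = triggers_per_type, n_filler = n_filler,
                 n_ambiguous_triggers = n_ambiguous_triggers,
                 type_distribution = type_distribution,
                 groups_per_doc = groups_per_doc,
                 regulation_nesting_prob = regulation_nesting_prob,
                 binding_multitheme_prob = binding_multitheme_prob,
                 cause_prob = cause_prob, rho = rho,
                 trigger_ambiguity = trigger_ambiguity,
                 decoy_anchor_rate = decoy_anchor_rate,
                 multiword_trigger_rate = multiword_trigger_rate,
                 inv = inv, seed = seed),
            class = "generator_config")
}

gen_vocab <- function(config) {
  types <- all_types(config$inv)
  trig <- lapply(stats::setNames(types, types), function(t) {
    sprintf("%s_%d", tolower(substr(gsub("_", "", t), 1, 4)),
            seq_len(config$triggers_per_type))
  })
  list(proteins = sprintf("PROT%d", seq_len(config$n_protein_names)),
       triggers = trig,
       ambiguous = sprintf("trigamb%d", seq_len(config$n_ambiguous_triggers)),
       filler = sprintf("w%d", seq_len(config$n_filler)),
       decoys = sprintf("decoy%d", 1:8))
}

#' Generate a synthetic standoff corpus
#'
#' @param config A [generator_config()].
#' @return A named list of [event_document()]s (class `event_corpus`), each
#'   carrying its token table in `$tokens`. An attribute `manifest` records
#'   realized statistics (non-projective document fraction, event counts).
#' @export
generate_corpus <- function(config) {
  vocab <- gen_vocab(config)
  docs <- with_seed(config$seed, {
    lapply(seq_len(config$n_docs), function(d) {
      gen_document(sprintf("synth%04d", d), config, vocab)
    })
  })
  names(docs) <- vapply(docs, `[[`, "", "doc_id")
  crossings <- vapply(docs, function(doc) {
    crossing_count(events_to_graph(doc, inv = config$inv))
  }, integer(1))
  structure(docs, class = "event_corpus",
            manifest = list(
              n_docs = length(docs),
              nonprojective_doc_fraction = mean(crossings > 0),
              total_events = sum(vapply(docs, function(d) length(d$events),
                                        integer(1))),
              seed = config$seed))
}

# One document: a single sentence of sequential event groups (plus an
# optional injected crossing motif and decoy anchors), padded with filler.
gen_document <- function(doc_id, config, vocab) {
  sent <- new_sentence_builder()
  inv <- config$inv
  pick_trigger_word <- function(type) {
    if (stats::runif(1) < config$trigger_ambiguity) {
      sample(vocab$ambiguous, 1)
    } else {
      sample(vocab$triggers[[type]], 1)
    }
  }

  add_trigger <- function(type) {
    word <- pick_trigger_word(type)
    if (stats::runif(1) < config$multiword_trigger_rate) {
      i1 <- sent$add_token(sample(vocab$filler, 1), "OTHER", head = 0L)
      i2 <- sent$add_token(word, "CANDIDATE_ANCHOR", head = 1L)
      sent$add_trigger(type, from = i1, to = i2, head = i2)
    } else {
      i <- sent$add_token(word, "CANDIDATE_ANCHOR", head = 1L)
      sent$add_trigger(type, from = i, to = i, head = i)
    }
  }
  add_protein <- function() {
    i <- sent$add_token(sample(vocab$proteins, 1), "PROTEIN", head = 1L)
    sent$add_protein(i)
  }

  # Build one event group; returns the id of its top event.
  gen_group <- function(type, depth) {
    if (type %in% inv$binding_types) {
      tr <- add_trigger(type)
      p1 <- add_protein()
      themes <- p1
      if (stats::runif(1) < config$binding_multitheme_prob) {
        themes <- c(themes, add_protein())
      }
      sent$add_event(type, tr, themes = themes)
    } else if (type %in% inv$regulation_types) {
      tr <- add_trigger(type)
      theme <- if (depth < 2 && stats::runif(1) < config$regulation_nesting_prob) {
        sub_type <- sample_type(config)
        gen_group(sub_type, depth + 1)
      } else {
        add_protein()
      }
      cause <- if (type %in% inv$cause_licensed_types &&
                   stats::runif(1) < config$cause_prob) add_protein() else NULL
      sent$add_event(type, tr, themes = theme, causes = cause)
    } else {
      tr <- add_trigger(type)
      sent$add_event(type, tr, themes = add_protein())
    }
  }

  # Canonical crossing construction: a regulation whose CAUSE is an event
  # interleaved with its THEME — token order [ts, tr, pa, tb, pb] gives
  # arcs ts->pa and tr->tb that cross. Every node has a single parent, so
  # the crossing survives the tree projection too.
  gen_crossing_motif <- function() {
    simple_pool <- intersect(names(config$type_distribution), inv$simple_types)
    reg_pool <- intersect(names(config$type_distribution),
                          inv$cause_licensed_types)
    bind_pool <- intersect(names(config$type_distribution), inv$binding_types)
    st <- sample(simple_pool, 1); rt <- sample(reg_pool, 1)
    bt <- if (length(bind_pool)) sample(bind_pool, 1) else sample(simple_pool, 1)
    ts <- add_trigger(st)
    tr <- add_trigger(rt)
    pa <- add_protein()
    tb <- add_trigger(bt)
    pb <- add_protein()
    es <- sent$add_event(st, ts, themes = pa)
    eb <- sent$add_event(bt, tb, themes = pb)
    sent$add_event(rt, tr, themes = eb, causes = es)
  }

  n_groups <- sample(seq_along(config$groups_per_doc), 1,
                     prob = config$groups_per_doc)
  inject <- stats::runif(1) < config$rho
  cross_at <- if (inject) sample(n_groups + 1L, 1) else 0L
  for (gi in seq_len(n_groups + as.integer(inject))) {
    if (gi > 1) sent$add_token(sample(vocab$filler, 1), "OTHER", head = 1L)
    if (gi == cross_at) gen_crossing_motif() else {
      gen_group(sample_type(config), 1)
    }
  }
  if (stats::runif(1) < config$decoy_anchor_rate) {
    sent$add_token(sample(vocab$decoys, 1), "CANDIDATE_ANCHOR", head = 1L)
  }
  while (sent$n_tokens() < config$tokens_per_sentence) {
    sent$add_token(sample(vocab$filler, 1), "OTHER", head = 1L)
  }
  sent$build(doc_id)
}

sample_type <- function(config) {
  sample(names(config$type_distribution), 1, prob = config$type_distribution)
}

# Mutable sentence accumulator used by the generator.
new_sentence_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$words <- character(); env$kind <- character(); env$head <- integer()
  env$prot <- list(); env$trig <- list(); env$events <- list()

  add_token <- function(word, kind, head = 1L) {
    env$words <- c(env$words, word)
    env$kind <- c(env$kind, kind)
    env$head <- c(env$head, head)
    length(env$words) - 1L  # 0-based index
  }
  add_protein <- function(tok) {
    id <- sprintf("T%d", length(env$prot) + 1L)
    env$prot[[length(env$prot) + 1L]] <- list(id = id, tok = tok)
    id
  }
  add_trigger <- function(type, from, to, head) {
    id <- sprintf("G%d", length(env$trig) + 1L)
    env$trig[[length(env$trig) + 1L]] <-
      list(id = id, type = type, from = from, to = to, head = head)
    id
  }
  add_event <- function(type, trigger, themes, causes = NULL) {
    id <- sprintf("E%d", length(env$events) + 1L)
    env$events[[length(env$events) + 1L]] <-
      list(id = id, type = type, trigger = trigger,
           args = data.frame(
             role = c(rep("THEME", length(themes)),
                      rep("CAUSE", length(causes))),
             target = c(themes, causes), stringsAsFactors = FALSE))
    id
  }
  build <- function(doc_id) {
    words <- env$words
    ends <- cumsum(nchar(words) + 1L) - 1L
    starts <- ends - nchar(words)
    text <- paste(words, collapse = " ")
    tok_span <- function(from, to) c(starts[from + 1L], ends[to + 1L])
    proteins <- do.call(rbind, lapply(env$prot, function(p) {
      sp <- tok_span(p$tok, p$tok)
      data.frame(id = p$id, type = "Protein", start = sp[1], end = sp[2],
                 text = words[p$tok + 1L], stringsAsFactors = FALSE)
    })) %||% empty_mentions()
    triggers <- do.call(rbind, lapply(env$trig, function(tr) {
      sp <- tok_span(tr$from, tr$to)
      data.frame(id = tr$id, type = tr$type, start = sp[1], end = sp[2],
                 text = substr(text, sp[1] + 1L, sp[2]),
                 stringsAsFactors = FALSE)
    })) %||% empty_mentions()
    tokens <- data.frame(index = seq_along(words) - 1L, start = starts,
                         end = ends, text = words, kind = env$kind,
                         head = env$head, sentence = 1L,
                         stringsAsFactors = FALSE)
    event_document(doc_id, text, proteins, triggers, env$events,
                   tokens = tokens)
  }
  list(add_token = add_token, add_protein = add_protein,
       add_trigger = add_trigger, add_event = add_event,
       n_tokens = function() length(env$words), build = build)
}

# Corruption -----------------------------------------------------------------

#' Corruption configuration for simulated base-model output
#'
#' [corrupt_corpus()] degrades a gold corpus into the output of a base
#' model of stated quality: anchors are missed or type-confused, argument
#' arcs are dropped or hallucinated, trigger spans are jittered. The
#' corrupted corpus stands in for a real extractor's predictions when
#' testing stacking and combination.
#'
#' @param anchor_miss_rate Probability a trigger (with all its events) is
#'   dropped.
#' @param type_confusion_rate Probability a trigger's event type is replaced
#'   by a uniformly drawn other type (CAUSE arguments are dropped when the
#'   new type is not cause-licensed).
#' @param arc_miss_rate Probability an individual argument arc is dropped
#'   (events losing their last THEME are dropped).
#' @param arc_add_rate Probability an event gains a spurious THEME to a
#'   random unused protein.
#' @param span_jitter_rate Probability a trigger span is widened by one
#'   token to the left.
#' @param seed RNG seed.
#' @return Object of class `corruption_config`.
#' @export
corruption_config <- function(anchor_miss_rate = 0.1,
                              type_confusion_rate = 0.1,
                              arc_miss_rate = 0.1, arc_add_rate = 0.05,
                              span_jitter_rate = 0.1, seed = 1) {
  rates <- c(anchor_miss_rate, type_confusion_rate, arc_miss_rate,
             arc_add_rate, span_jitter_rate)
  if (any(rates < 0 | rates > 1)) stop_validation("rates must lie in [0,1]")
  structure(list(anchor_miss_rate = anchor_miss_rate,
                 type_confusion_rate = type_confusion_rate,
                 arc_miss_rate = arc_miss_rate, arc_add_rate = arc_add_rate,
                 span_jitter_rate = span_jitter_rate, seed = seed),
            class = "corruption_config")
}

#' Corrupt a gold corpus into simulated base-model predictions
#'
#' @param gold A gold corpus.
#' @param config A [corruption_config()].
#' @param inv A [type_inventory()].
#' @return A corpus of valid standoff documents with degraded annotations.
#' @export
corrupt_corpus <- function(gold, config, inv = type_inventory("ge")) {
  out <- with_seed(config$seed, {
    lapply(gold, function(doc) corrupt_document(doc, config, inv))
  })
  names(out) <- names(gold)
  structure(out, class = "event_corpus")
}

corrupt_document <- function(doc, config, inv) {
  triggers <- doc$triggers
  events <- doc$events
  drop_ids <- character()

  # anchor misses: drop trigger + its events
  for (tid in triggers$id) {
    if (stats::runif(1) < config$anchor_miss_rate) {
      drop_ids <- c(drop_ids,
                    vapply(Filter(function(e) e$trigger == tid, events),
                           `[[`, "", "id"))
    }
  }
  # type confusion (per trigger, applied to the trigger and its events)
  types <- all_types(inv)
  for (k in seq_len(nrow(triggers))) {
    if (stats::runif(1) < config$type_confusion_rate) {
      new_type <- sample(setdiff(types, triggers$type[k]), 1)
      old <- triggers$id[k]
      triggers$type[k] <- new_type
      events <- lapply(events, function(ev) {
        if (ev$trigger == old) {
          ev$type <- new_type
          if (!new_type %in% inv$cause_licensed_types) {
            ev$args <- ev$args[ev$args$role != "CAUSE", , drop = FALSE]
          }
          if (new_type %in% inv$simple_types && sum(ev$args$role == "THEME") > 1) {
            first_theme <- which(ev$args$role == "THEME")[1]
            ev$args <- ev$args[c(first_theme, which(ev$args$role != "THEME")), ,
                               drop = FALSE]
          }
        }
        ev
      })
    }
  }
  # arc misses and additions
  events <- lapply(events, function(ev) {
    if (ev$id %in% drop_ids) return(ev)
    keep <- stats::runif(nrow(ev$args)) >= config$arc_miss_rate
    ev$args <- ev$args[keep, , drop = FALSE]
    if (stats::runif(1) < config$arc_add_rate &&
        !ev$type %in% inv$simple_types) {
      unused <- setdiff(doc$proteins$id, ev$args$target)
      if (length(unused) && !(ev$type %in% inv$regulation_types &&
                              any(ev$args$role == "THEME"))) {
        ev$args <- rbind(ev$args,
                         data.frame(role = "THEME", target = sample(unused, 1)))
      }
    }
    ev
  })
  themeless <- vapply(events, function(ev) !any(ev$args$role == "THEME"),
                      logical(1))
  drop_ids <- c(drop_ids, vapply(events[themeless], `[[`, "", "id"))

  # span jitter: widen trigger one token leftwards
  for (k in seq_len(nrow(triggers))) {
    if (stats::runif(1) < config$span_jitter_rate) {
      prefix <- substr(doc$text, 1, triggers$start[k] - 1L)
      m <- gregexpr("\\S+", prefix)[[1]]
      if (m[1] != -1L) {
        new_start <- as.integer(m[length(m)]) - 1L
        triggers$start[k] <- new_start
        triggers$text[k] <- span_text(doc$text, new_start, triggers$end[k])
      }
    }
  }

  tmp <- event_document(doc$doc_id, doc$text, doc$proteins, triggers, events,
                        doc$extra, doc$tokens, validate = FALSE)
  drop_events(tmp, unique(drop_ids))
}

#' Token-level stacked-prediction view of a prediction document
#'
#' Converts a prediction document into the form the stacking features
#' consume: `h`, the predicted event type per anchor token (absent = no
#' anchor there), and `arcs`, the predicted (source token, target token,
#' role) triples.
#'
#' @param doc A prediction [event_document()].
#' @param tokens Token table (defaults to `doc$tokens`).
#' @param system System tag (e.g. `"1P"`).
#' @param inv A [type_inventory()].
#' @return Object of class `stacked_prediction`.
#' @export
as_stacked_prediction <- function(doc, tokens = doc$tokens, system = "S",
                                  inv = type_inventory("ge")) {
  g <- events_to_graph(doc, tokens = tokens, inv = inv)
  h <- stats::setNames(g$labels$type, g$labels$index)
  structure(list(system = system, h = h, arcs = g$edges),
            class = "stacked_prediction")
}
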