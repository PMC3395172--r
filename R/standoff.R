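#' Construct a biomedical event document
#'
#' An `event_document` bundles the content of one BioNLP standoff triple:
#' the raw text, the given protein mentions (`.a1`), and the triggers and
#' events (`.a2`). Character offsets are 0-based and half-open, per the
#' standoff convention, so the surface string of a span `[start, end)` is
#' `substr(text, start + 1, end)`.
#'
#' @param doc_id Document identifier (the file basename).
#' @param text Document text.
#' @param proteins data.frame with columns `id`, `type`, `start`, `end`,
#'   `text` — the given entity mentions.
#' @param triggers data.frame with the same columns — event anchors; `type`
#'   is the event type anchored there.
#' @param events list of event records, each a list with `id`, `type`,
#'   `trigger` (a trigger id) and `args`, a data.frame with columns `role`
#'   (`"THEME"` or `"CAUSE"`) and `target` (a protein or event id). An
#'   optional `extra_args` character vector carries unparsed argument text
#'   (e.g. Site arguments) verbatim.
#' @param extra Character vector of opaque pass-through `.a2` lines
#'   (modifications, equivalences) that are preserved but never interpreted.
#' @param tokens Optional token table (see [read_token_table()]).
#' @param validate Check all invariants (default `TRUE`).
#' @return An object of class `event_document`.
#' @export
#' @examples
#' doc <- event_document("d1", "STAT1 binds STAT2",
#'   proteins = data.frame(id = c("T1", "T2"), type = "Protein",
#'                         start = c(0L, 12L), end = c(5L, 17L),
#'                         text = c("STAT1", "STAT2")),
#'   triggers = data.frame(id = "T3", type = "Binding",
#'                         start = 6L, end = 11L, text = "binds"),
#'   events = list(list(id = "E1", type = "Binding", trigger = "T3",
#'                      args = data.frame(role = c("THEME", "THEME"),
#'                                        target = c("T1", "T2")))))
event_document <- function(doc_id, text, proteins = empty_mentions(),
                           triggers = empty_mentions(), events = list(),
                           extra = character(), tokens = NULL,
                           validate = TRUE) {
  events <- lapply(events, function(ev) {
    ev$args$role <- as.character(ev$args$role)
    ev$args$target <- as.character(ev$args$target)
    ev$extra_args <- ev$extra_args %||% character()
    ev
  })
  doc <- structure(list(doc_id = doc_id, text = text,
                        proteins = normalize_mentions(proteins),
                        triggers = normalize_mentions(triggers),
                        events = events, extra = extra, tokens = tokens),
                   class = "event_document")
  if (validate) validate_document(doc)
  doc
}

empty_mentions <- function() {
  data.frame(id = character(), type = character(), start = integer(),
             end = integer(), text = character(), stringsAsFactors = FALSE)
}

normalize_mentions <- function(m) {
  m <- as.data.frame(m, stringsAsFactors = FALSE)
  if (nrow(m) == 0L) return(empty_mentions())
  m$id <- as.character(m$id)
  m$type <- as.character(m$type)
  m$start <- as.integer(m$start)
  m$end <- as.integer(m$end)
  m$text <- as.character(m$text)
  rownames(m) <- NULL
  m[, c("id", "type", "start", "end", "text")]
}

#' @export
print.event_document <- function(x, ...) {
  cat(sprintf("<event_document %s: %d chars, %d proteins, %d triggers, %d events>\n",
              x$doc_id, nchar(x$text), nrow(x$proteins), nrow(x$triggers),
              length(x$events)))
  invisible(x)
}

span_text <- function(text, start, end) substring(text, start + 1L, end)

#' Validate an event document
#'
#' Checks all structural invariants: unique ids, spans inside the text whose
#' substring equals the recorded surface string, resolvable trigger and
#' argument references, event type equal to its trigger's type, and acyclic
#' event-to-event references.
#'
#' @param doc An [event_document()].
#' @return `doc`, invisibly; signals a classed validation error otherwise.
#' @export
validate_document <- function(doc) {
  ids <- c(doc$proteins$id, doc$triggers$id, vapply(doc$events, `[[`, "", "id"))
  if (anyDuplicated(ids)) {
    stop_validation("document %s: duplicate id '%s'", doc$doc_id,
                    ids[duplicated(ids)][1])
  }
  n <- nchar(doc$text)
  for (m in list(doc$proteins, doc$triggers)) {
    if (nrow(m) == 0L) next
    bad <- m$start < 0L | m$end <= m$start | m$end > n
    if (any(bad)) {
      stop_validation("document %s: span [%d,%d) of %s out of bounds",
                      doc$doc_id, m$start[bad][1], m$end[bad][1], m$id[bad][1])
    }
    got <- span_text(doc$text, m$start, m$end)
    if (any(got != m$text)) {
      i <- which(got != m$text)[1]
      stop_validation("document %s: %s text '%s' != span text '%s'",
                      doc$doc_id, m$id[i], m$text[i], got[i])
    }
  }
  trig_type <- stats::setNames(doc$triggers$type, doc$triggers$id)
  ev_ids <- vapply(doc$events, `[[`, "", "id")
  known <- c(doc$proteins$id, doc$triggers$id, ev_ids)
  for (ev in doc$events) {
    if (!ev$trigger %in% doc$triggers$id) {
      stop_validation("document %s: event %s references undefined trigger %s",
                      doc$doc_id, ev$id, ev$trigger)
    }
    if (trig_type[[ev$trigger]] != ev$type) {
      stop_validation("document %s: event %s type %s != trigger type %s",
                      doc$doc_id, ev$id, ev$type, trig_type[[ev$trigger]])
    }
    dangling <- setdiff(ev$args$target, known)
    if (length(dangling)) {
      stop_validation("document %s: event %s references undefined id %s",
                      doc$doc_id, ev$id, dangling[1])
    }
    bad_role <- setdiff(ev$args$role, c("THEME", "CAUSE"))
    if (length(bad_role)) {
      stop_validation("document %s: event %s has unsupported role %s",
                      doc$doc_id, ev$id, bad_role[1])
    }
  }
  if (is.null(event_topo_order(doc$events))) {
    stop_validation("document %s: cyclic event references", doc$doc_id)
  }
  invisible(doc)
}

# Topological order of events (arguments before the events that use them).
# Returns NULL on a cycle.
event_topo_order <- function(events) {
  ev_ids <- vapply(events, `[[`, "", "id")
  idx <- stats::setNames(seq_along(events), ev_ids)
  deps <- lapply(events, function(ev) {
    unname(idx[intersect(ev$args$target, ev_ids)])
  })
  state <- integer(length(events))  # 0 unseen, 1 on stack, 2 done
  order <- integer(0)
  visit <- function(i) {
    if (state[i] == 1L) return(FALSE)
    if (state[i] == 2L) return(TRUE)
    state[i] <<- 1L
    for (d in deps[[i]]) if (!visit(d)) return(FALSE)
    state[i] <<- 2L
    order <<- c(order, i)
    TRUE
  }
  for (i in seq_along(events)) if (!visit(i)) return(NULL)
  order
}

# Standoff parsing -----------------------------------------------------------

parse_t_line <- function(line, lineno, file) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) < 2L) {
    stop_parse("%s line %d: malformed T record '%s'", file, lineno, line)
  }
  head <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
  if (length(head) != 3L || grepl(";", parts[2], fixed = TRUE)) {
    stop_parse("%s line %d: unsupported span syntax '%s'", file, lineno, parts[2])
  }
  list(id = parts[1], type = head[1],
       start = as.integer(head[2]), end = as.integer(head[3]),
       text = if (length(parts) >= 3L) parts[3] else "")
}

parse_e_line <- function(line, lineno, file) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) < 2L) {
    stop_parse("%s line %d: malformed E record '%s'", file, lineno, line)
  }
  fields <- strsplit(trimws(parts[2]), " +")[[1]]
  ht <- strsplit(fields[1], ":", fixed = TRUE)[[1]]
  if (length(ht) != 2L) {
    stop_parse("%s line %d: malformed event head '%s'", file, lineno, fields[1])
  }
  roles <- character(0); targets <- character(0); extra_args <- character(0)
  for (f in fields[-1]) {
    rt <- strsplit(f, ":", fixed = TRUE)[[1]]
    if (length(rt) != 2L) {
      stop_parse("%s line %d: malformed argument '%s'", file, lineno, f)
    }
    role <- toupper(rt[1])
    if (grepl("^THEME[0-9]*$", role)) {
      roles <- c(roles, "THEME"); targets <- c(targets, rt[2])
    } else if (role == "CAUSE") {
      roles <- c(roles, "CAUSE"); targets <- c(targets, rt[2])
    } else {
      extra_args <- c(extra_args, f)  # Site etc.: pass through untouched
    }
  }
  list(id = parts[1], type = ht[1], trigger = ht[2],
       args = data.frame(role = roles, target = targets,
                         stringsAsFactors = FALSE),
       extra_args = extra_args)
}

#' Read one standoff document from in-memory file contents
#'
#' Parses BioNLP shared-task standoff syntax: `.a1` holds given entity
#' (`T`) records, `.a2` holds trigger `T` records and event `E` records.
#' Numbered THEME roles (`Theme2`, `Theme3`, ...) are normalized to `THEME`
#' with order preserved. Duplicate triggers with identical span and type are
#' merged into one canonical trigger. Modification and other non-`T`/`E`
#' lines are kept verbatim in `$extra`.
#'
#' @param doc_id Document identifier.
#' @param txt Text-file content (a single string).
#' @param a1 `.a1` content (string; may be empty).
#' @param a2 `.a2` content (string; may be empty).
#' @return A validated [event_document()].
#' @export
read_standoff <- function(doc_id, txt, a1 = "", a2 = "") {
  split_lines <- function(x) {
    ls <- strsplit(x, "\n", fixed = TRUE)[[1]]
    ls[nzchar(ls)]
  }
  a1_lines <- split_lines(a1)
  prot_rows <- list()
  for (i in seq_along(a1_lines)) {
    line <- a1_lines[i]
    if (!startsWith(line, "T")) stop_parse(".a1 line %d: expected T record", i)
    prot_rows[[i]] <- parse_t_line(line, i, ".a1")
  }
  proteins <- do.call(rbind, lapply(prot_rows, as.data.frame)) %||% empty_mentions()

  trig_rows <- list(); ev_rows <- list(); extra <- character()
  a2_lines <- split_lines(a2)
  for (i in seq_along(a2_lines)) {
    line <- a2_lines[i]
    if (startsWith(line, "T")) {
      trig_rows[[length(trig_rows) + 1L]] <- parse_t_line(line, i, ".a2")
    } else if (startsWith(line, "E")) {
      ev_rows[[length(ev_rows) + 1L]] <- parse_e_line(line, i, ".a2")
    } else {
      extra <- c(extra, line)
    }
  }
  triggers <- do.call(rbind, lapply(trig_rows, as.data.frame)) %||% empty_mentions()

  # Canonicalize: merge duplicate triggers sharing span + type.
  if (nrow(triggers) > 0L) {
    key <- paste(triggers$type, triggers$start, triggers$end)
    keep <- !duplicated(key)
    remap <- stats::setNames(triggers$id[keep][match(key, key[keep])], triggers$id)
    triggers <- triggers[keep, , drop = FALSE]
    ev_rows <- lapply(ev_rows, function(ev) {
      if (ev$trigger %in% names(remap)) ev$trigger <- remap[[ev$trigger]]
      ev
    })
  }
  doc <- event_document(doc_id, txt, proteins, triggers, ev_rows, extra)
  doc
}

# Standoff writing -----------------------------------------------------------

#' Serialize an event document to standoff strings
#'
#' Emits `.a1` and `.a2` content. Triggers are renumbered after the highest
#' given-entity number in span order; events are renumbered `E1..En` in
#' topological order (arguments before the events that use them) so output
#' is deterministic. Multi-THEME events serialize their themes as
#' `Theme`, `Theme2`, ... Pass-through lines are appended unchanged.
#'
#' @param doc A validated [event_document()].
#' @return A list with elements `a1` and `a2` (single strings, possibly "").
#' @export
write_standoff <- function(doc) {
  validate_document(doc)
  fmt_t <- function(m) sprintf("%s\t%s %d %d\t%s", m$id, m$type, m$start, m$end, m$text)

  a1 <- if (nrow(doc$proteins)) paste0(paste(apply_rows(doc$proteins, fmt_t),
                                             collapse = "\n"), "\n") else ""

  # Renumber triggers deterministically after the given entities.
  tn <- suppressWarnings(as.integer(sub("^T", "", doc$proteins$id)))
  base <- if (length(tn) && !anyNA(tn)) max(tn) else nrow(doc$proteins)
  trig <- doc$triggers
  if (nrow(trig)) {
    ord <- order(trig$start, trig$end, trig$type)
    trig <- trig[ord, , drop = FALSE]
    trig_map <- stats::setNames(sprintf("T%d", base + seq_len(nrow(trig))), trig$id)
    trig$id <- unname(trig_map[trig$id])
  } else {
    trig_map <- character()
  }

  topo <- event_topo_order(doc$events) %||% seq_along(doc$events)
  events <- doc$events[topo]
  ev_map <- stats::setNames(sprintf("E%d", seq_along(events)),
                            vapply(events, `[[`, "", "id"))
  remap <- function(id) {
    if (id %in% names(ev_map)) ev_map[[id]]
    else if (id %in% names(trig_map)) trig_map[[id]]
    else id
  }
  ev_lines <- vapply(seq_along(events), function(k) {
    ev <- events[[k]]
    theme_n <- 0L
    args <- vapply(seq_len(nrow(ev$args)), function(j) {
      role <- ev$args$role[j]
      lab <- if (role == "THEME") {
        theme_n <<- theme_n + 1L
        if (theme_n == 1L) "Theme" else sprintf("Theme%d", theme_n)
      } else "Cause"
      sprintf("%s:%s", lab, remap(ev$args$target[j]))
    }, character(1))
    paste0(sprintf("E%d\t%s:%s", k, ev$type, remap(ev$trigger)),
           if (length(args) || length(ev$extra_args)) " " else "",
           paste(c(args, ev$extra_args), collapse = " "))
  }, character(1))

  a2_lines <- c(if (nrow(trig)) apply_rows(trig, fmt_t), ev_lines, doc$extra)
  a2 <- if (length(a2_lines)) paste0(paste(a2_lines, collapse = "\n"), "\n") else ""
  list(a1 = a1, a2 = a2)
}

apply_rows <- function(df, f) {
  vapply(seq_len(nrow(df)), function(i) f(df[i, , drop = FALSE]), character(1))
}

# Corpus IO ------------------------------------------------------------------

#' Read a directory of standoff triples
#'
#' Expects `<id>.txt`, `<id>.a1`, `<id>.a2` (the annotation files may be
#' absent, read as empty) and optionally `<id>.tok.tsv` token tables.
#'
#' @param dir Directory path.
#' @return A named list of [event_document()]s (class `event_corpus`).
#' @export
read_corpus <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (!length(txts)) stop_usage("no .txt files found in %s", dir)
  docs <- lapply(txts, function(path) {
    id <- sub("\\.txt$", "", basename(path))
    read_file <- function(ext) {
      p <- file.path(dir, paste0(id, ext))
      if (file.exists(p)) paste(readLines(p, warn = FALSE), collapse = "\n") else ""
    }
    doc <- read_standoff(id, paste(readLines(path, warn = FALSE), collapse = "\n"),
                         read_file(".a1"), read_file(".a2"))
    tok <- file.path(dir, paste0(id, ".tok.tsv"))
    if (file.exists(tok)) doc$tokens <- read_token_table(tok)
    doc
  })
  names(docs) <- vapply(docs, `[[`, "", "doc_id")
  structure(docs, class = "event_corpus")
}

#' Write a corpus of documents as standoff triples
#'
#' @param corpus Named list of [event_document()]s.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (doc in corpus) {
    out <- write_standoff(doc)
    writeLines(doc$text, file.path(dir, paste0(doc$doc_id, ".txt")), sep = "\n")
    cat(out$a1, file = file.path(dir, paste0(doc$doc_id, ".a1")))
    cat(out$a2, file = file.path(dir, paste0(doc$doc_id, ".a2")))
    if (!is.null(doc$tokens)) {
      write_token_table(doc$tokens, file.path(dir, paste0(doc$doc_id, ".tok.tsv")))
    }
  }
  invisible(dir)
}

#' @export
print.event_corpus <- function(x, ...) {
  cat(sprintf("<event_corpus: %d documents, %d events>\n", length(x),
              sum(vapply(x, function(d) length(d$events), integer(1)))))
  invisible(x)
}

# Token tables ---------------------------------------------------------------

#' Read or write a token table sidecar
#'
#' Token tables carry the tokenization a document was generated with:
#' columns `index` (0-based), `start`, `end` (character offsets), `text`,
#' `kind` (`PROTEIN`, `CANDIDATE_ANCHOR` or `OTHER`), `head` (1 marks the
#' head token of a multiword annotation span) and `sentence` (1-based).
#'
#' @param path TSV file path.
#' @return data.frame of tokens.
#' @export
read_token_table <- function(path) {
  tok <- utils::read.delim(path, stringsAsFactors = FALSE)
  tok$index <- as.integer(tok$index)
  tok$start <- as.integer(tok$start)
  tok$end <- as.integer(tok$end)
  tok$head <- as.integer(tok$head)
  if (is.null(tok$sentence)) tok$sentence <- 1L
  tok
}

#' @param tokens Token data.frame.
#' @rdname read_token_table
#' @export
write_token_table <- function(tokens, path) {
  utils::write.table(tokens, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Build a token table directly from whitespace-tokenized text where every
# annotation is single-token; used by tests and small examples.
tokens_from_text <- function(doc) {
  words <- strsplit(doc$text, " ", fixed = TRUE)[[1]]
  ends <- cumsum(nchar(words) + 1L) - 1L
  starts <- ends - nchar(words)
  kind <- rep("OTHER", length(words))
  for (i in seq_len(nrow(doc$proteins))) {
    kind[starts == doc$proteins$start[i]] <- "PROTEIN"
  }
  for (i in seq_len(nrow(doc$triggers))) {
    kind[starts == doc$triggers$start[i]] <- "CANDIDATE_ANCHOR"
  }
  data.frame(index = seq_along(words) - 1L, start = starts, end = ends,
             text = words, kind = kind, head = 1L, sentence = 1L,
             stringsAsFactors = FALSE)
}
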