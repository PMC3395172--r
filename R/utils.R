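# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Condition constructors used across the package
#'
#' Errors are signalled with classed conditions so callers and the CLI can map
#' them to exit codes: `eventstack_parse_error`, `eventstack_validation_error`,
#' `eventstack_usage_error`.
#' @noRd
stop_parse <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("eventstack_parse_error", "eventstack_error")))
}

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("eventstack_validation_error", "eventstack_error")))
}

stop_usage <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("eventstack_usage_error", "eventstack_error")))
}

# Run code under a local RNG state: seeds deterministically, restores the
# caller's .Random.seed afterwards so generators never perturb user RNG flow.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a stream index, staying < 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647
}

# Sparse feature/weight maps -------------------------------------------------

# Sparse features are plain named numeric vectors. Weights live in a hashed
# environment so lookups and online updates stay O(1) per key.

new_weights <- function() {
  list(w = new.env(hash = TRUE, parent = emptyenv()),
       u = new.env(hash = TRUE, parent = emptyenv()),  # averaging accumulator
       k = new.env(hash = TRUE, parent = emptyenv()))  # shared step counter
}

weights_get <- function(ws, keys) {
  if (length(keys) == 0L) return(numeric(0))
  vapply(keys, function(k) {
    v <- ws$w[[k]]
    if (is.null(v)) 0 else v
  }, numeric(1), USE.NAMES = FALSE)
}

weights_dot <- function(ws, feats) {
  if (length(feats) == 0L) return(0)
  sum(weights_get(ws, names(feats)) * unname(feats))
}

# w[key] += delta; u[key] += step * delta (for averaging).
weights_add <- function(ws, feats, scale, step = 0) {
  if (length(feats) == 0L || scale == 0) return(invisible(ws))
  keys <- names(feats)
  vals <- unname(feats) * scale
  for (idx in seq_along(keys)) {
    k <- keys[[idx]]
    ws$w[[k]] <- (ws$w[[k]] %||% 0) + vals[[idx]]
    if (step > 0) ws$u[[k]] <- (ws$u[[k]] %||% 0) + step * vals[[idx]]
  }
  invisible(ws)
}

# Averaged weights after K online steps: avg = w - u / K.
weights_average <- function(ws, total_steps) {
  out <- new_weights()
  for (k in ls(ws$w, all.names = TRUE)) {
    out$w[[k]] <- ws$w[[k]] - (ws$u[[k]] %||% 0) / total_steps
  }
  out
}

weights_as_vector <- function(ws) {
  keys <- sort(ls(ws$w, all.names = TRUE))
  stats::setNames(vapply(keys, function(k) ws$w[[k]], numeric(1)), keys)
}

weights_from_vector <- function(v) {
  ws <- new_weights()
  for (i in seq_along(v)) ws$w[[names(v)[i]]] <- unname(v[i])
  ws
}

# Feature accumulation: sum named numeric vectors (duplicate keys summed).
feats_sum <- function(...) {
  xs <- list(...)
  all <- unlist(xs)
  if (length(all) == 0L) return(stats::setNames(numeric(0), character(0)))
  tapply_keys <- tapply(unname(all), names(all), sum)
  stats::setNames(as.numeric(tapply_keys), names(tapply_keys))
}

# feats_sum(a, feats_scale(b, -1)) etc.
feats_scale <- function(f, s) {
  if (length(f) == 0L) return(f)
  stats::setNames(unname(f) * s, names(f))
}
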