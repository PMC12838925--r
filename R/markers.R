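#' Synthetic somatic marker configuration
#'
#' The marker stores one scalar valence per observed signature, updated by
#' `V <- clip(V + alpha * outcome, v_min, v_max)` after every visit, where
#' `outcome` is the oracle's +1/-1 label.
#'
#' @param alpha Evaluative learning rate, > 0. Default 0.1.
#' @param v_min,v_max Clip bounds of the valence scale. Fixed at -1 and +1
#'   in the reference setting.
#' @return An object of class `ssm_config`.
#' @export
ssm_config <- function(alpha = 0.1, v_min = -1, v_max = 1) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  stopifnot(v_min < v_max)
  structure(list(alpha = alpha, v_min = v_min, v_max = v_max),
            class = "ssm_config")
}

#' Threshold-agent configuration
#'
#' The decision rule is `reset` iff the current signature's valence is
#' strictly below `theta`, `keep` otherwise. `theta` encodes structural
#' risk aversion: values closer to 0 reset sooner on bad history.
#'
#' @param theta Decision threshold, normally within the valence range
#'   `[-1, 1]` (a warning is issued outside it). Default -0.5.
#' @return An object of class `agent_config`.
#' @export
agent_config <- function(theta = -0.5) {
  stopifnot(is.numeric(theta), length(theta) == 1L, !is.na(theta))
  if (theta < -1 || theta > 1) {
    warning("theta outside the valence range [-1, 1]; the rule degenerates")
  }
  structure(list(theta = theta), class = "agent_config")
}

#' Create an empty valence memory
#'
#' A mutable map from signature to scalar valence. Unseen signatures read
#' as exactly 0. Implemented as an environment so the per-step update is
#' in-place, mirroring the dictionary the agent carries through a run.
#'
#' @return An object of class `valence_memory`.
#' @export
valence_memory <- function() {
  structure(new.env(parent = emptyenv()), class = "valence_memory")
}

#' @export
print.valence_memory <- function(x, ...) {
  keys <- ls(x)
  cat(sprintf("<valence_memory: %d signature(s)>\n", length(keys)))
  if (length(keys)) {
    df <- valence_table(x)
    print(utils::head(df[order(df$valence), ], 10L), row.names = FALSE)
  }
  invisible(x)
}

#' Valence memory as a data frame
#'
#' @param memory A [valence_memory()].
#' @return A data frame with columns `signature` and `valence`, one row per
#'   observed signature, in lexicographic key order.
#' @export
valence_table <- function(memory) {
  keys <- sort(ls(memory))
  data.frame(signature = keys,
             valence = vapply(keys, function(k) memory[[k]], numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Look up the valence of a signature
#'
#' @param memory A [valence_memory()].
#' @param sig An integer signature vector (or its key string).
#' @return The stored valence, or exactly 0 for a signature never updated.
#' @export
get_valence <- function(memory, sig) {
  key <- if (is.character(sig)) sig else signature_key(sig)
  v <- memory[[key]]
  if (is.null(v)) 0 else v
}

#' Clipped incremental valence update
#'
#' Applies `V(sig) <- clip(V(sig) + alpha * outcome, v_min, v_max)` in
#' place. All other entries are untouched. Accumulation is plain double
#' precision; at the default `alpha = 0.1`, `theta = -0.5` a fresh
#' signature needs exactly 6 consecutive bad outcomes before the strict
#' threshold comparison trips (after 5 the stored value equals -0.5, which
#' keeps) — this boundary behaviour is part of the contract and is
#' asserted in the test suite.
#'
#' @param memory A [valence_memory()]; modified in place.
#' @param sig An integer signature vector (or key string).
#' @param outcome `+1` or `-1`.
#' @param config An [ssm_config()].
#' @return The updated valence, invisibly usable as a plain number.
#' @export
update_valence <- function(memory, sig, outcome, config = ssm_config()) {
  stopifnot(outcome %in% c(-1L, 1L))
  key <- if (is.character(sig)) sig else signature_key(sig)
  v <- get_valence(memory, key)
  v <- min(config$v_max, max(config$v_min, v + config$alpha * outcome))
  memory[[key]] <- v
  v
}

#' Threshold keep/reset decision
#'
#' @param valence A scalar valence.
#' @param config An [agent_config()].
#' @return `"reset"` iff `valence < theta` strictly, else `"keep"`.
#' @export
decide <- function(valence, config = agent_config()) {
  if (valence < config$theta) "reset" else "keep"
}

#' Serialize a valence memory to JSON
#'
#' Writes the map signature-key -> valence as a JSON object, so a run's
#' evaluative state can be inspected or resumed. `read_valence_memory()`
#' is its inverse.
#'
#' @param memory A [valence_memory()].
#' @param path File path.
#' @return `write_valence_memory()`: `path`, invisibly.
#'   `read_valence_memory()`: a [valence_memory()].
#' @export
write_valence_memory <- function(memory, path) {
  df <- valence_table(memory)
  vals <- as.list(stats::setNames(df$valence, df$signature))
  jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_valence_memory
#' @export
read_valence_memory <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  mem <- valence_memory()
  for (key in names(vals)) mem[[key]] <- as.numeric(vals[[key]])
  mem
}
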