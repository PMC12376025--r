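## Internal helpers: classed conditions, event log, seeded RNG scopes.

abort <- function(msg, class) {
  stop(structure(
    class = c(class, "autosas_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

io_error            <- function(msg) abort(msg, "autosas_io_error")
malformed_error     <- function(msg) abort(msg, "autosas_malformed_input_error")
config_error        <- function(msg) abort(msg, "autosas_config_error")
domain_error        <- function(msg) abort(msg, "autosas_domain_error")
insufficient_error  <- function(msg) abort(msg, "autosas_insufficient_data_error")

## Plain-text event log: one event per line, kept in a session buffer.
.log_env <- new.env(parent = emptyenv())
.log_env$events <- character(0)

log_event <- function(...) {
  line <- paste0(...)
  .log_env$events <- c(.log_env$events, line)
  if (isTRUE(getOption("autosas.verbose", FALSE))) message(line)
  invisible(line)
}

#' Retrieve or clear the session event log
#'
#' Every dropped data point, clipped value and convergence failure is logged
#' as one plain-text line tagged with the sample id.
#'
#' @param clear if `TRUE`, empty the log after returning it.
#' @return Character vector of log lines.
#' @export
sas_log <- function(clear = FALSE) {
  ev <- .log_env$events
  if (clear) .log_env$events <- character(0)
  ev
}

## Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

## Stable 32-bit-safe seed derived from a base seed and identifying strings.
derive_seed <- function(seed, ...) {
  s <- paste(..., collapse = "|")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 1048573
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
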