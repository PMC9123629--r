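# Classed conditions so callers (and the CLI) can tell user-input problems
# from internal failures.

abort_io <- function(message, ...) {
  abort(message, class = c("hubscreen_io_error", "hubscreen_error"), ...)
}

abort_parse <- function(message, ...) {
  abort(message, class = c("hubscreen_parse_error", "hubscreen_error"), ...)
}

abort_validation <- function(message, ...) {
  abort(message, class = c("hubscreen_validation_error", "hubscreen_error"), ...)
}

#' Regulatory action layer names
#'
#' The three regulatory modes an action map distinguishes.
#'
#' @return Character vector `c("activation", "inhibition", "expression")`.
#' @export
action_modes <- function() c("activation", "inhibition", "expression")

# Derive a per-network seed from a master seed; kept within 32-bit range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% .Machine$integer.max)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

check_string <- function(x, what) {
  if (!is_string(x) || !nzchar(x)) {
    abort_validation(sprintf("`%s` must be a single non-empty string.", what))
  }
  invisible(x)
}

# Wrap a pipeline stage so reader/validation failures carry stage context
# while keeping their condition class.
with_stage <- function(stage, expr) {
  tryCatch(
    expr,
    hubscreen_error = function(cnd) {
      cls <- intersect(
        class(cnd),
        c("hubscreen_io_error", "hubscreen_parse_error",
          "hubscreen_validation_error", "hubscreen_error")
      )
      abort(
        sprintf("[stage: %s] %s", stage, conditionMessage(cnd)),
        class = cls, parent = cnd
      )
    }
  )
}
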