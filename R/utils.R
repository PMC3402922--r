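# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# all identifier ordering in the package is C-locale radix order so that
# "select the first one among them" is reproducible across platforms
sort_ids <- function(x) sort(unique(as.character(x)), method = "radix")

first_id <- function(x) {
  x <- as.character(x)
  x[order(x, method = "radix")][1L]
}

order_ids <- function(...) order(..., method = "radix")

stop_validation <- function(msg, ...) {
  stop(structure(
    class = c("metalign_validation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  ))
}

check_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop_validation(msg, ...)
  invisible(TRUE)
}

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}
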