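# Classed conditions so callers (and the command-line wrapper) can map
# failure modes to exit codes without string matching.

sm_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "shellmorph_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

abort_usage <- function(msg, ...) sm_stop("shellmorph_usage_error", msg, ...)
abort_format <- function(msg, ...) sm_stop("shellmorph_format_error", msg, ...)
abort_degenerate <- function(msg, ...) sm_stop("shellmorph_degenerate_error", msg, ...)
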