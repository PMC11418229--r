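# Classed conditions used across the package.  Every user-facing failure is a
# condition inheriting from "gs_error" with a specific subclass so that the
# CLI (and tests) can branch on the failure kind rather than on message text.

gs_error <- function(class, message, data = list(), call = sys.call(-1)) {
  stop(structure(
    class = c(class, "gs_error", "error", "condition"),
    list(message = message, call = call, data = data)
  ))
}

gs_warning <- function(class, message, data = list()) {
  warning(structure(
    class = c(class, "gs_warning", "warning", "condition"),
    list(message = message, call = NULL, data = data)
  ))
}

# Debug-level notes (dropped edges, ignored tags).  Routed through message()
# so they land on stderr and can be suppressed wholesale.
gs_note <- function(...) {
  message("goseries: ", ...)
}
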