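# Structured error conditions. Every user-facing failure is signalled with a
# class so callers (and the HTTP router) can map it to a response without
# string-matching messages.

kghop_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "kghop_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

abort_schema_invalid <- function(message, ...) {
  kghop_abort(message, "kghop_schema_invalid", ...)
}

abort_unknown_element <- function(label, kind) {
  kghop_abort(
    sprintf("unknown %s label: '%s'", kind, label),
    "kghop_unknown_element", label = label, kind = kind
  )
}

abort_format <- function(message, file = NULL, line = NULL) {
  loc <- if (!is.null(file)) {
    if (!is.null(line)) sprintf(" [%s, line %d]", file, as.integer(line))
    else sprintf(" [%s]", file)
  } else ""
  kghop_abort(paste0(message, loc), "kghop_format_error", file = file, line = line)
}

abort_config <- function(message, ...) {
  kghop_abort(message, "kghop_config_error", ...)
}

abort_load <- function(message, ...) {
  kghop_abort(message, "kghop_load_error", ...)
}

abort_query_structure <- function(message) {
  kghop_abort(message, c("kghop_query_structure_error", "kghop_query_error"))
}

abort_unpinned_query <- function(message) {
  kghop_abort(message, c("kghop_unpinned_query_error", "kghop_query_error"))
}

abort_constraint <- function(message) {
  kghop_abort(message, c("kghop_constraint_error", "kghop_query_error"))
}

abort_spec <- function(message) {
  kghop_abort(message, "kghop_fixture_spec_error")
}
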