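#' @keywords internal
"_PACKAGE"

# Structured conditions: every user-facing failure carries a condition class
# (prefixed "tag_") so callers and tests can catch specific failure modes.

tag_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "tag_error")))
}

tag_assert <- function(ok, msg, class = "tag_parameter_error") {
  if (!isTRUE(ok)) tag_stop(msg, class)
  invisible(TRUE)
}
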