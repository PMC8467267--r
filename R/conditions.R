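# Classed conditions so callers (and tests) can distinguish failure modes
# without matching message text.

stop_cc <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "crashcausal_error")))
}

stop_domain    <- function(msg) stop_cc(msg, "cc_domain_error")
stop_malformed <- function(msg) stop_cc(msg, "cc_malformed_code")
stop_severity  <- function(msg) stop_cc(msg, "cc_invalid_severity")
stop_schema    <- function(msg) stop_cc(msg, "cc_schema_error")
stop_separation <- function(msg) stop_cc(msg, "cc_separation_error")
stop_ratio     <- function(msg) stop_cc(msg, "cc_undefined_ratio")

warn_cc <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "crashcausal_warning")))
}
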