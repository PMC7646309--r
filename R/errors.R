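# Typed condition helpers. Every error the package raises carries a class
# of the form "smdpair_error_<kind>" plus "smdpair_error", so callers (and
# the CLI exit-code mapping) can branch on the kind without string matching.

stop_smd <- function(kind, message, ...) {
  abort(message, class = c(paste0("smdpair_error_", kind), "smdpair_error"), ...)
}

stop_insufficient_data <- function(message, ...) stop_smd("insufficient_data", message, ...)
stop_zero_variance     <- function(message, ...) stop_smd("zero_variance", message, ...)
stop_invalid_input     <- function(message, ...) stop_smd("invalid_input", message, ...)
stop_invalid_family    <- function(message, ...) stop_smd("invalid_family", message, ...)
stop_invalid_df        <- function(message, ...) stop_smd("invalid_df", message, ...)
stop_formula_undefined <- function(message, ...) stop_smd("formula_undefined", message, ...)
stop_already_corrected <- function(message, ...) stop_smd("already_corrected", message, ...)
stop_missing_input     <- function(message, fields = character(), ...) {
  stop_smd("missing_input", message, fields = fields, ...)
}
stop_degenerate_resample <- function(message, ...) stop_smd("degenerate_resample", message, ...)
stop_template_incomplete <- function(message, fields = character(), ...) {
  stop_smd("template_incomplete", message, fields = fields, ...)
}
stop_percent_change <- function(message, ...) stop_smd("percent_change", message, ...)

check_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) || (finite && any(!is.finite(x)))) {
    stop_invalid_input(sprintf("`%s` must be a finite numeric value.", name))
  }
  invisible(x)
}
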