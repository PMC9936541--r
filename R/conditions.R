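# Classed conditions so callers can distinguish failure modes programmatically.

abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "amylokin_error")))
}

#' @keywords internal
stop_input <- function(msg, ...) abort(msg, "amylokin_input_error", ...)
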