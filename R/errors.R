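# Classed conditions so callers (and the CLI) can distinguish user
# configuration mistakes from problems in the data themselves.

ag_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "agreemix_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

ag_config_error <- function(msg) ag_stop(msg, "agreemix_config_error")
ag_data_error <- function(msg) ag_stop(msg, "agreemix_data_error")
ag_argument_error <- function(msg) ag_stop(msg, "agreemix_argument_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
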