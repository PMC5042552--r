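# Classed conditions so callers (and the CLI) can map failures to exit codes:
# configuration problems, malformed data, and model-fitting failures.

abort_config <- function(msg, ...) {
  abort(msg, class = "allogenomics_config_error", ...)
}

abort_data <- function(msg, ...) {
  abort(msg, class = "allogenomics_data_error", ...)
}

abort_model <- function(msg, ...) {
  abort(msg, class = "allogenomics_model_error", ...)
}

abort_contract <- function(msg, ...) {
  abort(msg, class = "allogenomics_contract_error", ...)
}
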