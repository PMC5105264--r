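# Classed conditions used throughout the pipeline so callers can react to
# the failure stage (configuration, file parsing, data integrity, or an
# empty/degenerate analysis) rather than matching on message text.

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("config_error", "genoconcord_error")))
}

stop_parse <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("parse_error", "genoconcord_error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("data_error", "genoconcord_error")))
}

stop_pipeline <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("pipeline_error", "genoconcord_error")))
}

stop_lookup <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("lookup_error", "genoconcord_error")))
}
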