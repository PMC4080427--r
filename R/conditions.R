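# Condition helpers: input/format problems vs infeasible parameter requests.
# The CLI maps these classes onto exit codes (2 and 3 respectively).

stop_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("tflogic_input_error", "tflogic_error")))
}

stop_infeasible <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("tflogic_infeasible_error", "tflogic_error")))
}
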