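# Classed conditions so callers can distinguish "the answer is undefined on
# this pixel population" from programming errors, and record gaps in sweeps.

stop_undefined <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("colocbench_undefined", "error", "condition"),
                 list(message = msg, call = call)))
}

stop_no_estimate <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("colocbench_no_estimate", "error", "condition"),
                 list(message = msg, call = call)))
}

stop_config <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("colocbench_config", "error", "condition"),
                 list(message = msg, call = call)))
}

# Evaluate a coefficient, mapping an undefined-result signal to NA so that
# sweeps can record the gap (e.g. AND cannot be measured at Fill% 0).
na_if_undefined <- function(expr) {
  tryCatch(expr, colocbench_undefined = function(e) NA_real_)
}
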