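# Classed error conditions so callers (and tests) can dispatch on failure mode
# rather than on message text.

swarm_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "swarmcorr_error"), call = call))
}

#' @noRd
swarm_warn <- function(msg, class = "swarmcorr_warning") {
  warning(warningCondition(msg, class = class))
}
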