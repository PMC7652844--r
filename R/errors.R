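# classed error helper: every package error carries class c(subclass, "relbeta_error")
stop_relbeta <- function(msg, subclass, ...) {
  stop(errorCondition(msg, ..., class = c(subclass, "relbeta_error", "error", "condition")))
}
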