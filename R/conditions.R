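# Classed conditions so callers (and tests) can branch on failure modes
# without string-matching messages. All inherit from "perfquant_error".

pq_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "perfquant_error")))
}

pq_check <- function(cond, class, msg, ...) {
  if (!isTRUE(cond)) pq_stop(class, msg, ...)
  invisible(TRUE)
}
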