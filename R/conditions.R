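# Classed conditions so callers (and tests) can distinguish failure modes
# programmatically instead of matching message text.

odorStop <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "odorDB_error")))
}

# "skip" signals: an analysis that declines to run (too few matched items,
# empty join, ...) rather than a malformed input.
odorSkip <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "odorDB_skip", "odorDB_error")))
}
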