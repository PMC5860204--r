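# Classed conditions so callers can catch specific failure modes
# (tested with expect_error(..., class = )).

snap_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "snapgrn_error")))
}

snap_warning <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "snapgrn_warning")))
}
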