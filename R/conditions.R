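# Structured error conditions. Every domain error carries a class
# "dyntexseg_<name>" (plus "dyntexseg_error") so callers can test for the
# specific failure with expect_error(..., class = ...).

stop_dts <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("dyntexseg_", class), "dyntexseg_error")))
}
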