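# Classed conditions so the command-line wrapper can map failures onto exit
# codes: usage errors (bad invocation, missing paths) vs data errors
# (malformed ontology/cluster/index/gold files, schema mismatches).

stop_usage <- function(msg) {
  stop(structure(
    class = c("sigcr_usage_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_data <- function(msg) {
  stop(structure(
    class = c("sigcr_data_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
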