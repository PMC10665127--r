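# Classed conditions so callers can distinguish failure modes programmatically.

sh_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "seedhull_error"), call = call))
}

sh_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "seedhull_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
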