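# internal validation helpers

is_scalar_num <- function(x, allow_inf = FALSE) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && (allow_inf || is.finite(x))
}

stop_unless <- function(cond, msg) {
  if (!isTRUE(cond)) {
    stop(errorCondition(msg, class = "senaccum_domain_error",
                        call = sys.call(-1)))
  }
  invisible(TRUE)
}
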