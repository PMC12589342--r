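# Shared constants and internal helpers (loaded first by collation order).

# Tissue-group vocabulary used throughout: normal lung, RUNX3-negative cancer,
# RUNX3-positive cancer.
TISSUE_GROUPS <- c("NOR", "RUNX3_Neg", "RUNX3_Pos")

`%||%` <- function(a, b) if (is.null(a)) b else a

.stop_tme <- function(msg, class = "tmeatlas_error", call. = FALSE) {
  stop(structure(
    class = c(class, "tmeatlas_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

.assert <- function(ok, msg, class = "tmeatlas_validation_error") {
  if (!isTRUE(ok)) .stop_tme(msg, class = class)
  invisible(TRUE)
}
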