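# Canonical timescale tags. The short forms are what the CLI flags use;
# both spellings are accepted anywhere a timescale is given. No unit
# conversion is ever performed: the tag travels with the data and the
# relaxation-time axis of the output inherits it.
TIMESCALES <- c(
  s = "seconds", ms = "milliseconds", us = "microseconds",
  seconds = "seconds", milliseconds = "milliseconds",
  microseconds = "microseconds"
)

normalize_timescale <- function(timescale) {
  if (!is.character(timescale) || length(timescale) != 1 ||
      !(timescale %in% names(TIMESCALES))) {
    abort(paste0(
      "`timescale` must be one of ",
      paste(unique(names(TIMESCALES)), collapse = ", "),
      ", not ", deparse(substitute(timescale)), " = ",
      deparse(timescale), "."
    ))
  }
  unname(TIMESCALES[[timescale]])
}

KERNEL_KINDS <- c(cpmg = "cpmg", ir = "ir", sr = "sr",
                  CPMG = "cpmg", IR = "ir", SR = "sr")

normalize_kernel_kind <- function(kind) {
  if (!is.character(kind) || length(kind) != 1 ||
      !(kind %in% names(KERNEL_KINDS))) {
    abort("`kind` must be one of \"cpmg\", \"ir\", \"sr\".")
  }
  unname(KERNEL_KINDS[[kind]])
}
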