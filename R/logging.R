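# Minimal leveled logger.  Every record-dropping or SNP-dropping step in the
# pipeline reports its count through hb_log() so a run can be audited against
# the input files.

.hb_levels <- c(DEBUG = 10L, INFO = 20L, WARN = 30L, NONE = 99L)

hb_log_threshold <- function() {
  lev <- toupper(getOption("herdblup.log_level", "INFO"))
  if (!lev %in% names(.hb_levels)) lev <- "INFO"
  .hb_levels[[lev]]
}

#' @keywords internal
hb_log <- function(msg, ..., level = "INFO") {
  if (.hb_levels[[level]] >= hb_log_threshold()) {
    message(sprintf("[%s] %s", level, sprintf(msg, ...)))
  }
  invisible(NULL)
}
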