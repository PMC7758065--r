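#' @importFrom stats median rbinom rexp rlnorm rmultinom runif var wilcox.test
#'   cmdscale cor dist p.adjust setNames quantile
#' @importFrom utils head read.delim write.table
#' @importFrom data.table := .N data.table as.data.table fread fwrite
#'   setnames setorder setkey shift copy
NULL

utils::globalVariables(c(
  ".N", "start", "end", "read_id", "gap_ok", "spliced", "unspliced",
  "ambiguous", "ih", "wi", "cigar"))

.LOG_LEVELS <- c(debug = 10L, info = 20L, warn = 30L, error = 40L)

#' Set the package log level
#'
#' Messages below the chosen level are suppressed.  All logging goes to
#' standard error so that tabular output on standard output stays clean.
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return the previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  old <- getOption("echoRNA.log_level", "info")
  options(echoRNA.log_level = level)
  invisible(old)
}

er_log <- function(level, ...) {
  cur <- getOption("echoRNA.log_level", "info")
  if (.LOG_LEVELS[[level]] >= .LOG_LEVELS[[cur]]) {
    message(sprintf("[%s] %s", level, paste0(..., collapse = "")))
  }
  invisible(NULL)
}

er_stop <- function(...) stop(sprintf(...), call. = FALSE)

#' Derive a stage seed from a master seed
#'
#' All randomness in a pipeline run flows from one master seed; per-stage
#' seeds are derived by fixed offsets so stages are independently
#' reproducible.  Result is kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param offset fixed non-negative stage offset.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(offset) * 9973) %% 2147483629)
}

# shared validation helpers ------------------------------------------------

check_unique <- function(ids, what) {
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    er_stop("duplicate %s id(s): %s", what,
            paste(unique(dup)[seq_len(min(5, length(unique(dup))))], collapse = ", "))
  }
  invisible(TRUE)
}

is_wholenumber <- function(x, tol = 1e-8) {
  all(abs(x - round(x)) < tol)
}
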