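#' @keywords internal
"_PACKAGE"

# Package-wide logging: messages go to stderr (via message()) and, when a log
# file has been set with wm_set_logfile(), are appended there too.
.wm_env <- new.env(parent = emptyenv())
.wm_env$logfile <- NULL

#' Direct wolfmove log messages to a file
#'
#' @param path File to append log lines to, or `NULL` to log to stderr only.
#' @return Previous log file path, invisibly.
#' @export
wm_set_logfile <- function(path = NULL) {
  old <- .wm_env$logfile
  .wm_env$logfile <- path
  invisible(old)
}

wm_log <- function(..., level = "INFO") {
  msg <- paste0("[", level, "] ", paste0(..., collapse = ""))
  message(msg)
  if (!is.null(.wm_env$logfile)) {
    cat(msg, "\n", sep = "", file = .wm_env$logfile, append = TRUE)
  }
  invisible(msg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wrap an angle into (-pi, pi].
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a <= -pi] <- pi
  a
}

stopifnot_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# md5 of an arbitrary R object through its canonical JSON form; used to stamp
# run manifests so reruns with an identical config are recognisable.
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tf)
  unname(tools::md5sum(tf))
}
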