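TRIAL_COLS <- c("subject", "group", "block", "trial", "type", "ssd_ms",
                "responded", "rt_ms", "outcome")

#' Read and write the standard trial table
#'
#' The trial table is tab-separated with header
#' `subject group block trial type ssd_ms responded rt_ms outcome`, missing
#' values as empty fields, times in milliseconds.
#'
#' @param trials a trial table data.frame.
#' @param path file path.
#' @return `read_trial_table` returns the data.frame;
#'   `write_trial_table` returns `path` invisibly.
#' @export
write_trial_table <- function(trials, path) {
  stopifnot(all(TRIAL_COLS %in% names(trials)))
  write.table(trials[, TRIAL_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, na.strings = "",
                    colClasses = c(subject = "character",
                                   group = "character", block = "integer",
                                   trial = "integer", type = "character",
                                   ssd_ms = "numeric", responded = "logical",
                                   rt_ms = "numeric", outcome = "character"),
                    stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRIAL_COLS, names(tab))
  if (length(missing_cols))
    stop("trial table at '", path, "' lacks columns: ",
         paste(missing_cols, collapse = ", "))
  tab
}

#' Validate a trial table against the schema
#'
#' Checks the header, column types and the per-row invariants of a trial
#' record: known trial types and outcomes, outcome consistent with type and
#' response flag, `rt_ms` present iff responded, non-negative SSD present
#' exactly on stop trials.
#'
#' @param x a data.frame or a path to a tab-separated trial table.
#' @return a data.frame of class `trial_validation` with one row per rule
#'   (`rule`, `violations`); attribute `valid` is `TRUE` when all counts are
#'   zero.
#' @export
validate_trial_table <- function(x) {
  tab <- if (is.character(x)) read_trial_table(x) else x
  missing_cols <- setdiff(TRIAL_COLS, names(tab))
  if (length(missing_cols))
    stop("trial table lacks columns: ", paste(missing_cols, collapse = ", "))
  go <- tab$type == "go"
  stop_t <- tab$type == "stop"
  rules <- c(
    "type in {go, stop}" = sum(!(go | stop_t)),
    "outcome in {go, signal-respond, signal-stop}" =
      sum(!tab$outcome %in% c("go", "signal-respond", "signal-stop")),
    "go trials have outcome 'go'" = sum(go & tab$outcome != "go"),
    "stop outcome matches response flag" =
      sum(stop_t & (tab$outcome == "signal-respond") != tab$responded),
    "rt_ms present iff responded" =
      sum(tab$responded != !is.na(tab$rt_ms)),
    "ssd_ms present iff stop trial" = sum(stop_t != !is.na(tab$ssd_ms)),
    "ssd_ms non-negative" = sum(!is.na(tab$ssd_ms) & tab$ssd_ms < 0),
    "block and trial positive" =
      sum(tab$block < 1 | tab$trial < 1, na.rm = TRUE)
  )
  out <- data.frame(rule = names(rules), violations = unname(rules),
                    stringsAsFactors = FALSE)
  attr(out, "valid") <- all(rules == 0)
  class(out) <- c("trial_validation", "data.frame")
  out
}

#' @export
print.trial_validation <- function(x, ...) {
  cat("trial table validation:",
      if (isTRUE(attr(x, "valid"))) "OK" else "VIOLATIONS FOUND", "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
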