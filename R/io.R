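#' Round half away from zero
#'
#' Printed-value convention used throughout the package's delimited output:
#' ties round away from zero (1.2345 at 3 decimals becomes 1.235).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

dataset_columns <- c("participant", "trial", "bits", "n_cues",
                     "outcome", "choice", "rt", "condition")

#' Read a trial-level dataset
#'
#' Reads comma-separated trial records with header
#' `participant, trial, bits, n_cues, outcome, choice, rt, condition` and
#' validates every row: `bits` must be an admissible pattern (all-absent and
#' all-present are rejected), `n_cues` must match the pattern, `rt` must be
#' a positive number of seconds, and `outcome`/`choice` must be
#' `"positive"`/`"negative"`. Malformed rows raise an error naming the line
#' and field.
#'
#' @param path file path.
#' @return Validated data frame of trial records.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.csv(path, colClasses = c(bits = "character"),
                stringsAsFactors = FALSE)
  miss <- setdiff(dataset_columns, names(d))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "))
  d <- d[, dataset_columns]
  if (nrow(d) == 0) return(d)
  fail <- function(row, field, msg) {
    stop(sprintf("line %d, field '%s': %s", row + 1L, field, msg))
  }
  k <- nchar(d$bits[1])
  for (i in seq_len(nrow(d))) {
    b <- d$bits[i]
    if (nchar(b) != k || grepl("[^01]", b))
      fail(i, "bits", paste0("'", b, "' is not a ", k, "-bit 0/1 string"))
    nc <- sum(strsplit(b, "")[[1]] == "1")
    if (nc == 0 || nc == k)
      fail(i, "bits", paste0("pattern '", b, "' is inadmissible: each ",
                             "trial must present between 1 and ", k - 1,
                             " cues"))
    if (d$n_cues[i] != nc)
      fail(i, "n_cues", paste0(d$n_cues[i], " does not match pattern '",
                               b, "'"))
    if (!is.finite(d$rt[i]) || d$rt[i] <= 0)
      fail(i, "rt", "response time must be a positive number of seconds")
    if (!d$outcome[i] %in% c("positive", "negative"))
      fail(i, "outcome", paste0("'", d$outcome[i], "'"))
    if (!d$choice[i] %in% c("positive", "negative"))
      fail(i, "choice", paste0("'", d$choice[i], "'"))
  }
  d
}

#' Write a trial-level dataset
#'
#' Deterministic column order and formatting; response times are written at
#' millisecond precision with ties rounded away from zero. Writing the same
#' dataset twice produces byte-identical files.
#'
#' @param dataset trial records.
#' @param path file path.
#' @export
write_dataset <- function(dataset, path) {
  miss <- setdiff(dataset_columns, names(dataset))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "))
  d <- dataset[, dataset_columns]
  d$rt <- sprintf("%.3f", round_half_up(d$rt, 3))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
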