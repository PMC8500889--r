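#' Write a judgment dataset to CSV
#'
#' Header `cue_1..cue_D,response,is_trained,learned_criterion`; the learned
#' criterion field is empty for untrained trials. Numeric fields are written
#' with full double precision so that exact-recall equality survives a
#' round trip.
#'
#' @param data a `judgment_data` data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_judgments <- function(data, path) {
  cue_cols <- grep("^cue_", names(data), value = TRUE)
  out <- data.frame(data[cue_cols],
                    response = format_num(data$response),
                    is_trained = data$is_trained,
                    learned_criterion = ifelse(data$is_trained,
                                               format_num(data$learned_criterion),
                                               ""))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_num <- function(x) {
  vapply(x, function(v) if (is.na(v)) "" else sprintf("%.17g", v), character(1))
}

#' Read a judgment dataset from CSV
#'
#' Reads and validates the dialect written by [write_judgments()]: binary
#' cues, responses on the 0-100 scale, and a learned criterion value present
#' exactly for trained trials. Validation errors name the offending data
#' row.
#'
#' @param path CSV file path.
#' @return a `judgment_data` data frame.
#' @export
read_judgments <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  cue_cols <- grep("^cue_[0-9]+$", names(raw), value = TRUE)
  need <- c("response", "is_trained", "learned_criterion")
  if (length(cue_cols) == 0L || !all(need %in% names(raw))) {
    stop("malformed header: expected cue_1..cue_D, response, is_trained, learned_criterion")
  }
  if (nrow(raw) == 0L) stop("dataset is empty")
  for (col in cue_cols) {
    bad <- which(!(raw[[col]] %in% c(0, 1)))
    if (length(bad) > 0) {
      stop(sprintf("non-binary cue value in column %s, data row %d", col, bad[1]))
    }
  }
  bad <- which(!is.finite(raw$response) | raw$response < 0 | raw$response > 100)
  if (length(bad) > 0) {
    stop(sprintf("response out of [0, 100] in data row %d", bad[1]))
  }
  raw$is_trained <- as.logical(raw$is_trained)
  if (anyNA(raw$is_trained)) stop("is_trained must be TRUE/FALSE")
  lc <- raw$learned_criterion
  if (is.character(lc)) lc <- suppressWarnings(as.numeric(lc))
  bad <- which(raw$is_trained & !is.finite(lc))
  if (length(bad) > 0) {
    stop(sprintf("trained trial missing learned_criterion in data row %d", bad[1]))
  }
  lc[!raw$is_trained] <- NA_real_
  out <- raw[c(cue_cols, "response", "is_trained")]
  out$learned_criterion <- lc
  structure(out, D = length(cue_cols),
            class = c("judgment_data", "data.frame"))
}
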