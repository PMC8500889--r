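#' Exemplar memory
#'
#' Bundles the cue patterns of the stored exemplars with their learned
#' criterion values. The cue matrix is binary (one row per exemplar) and the
#' criterion values live on the judgment scale (0-100 in the designs emulated
#' here, though the container itself only requires finite values).
#'
#' @param cues binary matrix (or vector for a single exemplar), one row per
#'   exemplar, entries 0/1.
#' @param criteria numeric vector of criterion values, one per exemplar.
#' @return an object of class `exemplar_memory` with elements `cues` and
#'   `criteria`.
#' @examples
#' exemplar_memory(rbind(c(0, 1), c(1, 1)), c(3, 7))
#' @export
exemplar_memory <- function(cues, criteria) {
  if (is.vector(cues)) cues <- matrix(cues, nrow = 1)
  cues <- as.matrix(cues)
  storage.mode(cues) <- "double"
  check_binary(cues, "cues")
  if (nrow(cues) < 1L) stop("exemplar memory must contain at least one exemplar")
  if (nrow(cues) != length(criteria)) {
    stop(sprintf("number of exemplars (%d) and criterion values (%d) differ",
                 nrow(cues), length(criteria)))
  }
  if (!all(is.finite(criteria))) stop("all criterion values must be finite")
  structure(list(cues = cues, criteria = as.numeric(criteria)),
            class = "exemplar_memory")
}

#' @export
print.exemplar_memory <- function(x, ...) {
  cat(sprintf("exemplar memory: %d exemplars, %d cues, criteria in [%g, %g]\n",
              nrow(x$cues), ncol(x$cues), min(x$criteria), max(x$criteria)))
  invisible(x)
}

check_binary <- function(x, what) {
  if (!all(x %in% c(0, 1))) {
    stop(sprintf("%s must contain only 0/1 entries", what))
  }
  invisible(TRUE)
}

check_s <- function(s) {
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0 || s > 1) {
    stop("s must be a single value in [0, 1]")
  }
  invisible(TRUE)
}

#' Context-model similarity between two cue patterns
#'
#' Multiplicative similarity of the context model: each cue contributes a
#' factor of 1 if probe and exemplar match on that cue and `s` if they
#' mismatch, which for binary cues reduces to `s` raised to the number of
#' mismatching cues. `s` close to 0 means sharp discrimination between
#' exemplars; `s = 1` makes all exemplars look alike.
#'
#' @param probe binary cue vector of the stimulus being judged.
#' @param exemplar binary cue vector of a stored exemplar, same length.
#' @param s mismatch-similarity parameter in \[0, 1\].
#' @return the similarity, a value in \[0, 1\] (`0^0` is taken as 1, so two
#'   identical patterns have similarity 1 even at `s = 0`).
#' @examples
#' similarity(c(0, 1, 1, 1), c(1, 1, 1, 1), s = 0.1) # 0.1
#' @export
similarity <- function(probe, exemplar, s) {
  probe <- as.numeric(probe)
  exemplar <- as.numeric(exemplar)
  if (length(probe) != length(exemplar)) {
    stop(sprintf("probe has %d cues but exemplar has %d",
                 length(probe), length(exemplar)))
  }
  check_binary(probe, "probe")
  check_binary(exemplar, "exemplar")
  check_s(s)
  mism <- sum(probe != exemplar)
  if (mism == 0L) 1 else s^mism
}

mismatch_matrix <- function(probes, memory) {
  if (is.vector(probes)) probes <- matrix(probes, nrow = 1)
  probes <- as.matrix(probes)
  storage.mode(probes) <- "double"
  if (ncol(probes) != ncol(memory$cues)) {
    stop(sprintf("probes have %d cues but memory has %d",
                 ncol(probes), ncol(memory$cues)))
  }
  check_binary(probes, "probes")
  # Hamming distances between probe rows and exemplar rows; for binary x, y:
  # d = sum(x) + sum(y) - 2 x.y
  px <- rowSums(probes)
  ex <- rowSums(memory$cues)
  m <- outer(px, ex, "+") - 2 * probes %*% t(memory$cues)
  storage.mode(m) <- "integer"
  m
}

#' Similarity-weighted criterion prediction
#'
#' The judged criterion value of a probe is the average of all stored
#' exemplar criterion values, weighted by each exemplar's context-model
#' similarity to the probe. The prediction is a convex combination of the
#' stored criteria, so it always lies inside their range; at `s = 1` it is
#' their unweighted mean for every probe.
#'
#' At `s = 0` only exactly matching exemplars carry weight: the prediction is
#' defined as the mean criterion of the exact matches, and an error is raised
#' when there is none (the model makes no prediction in that limit).
#'
#' @param probe binary cue vector.
#' @param memory an [exemplar_memory()].
#' @param s mismatch-similarity parameter in \[0, 1\].
#' @return the predicted criterion value.
#' @examples
#' mem <- exemplar_memory(rbind(c(0, 1), c(1, 1)), c(3, 7))
#' predict_criterion(c(0, 1), mem, s = 1)   # 5, the unweighted mean
#' predict_criterion(c(0, 1), mem, s = 0)   # 3, the exact match
#' @export
predict_criterion <- function(probe, memory, s) {
  drop(predict_batch(matrix(as.numeric(probe), nrow = 1), memory, s))
}

#' Predictions for a set of probes
#'
#' Row-wise [predict_criterion()] over a probe matrix.
#'
#' @param probes binary matrix, one probe per row.
#' @param memory an [exemplar_memory()].
#' @param s mismatch-similarity parameter in \[0, 1\].
#' @return numeric vector of predicted criterion values, one per probe row.
#' @export
predict_batch <- function(probes, memory, s) {
  stopifnot(inherits(memory, "exemplar_memory"))
  check_s(s)
  m <- mismatch_matrix(probes, memory)
  if (s == 0) {
    no_match <- rowSums(m == 0L) == 0L
    if (any(no_match)) {
      stop(sprintf(paste0("undefined prediction at s = 0 for probe row(s) %s: ",
                          "no exactly matching exemplar"),
                   paste(which(no_match), collapse = ", ")))
    }
    # mean criterion over exact matches (the s -> 0+ limit)
    return(apply(m == 0L, 1, function(hit) mean(memory$criteria[hit])))
  }
  drop(predict_draws_cpp(s, m, memory$criteria))
}
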