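# Label sets: per-pattern scores in [0,1] with a binary class at a
# stated cutoff, plus the CSV round trip shared by all classifiers.

#' Construct a label set
#'
#' @param pattern_id character ids (unique).
#' @param score numeric scores in `[0, 1]`.
#' @param theta cutoff; class is `1` iff `score > theta` (strict, so a
#'   score exactly at the cutoff goes to class 0).
#' @return data.frame of class `label_set` with columns `pattern_id`,
#'   `score`, `class` and attribute `theta`.
#' @export
label_set <- function(pattern_id, score, theta = 0.5) {
  pattern_id <- as.character(pattern_id)
  if (anyDuplicated(pattern_id)) stop("duplicate pattern ids")
  stopifnot(length(score) == length(pattern_id),
            all(is.finite(score)), theta >= 0, theta <= 1)
  out <- data.frame(pattern_id = pattern_id, score = as.numeric(score),
                    class = as.integer(score > theta),
                    stringsAsFactors = FALSE)
  attr(out, "theta") <- theta
  class(out) <- c("label_set", "data.frame")
  out
}

#' Write a label set to CSV
#'
#' Header `pattern_id,score,class`; [read_labels()] inverts the write
#' exactly.
#'
#' @param labels a [label_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "data.frame"))
  if (anyDuplicated(labels$pattern_id)) stop("duplicate pattern ids")
  write.csv(labels[, c("pattern_id", "score", "class")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a label set from CSV
#'
#' @param path CSV written by [write_labels()].
#' @param theta cutoff recorded on the returned object.
#' @return A [label_set()].
#' @export
read_labels <- function(path, theta = 0.5) {
  if (!file.exists(path)) stop("no such label file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c("character", "character", "character"))
  if (!all(c("pattern_id", "score", "class") %in% names(df)))
    stop("label file must have columns pattern_id,score,class")
  score <- suppressWarnings(as.numeric(df$score))
  if (anyNA(score))
    stop("non-numeric score at line ", which(is.na(score))[1] + 1,
         " of ", path)
  ls <- label_set(df$pattern_id, score, theta)
  # preserve the stored class column (it encodes the writer's theta)
  ls$class <- as.integer(df$class)
  ls
}

#' Classification accuracy against ground truth
#'
#' @param labels a [label_set()].
#' @param truth data.frame with `pattern_id` and `class` columns (or a
#'   named 0/1 vector).
#' @return fraction of patterns whose class matches, over the ids present
#'   in `labels`.
#' @export
label_accuracy <- function(labels, truth) {
  if (is.data.frame(truth)) {
    tr <- truth$class
    names(tr) <- truth$pattern_id
  } else tr <- truth
  tv <- tr[labels$pattern_id]
  if (anyNA(tv)) stop("truth is missing some pattern ids")
  mean(labels$class == as.integer(tv))
}
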