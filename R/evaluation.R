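# Confusion counts and metrics for classifier output against ground truth.
#
# Truth labels use the sentinel "OUT_OF_DB" for reads whose source is absent
# from the reference database; such reads should ideally stay unclassified.

#' Sentinel truth label for reads from genomes absent from the database
#' @export
OUT_OF_DB <- "OUT_OF_DB"

.as_pred_vector <- function(predictions) {
  if (is.data.frame(predictions)) {
    lab <- predictions$label
    if (!is.null(predictions$status)) {
      lab[predictions$status != "classified"] <- NA_character_
    }
    lab[!is.na(lab) & lab == "-"] <- NA_character_
    stats::setNames(as.character(lab), predictions$read_id)
  } else {
    stopifnot(!is.null(names(predictions)))
    predictions
  }
}

.as_truth_vector <- function(truth) {
  if (is.data.frame(truth)) {
    stats::setNames(as.character(truth$label), truth$read_id)
  } else {
    stopifnot(!is.null(names(truth)))
    truth
  }
}

#' Confusion counts for read classifications
#'
#' Per read: a true positive when the predicted label equals the truth
#' label; a false positive when a prediction was made but differs from the
#' truth (including any prediction for a read whose truth is out-of-database);
#' a false negative when no prediction was made but the truth label is in
#' the database; a true negative when no prediction was made and the truth
#' is flagged `OUT_OF_DB`.
#'
#' @param predictions data.frame as returned by [classify_stream()] (or a
#'   named character vector of labels, NA = unclassified).
#' @param truth data.frame with columns `read_id`, `label` (or a named
#'   character vector); label `OUT_OF_DB` marks reads from withheld genomes.
#'   Every predicted read must have a truth entry.
#' @return object of class `confusion_counts` with fields TP, FP, FN, TN.
#' @export
confusion_counts <- function(predictions, truth) {
  pred <- .as_pred_vector(predictions)
  tru <- .as_truth_vector(truth)
  missing_ids <- setdiff(names(pred), names(tru))
  if (length(missing_ids)) {
    stop(sprintf("predictions for reads missing from truth: %s%s",
                 paste(utils::head(missing_ids, 3), collapse = ", "),
                 if (length(missing_ids) > 3) ", ..." else ""))
  }
  tru <- tru[names(pred)]
  out_db <- tru == OUT_OF_DB
  has_pred <- !is.na(pred)
  tp <- sum(has_pred & !out_db & pred == tru)
  fp <- sum(has_pred & (out_db | pred != tru))
  fn <- sum(!has_pred & !out_db)
  tn <- sum(!has_pred & out_db)
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion_counts: TP=%d FP=%d FN=%d TN=%d (n=%d)\n",
              x$TP, x$FP, x$FN, x$TN, x$TP + x$FP + x$FN + x$TN))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Recall `TP/(TP+FN)`, precision `TP/(TP+FP)`, accuracy
#' `(TP+TN)/(TP+FP+FN+TN)`, and F1 (harmonic mean of precision and recall).
#' A metric whose denominator is zero is reported as NA (undefined), never
#' as 0.
#'
#' @param counts a [confusion_counts()] object.
#' @return list with `recall`, `precision`, `accuracy`, `f1`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  recall <- sdiv(counts$TP, counts$TP + counts$FN)
  precision <- sdiv(counts$TP, counts$TP + counts$FP)
  accuracy <- sdiv(counts$TP + counts$TN,
                   counts$TP + counts$FP + counts$FN + counts$TN)
  f1 <- if (!is.na(recall) && !is.na(precision) && (recall + precision) > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(recall = recall, precision = precision, accuracy = accuracy, f1 = f1)
}

#' Roll predictions and truth up to parent labels
#'
#' Replaces every label on both sides by its parent (e.g. species to genus)
#' before confusion counting. Labels absent from the map pass through
#' unchanged with a warning — mirroring taxonomies where a species' parent
#' is unranked and the species identifier stands in for the genus. The
#' `OUT_OF_DB` sentinel is never remapped.
#'
#' @param predictions,truth as in [confusion_counts()].
#' @param parent_map data.frame with columns `label`, `parent` (or a path to
#'   a two-column TSV).
#' @return list with remapped `predictions` and `truth` (named character
#'   vectors).
#' @export
rollup_labels <- function(predictions, truth, parent_map) {
  if (is.character(parent_map) && length(parent_map) == 1L) {
    parent_map <- utils::read.table(parent_map, sep = "\t", header = FALSE,
                                    col.names = c("label", "parent"),
                                    stringsAsFactors = FALSE)
  }
  stopifnot(all(c("label", "parent") %in% names(parent_map)))
  map <- stats::setNames(as.character(parent_map$parent),
                         as.character(parent_map$label))
  if (anyDuplicated(names(map))) stop("parent map has duplicate child labels")
  # cycle check: resolving any label upward must terminate
  for (start in names(map)) {
    seen <- character(0)
    cur <- start
    while (cur %in% names(map) && map[[cur]] != cur) {
      if (cur %in% seen) stop("parent map contains a cycle")
      seen <- c(seen, cur)
      cur <- map[[cur]]
    }
  }
  remap <- function(v) {
    lab <- v
    mappable <- !is.na(lab) & lab != OUT_OF_DB
    unknown <- mappable & !(lab %in% names(map))
    if (any(unknown)) {
      warning(sprintf("labels absent from parent map pass through: %s",
                      paste(unique(lab[unknown]), collapse = ", ")))
    }
    hit <- mappable & lab %in% names(map)
    lab[hit] <- map[lab[hit]]
    lab
  }
  pred <- .as_pred_vector(predictions)
  tru <- .as_truth_vector(truth)
  list(predictions = remap(pred), truth = remap(tru))
}
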