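#' Evaluation of annotation results
#'
#' All target cell types absent from the reference label set are collapsed
#' into one "unknown" class before scoring. Besides total accuracy, the
#' H-score — the harmonic mean of the accuracy on known-type cells and on
#' unknown cells — summarizes the open-set trade-off.
#'
#' @name metrics_eval
NULL

#' Collapse reference-absent truth labels to "unknown"
#'
#' @param truth character vector of true labels.
#' @param known_set character vector of reference (known) type names.
#' @return character vector with every label outside `known_set` replaced by
#'   `"unknown"`.
#' @export
collapse_private <- function(truth, known_set) {
  out <- as.character(truth)
  out[!(out %in% known_set)] <- "unknown"
  out
}

#' Score predicted against true labels
#'
#' @param pred character vector of predicted labels (`"unknown"` allowed).
#' @param truth character vector of true labels, same length.
#' @param known_set character vector of reference type names.
#' @return list of class `eval_report`: `total_accuracy`, `known_accuracy`,
#'   `unknown_accuracy`, `h_score` (harmonic mean, 0/0 defined as 0, `NA`
#'   when the truth holds no unknown cells), `per_class` accuracy table and
#'   the `confusion` table.
#' @export
evaluate_annotation <- function(pred, truth, known_set) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  truth_c <- collapse_private(truth, known_set)
  pred <- as.character(pred)
  total <- base::mean(pred == truth_c)
  is_unknown <- truth_c == "unknown"
  ka <- if (any(!is_unknown)) base::mean(pred[!is_unknown] == truth_c[!is_unknown]) else NA_real_
  ua <- if (any(is_unknown)) base::mean(pred[is_unknown] == truth_c[is_unknown]) else NA_real_
  h <- if (!any(is_unknown)) NA_real_
  else if (is.na(ka) || (ka + ua) == 0) 0
  else 2 * ka * ua / (ka + ua)
  per_class <- vapply(sort(unique(truth_c)), function(cl)
    base::mean(pred[truth_c == cl] == cl), numeric(1))
  structure(list(total_accuracy = total, known_accuracy = ka,
                 unknown_accuracy = ua, h_score = h,
                 per_class = per_class,
                 confusion = table(truth = truth_c, pred = pred)),
            class = "eval_report")
}
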