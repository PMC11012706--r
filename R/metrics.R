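#' Confusion counts from predicted and actual binary labels
#'
#' @param actual,predicted vectors of class labels (factors, characters or
#'   0/1) of equal length; `positive` names the positive class.
#' @param positive label of the positive class (default `1`).
#' @return object of class `confusion_counts` with fields TP, FP, TN, FN.
#' @export
confusion_counts <- function(actual, predicted, positive = 1) {
  stopifnot(length(actual) == length(predicted), length(actual) >= 1L)
  a <- as.character(actual) == as.character(positive)
  p <- as.character(predicted) == as.character(positive)
  structure(list(TP = sum(a & p), FP = sum(!a & p),
                 TN = sum(!a & !p), FN = sum(a & !p)),
            class = "confusion_counts")
}

#' Classification accuracy from confusion counts
#'
#' ACC = (TP + TN) / (TP + TN + FP + FN).
#'
#' @param c a [confusion_counts] object (or a list with TP/FP/TN/FN).
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(c) {
  total <- c$TP + c$TN + c$FP + c$FN
  if (total <= 0) stop("accuracy undefined for zero total count", call. = FALSE)
  (c$TP + c$TN) / total
}

#' Mean squared error
#'
#' @param actual,predicted numeric vectors of equal positive length.
#' @return mean of squared differences.
#' @export
mean_squared_error <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("actual and predicted lengths differ", call. = FALSE)
  if (!length(actual)) stop("empty vectors", call. = FALSE)
  mean((actual - predicted)^2)
}
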