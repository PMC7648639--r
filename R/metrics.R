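#' Confusion matrix for two-class predictions
#'
#' @param true,predicted character vectors of equal length; every value
#'   must be one of the two known classes.
#' @param positive the positive class (default `"case"`).
#' @return object of class `confusion_matrix`: list with counts `TP`,
#'   `TN`, `FP`, `FN` (summing to `length(true)`).
#' @export
confusion <- function(true, predicted, positive = "case") {
  true <- as.character(true); predicted <- as.character(predicted)
  if (length(true) != length(predicted))
    stop("true and predicted must have equal length", call. = FALSE)
  known <- unique(c(true, positive))
  if (length(known) > 2)
    stop("more than two classes present: ",
         paste(known, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(predicted), known)
  if (length(bad))
    stop("unknown predicted label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  pos_t <- true == positive
  pos_p <- predicted == positive
  structure(list(TP = sum(pos_t & pos_p), TN = sum(!pos_t & !pos_p),
                 FP = sum(!pos_t & pos_p), FN = sum(pos_t & !pos_p)),
            class = "confusion_matrix")
}

#' Accuracy, sensitivity and specificity (percent)
#'
#' `AC = 100 (TP + TN) / (TP + FP + TN + FN)`,
#' `SENS = 100 TP / (TP + FN)`, `SPEC = 100 TN / (TN + FP)`.
#'
#' @param cm a [confusion()] result (or a list with TP/TN/FP/FN counts).
#' @return named numeric vector `c(accuracy, sensitivity, specificity)`
#'   in percent.
#' @export
figures_of_merit <- function(cm) {
  total <- cm$TP + cm$TN + cm$FP + cm$FN
  if (total == 0)
    stop("accuracy undefined: no evaluated objects", call. = FALSE)
  if (cm$TP + cm$FN == 0)
    stop("sensitivity undefined: no positive objects", call. = FALSE)
  if (cm$TN + cm$FP == 0)
    stop("specificity undefined: no negative objects", call. = FALSE)
  c(accuracy = 100 * (cm$TP + cm$TN) / total,
    sensitivity = 100 * cm$TP / (cm$TP + cm$FN),
    specificity = 100 * cm$TN / (cm$TN + cm$FP))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> TP =", x$TP, "TN =", x$TN,
      "FP =", x$FP, "FN =", x$FN, "\n")
  invisible(x)
}
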