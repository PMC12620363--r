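# Directed threshold classifiers (DTCs) and ordinal classifier cascades.
#
# A DTC on 1-D values assigns the right (higher) class iff x >= tau.  Under
# a misclassification budget theta, up to floor(theta * n) samples of each
# side may fall on the wrong side of tau.  The feasible threshold set is an
# interval (lower, upper] determined exactly by order statistics:
#   lower = (k_l + 1)-th largest left value   (k_l = floor(theta * n_left))
#   upper = (k_r + 1)-th smallest right value (k_r = floor(theta * n_right))
# and is non-empty iff lower < upper.  At theta = 0 this reduces to
# "all left values < tau <= all right values".  The representative point is
# the margin midpoint of the feasible interval (the 1-D hard-margin SVM
# solution), computed analytically to avoid solver nondeterminism.

#' Fit a directed threshold classifier on one-dimensional data
#'
#' @param left_values,right_values numeric vectors of projected values for
#'   the lower (left) and higher (right) class.
#' @param theta tolerated per-class misclassification fraction, in
#'   `[0, 0.5]`; the budget is `floor(theta * n)` samples per class.
#' @param left_label,right_label optional class labels stored on the
#'   classifier.
#' @return An object of class `dtc` with fields `left_label`,
#'   `right_label`, `interval` (list `lower` (exclusive), `upper`
#'   (inclusive), `point`), `left_sens`, `right_sens` — or `NULL` when no
#'   threshold satisfies the budget (REJECT).
#' @examples
#' fit_dtc(c(0, 1), c(3, 4), theta = 0)$interval
#' @export
fit_dtc <- function(left_values, right_values, theta = 0,
                    left_label = "left", right_label = "right") {
  if (!length(left_values) || !length(right_values))
    stop2("empty class values")
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > 0.5)
    stop2("theta must be in [0, 0.5]")
  nl <- length(left_values); nr <- length(right_values)
  kl <- floor(theta * nl); kr <- floor(theta * nr)
  lower <- sort(left_values, decreasing = TRUE)[kl + 1L]
  upper <- sort(right_values)[kr + 1L]
  if (!(lower < upper)) return(NULL)
  point <- (lower + upper) / 2
  if (point <= lower) point <- upper  # degenerate width at float tolerance
  structure(list(left_label = left_label, right_label = right_label,
                 interval = list(lower = lower, upper = upper, point = point),
                 left_sens = mean(left_values < point),
                 right_sens = mean(right_values >= point)),
            class = "dtc")
}

#' Classify one-dimensional values with a DTC
#'
#' Boundary convention: `x >= point` is assigned the right (higher) label.
#'
#' @param dtc a fitted [fit_dtc()] object.
#' @param x numeric vector.
#' @return Character vector of labels.
#' @export
dtc_classify <- function(dtc, x) {
  stopifnot(inherits(dtc, "dtc"))
  ifelse(x >= dtc$interval$point, dtc$right_label, dtc$left_label)
}

# values of one class on the projection axis
.class_values <- function(projected, label) projected$values[projected$y == label]

#' Fit an ordinal classifier cascade for a candidate class order
#'
#' Fits one DTC per adjacent label pair (using only those two classes'
#' projected values), rejecting at the first pair with no feasible
#' threshold or whose threshold point breaks strict monotonicity; then
#' computes cascade class-wise sensitivities and rejects if any class
#' falls below `1 - theta`.
#'
#' @param projected a [fit_projection()] result.
#' @param order character vector of >= 2 class labels.
#' @param theta misclassification budget in `[0, 0.5]`.
#' @param cache optional environment memoizing fitted DTCs across calls
#'   (keyed by ordered label pair); see [screen_suborders()].
#' @return An object of class `cascade` (fields `order`, `classifiers`,
#'   `thresholds`, `sensitivities`) or an object of class
#'   `cascade_reject` with fields `position` (index of the failing
#'   adjacent pair, or failing class for the sensitivity stage) and
#'   `reason`.
#' @export
fit_cascade <- function(projected, order, theta = 0, cache = NULL) {
  stopifnot(inherits(projected, "projected_dataset"))
  order <- as.character(order)
  if (length(order) < 2L) stop2("order must contain at least two labels")
  unknown <- setdiff(order, unique(projected$y))
  if (length(unknown)) stop2("unknown label(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(order)) stop2("duplicate label in order")
  k <- length(order)
  classifiers <- vector("list", k - 1L)
  pts <- numeric(k - 1L)
  for (i in seq_len(k - 1L)) {
    d <- .fit_dtc_memo(projected, order[i], order[i + 1L], theta, cache)
    if (is.null(d))
      return(structure(list(position = i, reason = "infeasible"),
                       class = "cascade_reject"))
    if (i > 1L && !(d$interval$point > pts[i - 1L]))
      return(structure(list(position = i, reason = "non-monotone"),
                       class = "cascade_reject"))
    classifiers[[i]] <- d
    pts[i] <- d$interval$point
  }
  cas <- structure(list(order = order, classifiers = classifiers,
                        thresholds = pts, sensitivities = NULL),
                   class = "cascade")
  sens <- classwise_sensitivity(cas, projected)
  cas$sensitivities <- sens
  bad <- which(sens < 1 - theta - 1e-12)
  if (length(bad))
    return(structure(list(position = bad[1], reason = "sensitivity",
                          label = order[bad[1]], sensitivities = sens),
                     class = "cascade_reject"))
  cas
}

.fit_dtc_memo <- function(projected, left, right, theta, cache) {
  if (is.null(cache))
    return(fit_dtc(.class_values(projected, left),
                   .class_values(projected, right), theta,
                   left_label = left, right_label = right))
  key <- paste0(left, "\r", right)
  if (is.null(cache$hits)) cache$hits <- 0L
  if (!is.null(cache[[key]])) {
    cache$hits <- cache$hits + 1L
    return(if (identical(cache[[key]], "REJECT")) NULL else cache[[key]])
  }
  d <- fit_dtc(.class_values(projected, left),
               .class_values(projected, right), theta,
               left_label = left, right_label = right)
  cache[[key]] <- if (is.null(d)) "REJECT" else d
  d
}

#' @export
print.cascade <- function(x, ...) {
  cat("cascade:", paste(x$order, collapse = " < "), "\n")
  cat("thresholds:", paste(format(x$thresholds), collapse = ", "), "\n")
  cat("min sensitivity:", format(min(x$sensitivities)), "\n")
  invisible(x)
}

#' Predict labels with an ordinal classifier cascade
#'
#' Sequentially walks the cascade's classifiers: the first classifier
#' predicting its left label fixes the output; if every classifier
#' predicts right, the final label is returned. With strictly increasing
#' thresholds this is equivalent to looking up the interval containing
#' `x`; both routes are implemented (`method`) and agree.
#'
#' @param cascade a [fit_cascade()] result.
#' @param x numeric vector of projected values.
#' @param method `"interval"` (vectorized lookup, default) or
#'   `"sequential"` (literal walk).
#' @return Character vector of labels.
#' @export
cascade_predict <- function(cascade, x, method = c("interval", "sequential")) {
  stopifnot(inherits(cascade, "cascade"))
  method <- match.arg(method)
  if (method == "interval") {
    idx <- vapply(x, function(v) 1L + sum(v >= cascade$thresholds), integer(1))
    return(cascade$order[idx])
  }
  vapply(x, function(v) {
    for (cl in cascade$classifiers) {
      if (dtc_classify(cl, v) == cl$left_label) return(cl$left_label)
    }
    cascade$order[length(cascade$order)]
  }, character(1))
}

#' Class-wise sensitivity of a cascade
#'
#' For each label in the cascade's order, the fraction of that class's
#' samples assigned their true label by [cascade_predict()]. Samples of
#' labels outside the order are ignored.
#'
#' @param cascade a cascade.
#' @param projected a [fit_projection()] result covering the cascade's
#'   labels.
#' @return Named numeric vector, one sensitivity per class in the order.
#' @export
classwise_sensitivity <- function(cascade, projected) {
  stopifnot(inherits(cascade, "cascade"), inherits(projected, "projected_dataset"))
  vapply(cascade$order, function(l) {
    v <- .class_values(projected, l)
    mean(cascade_predict(cascade, v) == l)
  }, numeric(1))
}
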