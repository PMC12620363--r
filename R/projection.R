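#' Project a labeled dataset to one dimension via a class-pair max-margin axis
#'
#' Trains a deterministic soft-margin linear max-margin classifier on the
#' two classes of `pair` only (features standardized using the pair's
#' samples), then projects *all* samples onto the unit normal of the
#' decision boundary. Orientation is fixed so that the mean projected
#' value of the pair's second class is >= that of its first class;
#' swapping the pair therefore mirrors the axis exactly.
#'
#' @param dataset a [labeled_dataset()].
#' @param pair ordered character vector of two distinct class labels.
#' @param cost soft-margin cost; large by default so separable pairs get
#'   hard-margin behaviour.
#' @return An object of class `projected_dataset` with fields `values`
#'   (one real per sample), `y`, `sample_ids`, `labels`, `pair`,
#'   `direction_norm` (Euclidean norm of the separating direction before
#'   normalization) and `training_error`.
#' @export
fit_projection <- function(dataset, pair, cost = 1e6) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  pair <- as.character(pair)
  if (length(pair) != 2L) stop2("pair must have exactly two labels")
  if (pair[1] == pair[2]) stop2("pair labels must differ")
  missing <- setdiff(pair, dataset$labels)
  if (length(missing)) stop2("unknown label(s) in pair: ",
                             paste(missing, collapse = ", "))
  idx <- dataset$y %in% pair
  Xp <- dataset$X[idx, , drop = FALSE]
  yp <- ifelse(dataset$y[idx] == pair[2], 1, -1)
  # standardize from the pair's samples only, apply to all samples
  mu <- colMeans(Xp)
  sdv <- apply(Xp, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  scale_all <- function(M) sweep(sweep(M, 2, mu), 2, sdv, "/")
  fit <- fit_linear_maxmargin(scale_all(Xp), yp, cost = cost)
  if (fit$norm < 1e-12)
    stop2("degenerate projection: separating direction has zero norm for pair (",
          pair[1], ",", pair[2], ")")
  if (fit$training_error > 0)
    occ_log("pair (", pair[1], ",", pair[2], ") not linearly separable; ",
            "training error ", format(fit$training_error))
  u <- fit$w / fit$norm
  values <- as.vector(scale_all(dataset$X) %*% u)
  if (mean(values[dataset$y == pair[2]]) < mean(values[dataset$y == pair[1]]))
    values <- -values
  structure(list(values = values, y = dataset$y,
                 sample_ids = dataset$sample_ids, labels = dataset$labels,
                 pair = pair, direction_norm = fit$norm,
                 training_error = fit$training_error),
            class = "projected_dataset")
}

#' @export
print.projected_dataset <- function(x, ...) {
  cat("projected_dataset: pair (", x$pair[1], ",", x$pair[2], "), ",
      length(x$values), " samples\n", sep = "")
  invisible(x)
}

#' Check the mirror property of swapped projection pairs
#'
#' Projecting with `(l_j, l_i)` instead of `(l_i, l_j)` mirrors the axis:
#' the rank order of projected values is exactly reversed, so screening
#' the swapped projection yields the element-wise reversed suborders.
#'
#' @param dataset a [labeled_dataset()].
#' @param pair ordered label pair.
#' @return `TRUE` invisibly if the reversal holds; the comparison values
#'   are attached as attributes. Errors if the property is violated.
#' @export
reverse_projection_property <- function(dataset, pair) {
  f <- fit_projection(dataset, pair)
  r <- fit_projection(dataset, rev(pair))
  rho <- stats::cor(f$values, r$values, method = "spearman")
  if (!isTRUE(all.equal(rho, -1, tolerance = 1e-9)))
    stop2("reversal property violated: spearman rho = ", format(rho))
  invisible(structure(TRUE, forward = f, reverse = r, spearman = rho))
}

#' Select projection class pairs
#'
#' @param dataset a [labeled_dataset()].
#' @param strategy `"all"` (every unordered pair, canonical orientation
#'   following the dataset's label order), `"most_distant"` (the single
#'   pair with maximal Euclidean distance between class centroids in
#'   feature space), or `"explicit"`.
#' @param pairs for `strategy = "explicit"`, a list of 2-element character
#'   vectors.
#' @return List of ordered label pairs.
#' @export
select_projection_pairs <- function(dataset,
                                    strategy = c("all", "most_distant", "explicit"),
                                    pairs = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  strategy <- match.arg(strategy)
  labs <- dataset$labels
  if (length(labs) < 2L) stop2("need at least two classes")
  if (strategy == "all") {
    cm <- utils::combn(labs, 2L)
    return(lapply(seq_len(ncol(cm)), function(j) cm[, j]))
  }
  if (strategy == "most_distant") {
    cent <- do.call(rbind, lapply(labs, function(l)
      colMeans(dataset$X[dataset$y == l, , drop = FALSE])))
    rownames(cent) <- labs
    cm <- utils::combn(labs, 2L)
    d <- vapply(seq_len(ncol(cm)), function(j)
      sqrt(sum((cent[cm[1, j], ] - cent[cm[2, j], ])^2)), numeric(1))
    return(list(cm[, which.max(d)]))
  }
  # explicit
  if (is.null(pairs)) stop2("strategy 'explicit' requires pairs")
  pairs <- lapply(pairs, as.character)
  for (p in pairs) {
    if (length(p) != 2L || p[1] == p[2]) stop2("each pair must be two distinct labels")
    bad <- setdiff(p, labs)
    if (length(bad)) stop2("unknown label in explicit pair: ", paste(bad, collapse = ", "))
  }
  pairs
}
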