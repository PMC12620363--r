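# Independent total-order detection via pairwise separability matrices with
# monotonicity toward the diagonal: an ordinal class structure exists iff
# some arrangement of the rows/columns makes every row non-increasing
# toward the diagonal from both sides; each structure is found together
# with its reverse.

#' Build a pairwise class-separability matrix
#'
#' Fits one binary subtask per unordered class pair
#' (`|L|(|L|-1)/2` fits). `score = "accuracy"` is the resubstitution
#' accuracy of a linear max-margin classifier on the two classes;
#' `score = "fisher"` is a multidimensional Fisher discriminant ratio
#' `J = d' S_w^{-1} d` mapped monotonically to `[0, 1]` as `J / (1 + J)`.
#' The matrix is symmetric with zero diagonal by definition.
#'
#' @param dataset a [labeled_dataset()].
#' @param score `"accuracy"` (default) or `"fisher"`.
#' @return An object of class `separability_matrix`: list with `labels`
#'   and the `|L| x |L|` matrix `a`.
#' @export
build_separability_matrix <- function(dataset, score = c("accuracy", "fisher")) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  score <- match.arg(score)
  labs <- dataset$labels
  k <- length(labs)
  a <- matrix(0, k, k, dimnames = list(labs, labs))
  if (score == "fisher") {
    for (l in labs) {
      Xl <- dataset$X[dataset$y == l, , drop = FALSE]
      if (nrow(Xl) < 2L || all(apply(Xl, 2, stats::sd) < 1e-12))
        stop2("degenerate class for fisher score: ", l)
    }
  }
  cm <- utils::combn(labs, 2L)
  for (j in seq_len(ncol(cm))) {
    li <- cm[1, j]; lj <- cm[2, j]
    Xi <- dataset$X[dataset$y == li, , drop = FALSE]
    Xj <- dataset$X[dataset$y == lj, , drop = FALSE]
    val <- if (score == "accuracy") {
      X <- rbind(Xi, Xj)
      y <- rep(c(-1, 1), c(nrow(Xi), nrow(Xj)))
      mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
      sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
      Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
      1 - fit_linear_maxmargin(Xs, y)$training_error
    } else {
      d <- colMeans(Xi) - colMeans(Xj)
      Sw <- (crossprod(sweep(Xi, 2, colMeans(Xi))) +
             crossprod(sweep(Xj, 2, colMeans(Xj)))) /
            (nrow(Xi) + nrow(Xj) - 2L)
      Ji <- tryCatch(sum(d * solve(Sw, d)), error = function(e) {
        # singular pooled covariance: Moore-Penrose fallback
        s <- svd(Sw)
        pos <- s$d > max(s$d) * 1e-12
        sum(d * (s$v[, pos, drop = FALSE] %*%
                   ((t(s$u[, pos, drop = FALSE]) %*% d) / s$d[pos])))
      })
      Ji / (1 + Ji)
    }
    a[li, lj] <- a[lj, li] <- val
  }
  structure(list(labels = labs, a = a, score = score),
            class = "separability_matrix")
}

#' @export
print.separability_matrix <- function(x, ...) {
  cat("separability_matrix (", x$score, "), ", length(x$labels),
      " classes\n", sep = "")
  print(round(x$a, 3))
  invisible(x)
}

# does ordering pi of M admit rows monotonously decreasing toward the
# diagonal?  Incremental check used by the backtracking search: when the
# m-th label is appended it suffices to verify (a) its own row over the
# prefix is non-decreasing moving left-to-right toward itself and (b) each
# earlier row gains one rightward step that must not increase toward m.
.monotone_ok_append <- function(a, pi, m, tol) {
  lm <- pi[m]
  if (m >= 3L) {
    for (i in 1L:(m - 2L)) {
      if (a[pi[i], lm] < a[pi[i], pi[m - 1L]] - tol) return(FALSE)
    }
  }
  if (m >= 3L) {
    for (j in (m - 1L):2L) {
      if (a[lm, pi[j]] > a[lm, pi[j - 1L]] + tol) return(FALSE)
    }
  }
  TRUE
}

#' Detect total ordinal class structures in a separability matrix
#'
#' Returns every arrangement of the labels under which all rows (and by
#' symmetry columns) of the reordered matrix are non-increasing toward
#' the diagonal from both sides, i.e. farther class pairs are at least as
#' separable as nearer ones. Ties are tolerated up to an absolute
#' tolerance. Each structure is found together with its reverse; an empty
#' list means no total ordinal structure.
#'
#' @param M a [build_separability_matrix()] result.
#' @param method `"prune"` (backtracking with incremental monotonicity
#'   checks, default; exact) or `"exhaustive"` (generate all `|L|!`
#'   permutations; test oracle, `|L| <= 8`).
#' @param tol absolute tie tolerance on separability values.
#' @return List of character vectors (label orderings), possibly empty;
#'   cardinality is even since reverses pair up.
#' @export
detect_total_order <- function(M, method = c("prune", "exhaustive"),
                               tol = 1e-12) {
  stopifnot(inherits(M, "separability_matrix"))
  method <- match.arg(method)
  labs <- M$labels
  a <- M$a
  k <- length(labs)
  if (k == 1L) return(list(labs))
  found <- list()
  if (method == "prune") {
    recurse <- function(pi, remaining) {
      if (!length(remaining)) {
        found[[length(found) + 1L]] <<- pi
        return()
      }
      for (u in remaining) {
        cand <- c(pi, u)
        if (.monotone_ok_append(a, cand, length(cand), tol))
          recurse(cand, setdiff(remaining, u))
      }
    }
    recurse(character(0), labs)
  } else {
    if (k > 8L) stop2("exhaustive method limited to 8 classes")
    perms <- function(v) {
      if (length(v) == 1L) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
      out
    }
    for (pi in perms(labs)) {
      ok <- TRUE
      if (k >= 3L) for (m in 3:k)
        if (!.monotone_ok_append(a, pi, m, tol)) { ok <- FALSE; break }
      if (ok) found[[length(found) + 1L]] <- pi
    }
  }
  found[order(vapply(found, seq_key, character(1)))]
}

#' Cross-validate screened suborders with the monotone-matrix detector
#'
#' For each longest suborder, restricts the dataset to that suborder's
#' classes, builds the subset separability matrix, and runs
#' [detect_total_order()]: `"confirmed"` if the suborder's sequence (or
#' its reverse) is among the admitted orderings, `"contradicted"` if
#' orderings exist but the sequence is not among them, `"undetected"` if
#' none exist.
#'
#' @param dataset the [labeled_dataset()] the suborders were screened on.
#' @param suborders list of `suborder` objects.
#' @param score separability score passed to
#'   [build_separability_matrix()]; Fisher by default because perfectly
#'   separable classes tie at accuracy 1.0 and carry no order
#'   information.
#' @return Data frame with columns `suborder`, `length`, `status`,
#'   `n_orderings`.
#' @export
cross_validate_substructures <- function(dataset, suborders,
                                         score = c("fisher", "accuracy")) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  score <- match.arg(score)
  if (!length(suborders))
    return(data.frame(suborder = character(0), length = integer(0),
                      status = character(0), n_orderings = integer(0)))
  lens <- lengths(lapply(suborders, `[[`, "sequence"))
  longest <- suborders[lens == max(lens)]
  rows <- lapply(longest, function(s) {
    keep <- dataset$y %in% s$sequence
    sub <- labeled_dataset(dataset$X[keep, , drop = FALSE], dataset$y[keep],
                           sample_ids = dataset$sample_ids[keep],
                           labels = intersect(dataset$labels, s$sequence))
    orders <- detect_total_order(build_separability_matrix(sub, score))
    keys <- vapply(orders, seq_key, character(1))
    status <- if (!length(orders)) "undetected"
      else if (seq_key(s$sequence) %in% keys ||
               seq_key(rev(s$sequence)) %in% keys) "confirmed"
      else "contradicted"
    data.frame(suborder = paste(s$sequence, collapse = "<"),
               length = length(s$sequence), status = status,
               n_orderings = length(orders), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
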