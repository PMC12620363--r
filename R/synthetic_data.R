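#' Specify a synthetic branching class layout
#'
#' A branching layout places each class uniformly inside an interval on a
#' single "structure" axis (feature 1); overlap between intervals encodes
#' which class pairs are not ordinally separable. All remaining features
#' are pure uniform noise.
#'
#' @param class_intervals named list, label -> `c(low, high)` on the
#'   structure axis (arbitrary units, `low < high`).
#' @param n_per_class samples per class (>= 1).
#' @param noise_dims number of pure-noise features appended (>= 1).
#' @param noise_scale width of the uniform noise features (>= 0).
#' @param seed integer seed.
#' @return An object of class `branching_spec`.
#' @export
branching_spec <- function(class_intervals, n_per_class = 100L,
                           noise_dims = 1L, noise_scale = 1, seed = 1L) {
  stopifnot(is.list(class_intervals), length(class_intervals) >= 1L,
            !is.null(names(class_intervals)))
  for (nm in names(class_intervals)) {
    iv <- class_intervals[[nm]]
    if (length(iv) != 2L || !is.numeric(iv) || !(iv[1] < iv[2]))
      stop2("interval for class '", nm, "' must be c(low, high) with low < high")
  }
  if (n_per_class < 1L) stop2("n_per_class must be >= 1")
  if (noise_dims < 1L) stop2("noise_dims must be >= 1")
  if (noise_scale < 0) stop2("noise_scale must be >= 0")
  structure(list(class_intervals = class_intervals,
                 n_per_class = as.integer(n_per_class),
                 noise_dims = as.integer(noise_dims),
                 noise_scale = noise_scale,
                 seed = as.integer(seed)),
            class = "branching_spec")
}

# Are classes a, b separated left-to-right on the structure axis?
# Touching intervals (high == low) count as separated: with continuous
# uniform sampling the empirical gap is positive almost surely.
.interval_separated <- function(iv_a, iv_b) iv_a[2] <= iv_b[1]

# Brute-force ground truth: all maximal sequences of classes whose
# intervals are pairwise separated in left-to-right order.  Separation is
# transitive on intervals, so valid sequences are exactly the chains of
# the separation DAG; maximality is checked by single-class insertion.
interval_ground_truth <- function(class_intervals) {
  labs <- names(class_intervals)
  k <- length(labs)
  sep <- matrix(FALSE, k, k, dimnames = list(labs, labs))
  for (a in seq_len(k)) for (b in seq_len(k)) if (a != b)
    sep[a, b] <- .interval_separated(class_intervals[[a]], class_intervals[[b]])
  # enumerate all chains (paths in the DAG) by right extension; singletons
  # are kept so that a class separable from nothing still appears in the
  # ground truth as its own maximal (length-1) "sequence"
  frontier <- lapply(labs, identity)
  chains <- frontier
  while (length(frontier)) {
    nxt <- list()
    for (ch in frontier) {
      lastl <- ch[length(ch)]
      for (b in labs[sep[lastl, ]]) {
        if (b %in% ch) next
        nxt[[length(nxt) + 1L]] <- c(ch, b)
      }
    }
    chains <- c(chains, nxt)
    frontier <- nxt
  }
  # maximality: no single-class insertion at any position stays a chain
  is_max <- vapply(chains, function(ch) {
    others <- setdiff(labs, ch)
    for (u in others) {
      for (pos in 0:length(ch)) {
        left_ok <- pos == 0L || sep[ch[pos], u]
        right_ok <- pos == length(ch) || sep[u, ch[pos + 1L]]
        if (left_ok && right_ok) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  out <- chains[is_max]
  out[order(-lengths(out), vapply(out, seq_key, character(1)))]
}

#' Generate a synthetic branching dataset with known ground truth
#'
#' Samples each class uniformly inside its interval on feature 1 and adds
#' pure-noise features. The ground truth lists every maximal class
#' sequence whose intervals are pairwise separated left-to-right, computed
#' by brute force over the interval layout.
#'
#' @param spec a [branching_spec()].
#' @return A list with elements `dataset` (a [labeled_dataset()]) and
#'   `ground_truth` (list of character vectors, longest first).
#' @examples
#' bs <- branching_spec(list(a = c(0, 1), b = c(2, 3)), n_per_class = 5)
#' make_branching(bs)$ground_truth
#' @export
make_branching <- function(spec) {
  stopifnot(inherits(spec, "branching_spec"))
  labs <- names(spec$class_intervals)
  n <- spec$n_per_class
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  X <- do.call(rbind, lapply(labs, function(l) {
    iv <- spec$class_intervals[[l]]
    cbind(stats::runif(n, iv[1], iv[2]),
          matrix(stats::runif(n * spec$noise_dims, 0, spec$noise_scale),
                 nrow = n))
  }))
  colnames(X) <- c("structure_axis", paste0("noise_", seq_len(spec$noise_dims)))
  y <- rep(labs, each = n)
  ds <- labeled_dataset(X, y,
                        sample_ids = paste0(rep(labs, each = n), "_", seq_len(n)),
                        labels = labs)
  list(dataset = ds, ground_truth = interval_ground_truth(spec$class_intervals))
}

# Interval layout of the ten-class branching benchmark: two parallel
# ordinal chains l0<l1<{l2||l7}<{l3||l8}<l4<l5 with l6 overlapping the
# union of l0,l1 and l9 overlapping the union of l4,l5; l2/l7 and l3/l8
# are fully overlapping alternatives.  Feature 2 is pure noise.
figure4_intervals <- function() {
  list(l0 = c(0, 1),    l1 = c(1.5, 2.5), l2 = c(3, 4),    l3 = c(4.5, 5.5),
       l4 = c(6, 7),    l5 = c(7.5, 8.5), l6 = c(0.2, 2.3), l7 = c(3, 4),
       l8 = c(4.5, 5.5), l9 = c(6.2, 8.3))
}

#' Ten-class branching benchmark fixture
#'
#' Generates the two-feature, ten-class benchmark with two parallel
#' ordinal chains: no total order over all ten classes exists, while four
#' maximal suborders of length six
#' (`l0<l1<{l2|l7}<{l3|l8}<l4<l5`) and eight of length five (with `(l0,l1)`
#' replaced by `l6`, or `(l4,l5)` replaced by `l9`) are present, plus four
#' maximal length-4 sequences using both replacements.
#'
#' @param n_per_class samples per class (>= 2; default 100).
#' @param seed integer seed.
#' @return As [make_branching()]: list(`dataset`, `ground_truth`).
#' @export
make_figure4_fixture <- function(n_per_class = 100L, seed = 1L) {
  if (n_per_class < 2L) stop2("n_per_class must be >= 2")
  make_branching(branching_spec(figure4_intervals(),
                                n_per_class = n_per_class,
                                noise_dims = 1L, noise_scale = 1,
                                seed = seed))
}
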