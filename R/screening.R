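# Suborder screening: enumerate all maximal class sequences supported by a
# projected dataset at a sensitivity floor.
#
# The incremental screener enumerates candidate sequences by right
# extension over "chains": sequences whose every adjacent label pair has a
# feasible DTC.  Chain feasibility is checked with memoized pairwise
# classifiers (each adjacent-pair DTC fitted at most once) and is
# prefix-hereditary, so right extension enumerates every chain; this keeps
# the search complete even under theta > 0, where full-cascade acceptance
# (threshold monotonicity + cascade sensitivities) is *not* hereditary
# under class deletion and is therefore re-checked per candidate rather
# than assumed.  An exhaustive permutation oracle is retained behind
# `method = "exhaustive"` for testing.

.new_suborder <- function(sequence, cascade, source_pair, is_maximal) {
  structure(list(sequence = sequence, cascade = cascade,
                 min_sensitivity = min(cascade$sensitivities),
                 source_pair = source_pair, is_maximal = is_maximal),
            class = "suborder")
}

#' @export
print.suborder <- function(x, ...) {
  cat("suborder:", paste(x$sequence, collapse = " < "),
      " (min sens ", format(x$min_sensitivity), ")\n", sep = "")
  invisible(x)
}

.sort_suborders <- function(subs) {
  if (!length(subs)) return(subs)
  keys <- vapply(subs, function(s) seq_key(s$sequence), character(1))
  subs[order(-lengths(lapply(subs, `[[`, "sequence")), keys)]
}

#' Screen all maximal ordinal suborders of a projected dataset
#'
#' Enumerates every class sequence admitting an accepted ordinal cascade
#' at the given sensitivity floor and returns exactly those that are
#' maximal (no single-class insertion at any position yields an accepted
#' cascade). Adjacent-pair classifiers are fitted at most once and reused
#' across candidates; results are independent of exploration order.
#'
#' @param projected a [fit_projection()] result.
#' @param min_sens minimal class-wise sensitivity, in `[0.5, 1]`.
#' @param max_len maximal sequence length screened (default: number of
#'   classes).
#' @param method `"incremental"` (pairwise early rejection, default) or
#'   `"exhaustive"` (brute-force enumeration of all ordered subsets; the
#'   test oracle).
#' @param use_cache memoize pairwise DTCs (results are identical either
#'   way; the flag exists to test that).
#' @return List of maximal `suborder` objects, longest first, in a
#'   canonical deterministic order.
#' @export
screen_suborders <- function(projected, min_sens = 1, max_len = NULL,
                             method = c("incremental", "exhaustive"),
                             use_cache = TRUE) {
  stopifnot(inherits(projected, "projected_dataset"))
  method <- match.arg(method)
  if (!is.numeric(min_sens) || min_sens < 0.5 || min_sens > 1)
    stop2("min_sens must be in [0.5, 1]")
  theta <- 1 - min_sens
  labs <- intersect(projected$labels, unique(projected$y))
  if (is.null(max_len)) max_len <- length(labs)
  cache <- if (use_cache) new.env(parent = emptyenv()) else NULL

  accepted <- new.env(parent = emptyenv())  # key -> cascade
  try_seq <- function(s) {
    key <- seq_key(s)
    if (!is.null(accepted[[key]])) return(accepted[[key]])
    res <- fit_cascade(projected, s, theta, cache = cache)
    accepted[[key]] <- res
    res
  }

  if (method == "incremental") {
    # enumerate chains: adjacent pairwise-feasible sequences
    pair_ok <- function(a, b) !is.null(.fit_dtc_memo(projected, a, b, theta, cache))
    chains <- list()
    frontier <- lapply(labs, identity)
    while (length(frontier)) {
      nxt <- list()
      for (ch in frontier) {
        if (length(ch) >= max_len) next
        lastl <- ch[length(ch)]
        for (b in setdiff(labs, ch)) {
          if (pair_ok(lastl, b)) nxt[[length(nxt) + 1L]] <- c(ch, b)
        }
      }
      chains <- c(chains, nxt)
      frontier <- nxt
    }
    candidates <- chains
  } else {
    # exhaustive: all ordered subsets of length 2..max_len
    candidates <- list()
    recurse <- function(prefix, remaining) {
      if (length(prefix) >= 2L)
        candidates[[length(candidates) + 1L]] <<- prefix
      if (length(prefix) >= max_len) return()
      for (b in remaining)
        recurse(c(prefix, b), setdiff(remaining, b))
    }
    recurse(character(0), labs)
  }

  ok <- Filter(function(s) inherits(try_seq(s), "cascade"), candidates)
  if (!length(ok)) return(list())

  # maximality: no accepted single-class insertion at any position
  is_max <- vapply(ok, function(s) {
    for (u in setdiff(labs, s)) {
      if (length(s) + 1L > max_len) break
      for (pos in 0:length(s)) {
        cand <- append(s, u, after = pos)
        if (inherits(try_seq(cand), "cascade")) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  maximal <- ok[is_max]
  subs <- lapply(maximal, function(s)
    .new_suborder(s, try_seq(s), projected$pair, TRUE))
  .sort_suborders(subs)
}

#' Collapse mirror-image suborders to a canonical orientation
#'
#' Reversed orders arising from swapped projection pairs are mathematical
#' artifacts of the mapping, so orientation carries no information at
#' this stage. When `report_reversed` is `FALSE`, every sequence is
#' brought to its canonical orientation — the lexicographically smaller
#' of `{sequence, reverse(sequence)}` — and duplicates are collapsed, so
#' screening a pair and its swap canonicalize to identical sets. A
#' suborder whose observed orientation was flipped keeps its fitted
#' cascade (valid on the source projection's axis) and is marked
#' `orientation_flipped`; `has_reverse` records whether both orientations
#' were present in the input. When `report_reversed` is `TRUE` both
#' orientations are kept, tagged as mutual reverses.
#'
#' @param suborders list of `suborder` objects (possibly from several
#'   projections).
#' @param report_reversed keep both orientations.
#' @return Canonicalized list of suborders.
#' @export
canonicalize <- function(suborders, report_reversed = FALSE) {
  if (!length(suborders)) return(suborders)
  keys <- vapply(suborders, function(s) seq_key(s$sequence), character(1))
  suborders <- suborders[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  rkeys <- vapply(suborders, function(s) seq_key(rev(s$sequence)), character(1))
  for (i in seq_along(suborders))
    suborders[[i]]$has_reverse <- rkeys[i] %in% keys
  if (report_reversed) return(.sort_suborders(suborders))
  is_canonical <- keys <= rkeys
  out <- list()
  seen <- character(0)
  for (i in order(!is_canonical)) {  # canonical orientations first
    ckey <- if (is_canonical[i]) keys[i] else rkeys[i]
    if (ckey %in% seen) next
    seen <- c(seen, ckey)
    s <- suborders[[i]]
    if (!is_canonical[i]) {
      s$sequence <- rev(s$sequence)
      s$orientation_flipped <- TRUE
    }
    out[[length(out) + 1L]] <- s
  }
  .sort_suborders(out)
}

#' Screen every selected projection pair of a dataset
#'
#' Runs [fit_projection()] + [screen_suborders()] for each pair selected
#' by the configuration and logs the longest suborder length per pair.
#'
#' @param dataset a [labeled_dataset()].
#' @param config a [run_config()].
#' @return Named list (one element per pair, named `"A|B"`) of suborder
#'   lists.
#' @export
screen_all_pairs <- function(dataset, config = run_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"), inherits(config, "run_config"))
  pp <- config$projection_pairs
  pairs <- if (identical(pp, "all")) {
    select_projection_pairs(dataset, "all")
  } else if (identical(pp, "most_distant")) {
    select_projection_pairs(dataset, "most_distant")
  } else {
    select_projection_pairs(dataset, "explicit", pairs = pp)
  }
  out <- lapply(pairs, function(p) {
    proj <- fit_projection(dataset, p)
    subs <- screen_suborders(proj, min_sens = config$min_sensitivity,
                             max_len = config$max_order_length)
    occ_log("pair (", p[1], ",", p[2], "): ", length(subs),
            " maximal suborder(s), longest ",
            if (length(subs)) length(subs[[1]]$sequence) else 0)
    subs
  })
  names(out) <- vapply(pairs, paste, character(1), collapse = "|")
  out
}
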