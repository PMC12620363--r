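# Shared-threshold equivalence and aggregation of suborders into layered
# alternative-progression graphs.
#
# Two thresholds from different suborders are equivalent when they induce
# the same separation boundary in a region where two distinct branch
# classes have the same adjacent (anchor) class: left-shared if the anchor
# precedes both branches, right-shared if it follows both.  The feasible
# shared region is the intersection of the two branch transitions'
# feasible DTC intervals (at theta = 0 this is exactly
# "max anchor value < tau <= min over both branch classes" and its mirror;
# under theta > 0 the same order-statistic budget as fit_dtc applies).

.interval_intersect <- function(a, b) {
  lo <- max(a$lower, b$lower)
  hi <- min(a$upper, b$upper)
  tol <- .region_tol * max(1, abs(lo), abs(hi))
  if (!(lo < hi - tol)) return(NULL)
  list(lower = lo, upper = hi, point = (lo + hi) / 2)
}

#' Test whether two cascade thresholds are equivalent (shared)
#'
#' @param tau_i,tau_j the two fitted [fit_dtc()] classifiers whose
#'   thresholds are compared (taken from the cascades of two suborders).
#' @param context list with elements `anchor` (the common neighboring
#'   class), `branch_a`, `branch_b` (the two branch classes; equal for
#'   the trivial self-equivalent case), `side` (`"left"` if the anchor
#'   precedes both branches, `"right"` if it follows), and optionally
#'   `suborder_a`, `suborder_b` (the two sequences, used to validate
#'   membership preconditions).
#' @param projected the [fit_projection()] result the suborders came from.
#' @param theta misclassification budget.
#' @return An object of class `shared_threshold` (fields `kind`,
#'   `anchor_label`, `branch_labels`, `feasible`) or `NULL` when the
#'   shared region is empty.
#' @export
thresholds_equivalent <- function(tau_i, tau_j, context, projected, theta = 0) {
  stopifnot(inherits(projected, "projected_dataset"))
  anchor <- context$anchor
  a <- context$branch_a
  b <- context$branch_b
  side <- match.arg(context$side, c("left", "right"))
  if (anchor %in% c(a, b)) stop2("anchor must differ from branch classes")
  if (!is.null(context$suborder_a) && !is.null(context$suborder_b)) {
    oa <- context$suborder_a; ob <- context$suborder_b
    if (!(anchor %in% oa && anchor %in% ob))
      stop2("anchor '", anchor, "' must belong to both suborders")
    if (a != b) {
      if (!(a %in% oa && !(a %in% ob)))
        stop2("branch '", a, "' must belong to the first suborder only")
      if (!(b %in% ob && !(b %in% oa)))
        stop2("branch '", b, "' must belong to the second suborder only")
    }
  }
  anchor_v <- .class_values(projected, anchor)
  fit_side <- function(branch) {
    bv <- .class_values(projected, branch)
    if (side == "left") fit_dtc(anchor_v, bv, theta, anchor, branch)
    else fit_dtc(bv, anchor_v, theta, branch, anchor)
  }
  da <- fit_side(a)
  db <- if (identical(a, b)) da else fit_side(b)
  if (is.null(da) || is.null(db)) return(NULL)
  feas <- .interval_intersect(da$interval, db$interval)
  if (is.null(feas)) return(NULL)
  structure(list(kind = paste0(side, "_shared"), anchor_label = anchor,
                 branch_labels = c(a, b), feasible = feas),
            class = "shared_threshold")
}

#' @export
print.shared_threshold <- function(x, ...) {
  cat(x$kind, ": anchor ", x$anchor_label, ", branches {",
      paste(unique(x$branch_labels), collapse = ", "), "}, region (",
      format(x$feasible$lower), ", ", format(x$feasible$upper), "]\n", sep = "")
  invisible(x)
}

# boundary table of a suborder list: one row per adjacent transition
.boundary_table <- function(suborders) {
  rows <- list()
  for (i in seq_along(suborders)) {
    s <- suborders[[i]]
    k <- length(s$sequence)
    for (j in seq_len(k - 1L)) {
      d <- s$cascade$classifiers[[j]]
      rows[[length(rows) + 1L]] <- data.frame(
        suborder = i, position = j,
        left = s$sequence[j], right = s$sequence[j + 1L],
        lower = d$interval$lower, upper = d$interval$upper,
        point = d$interval$point, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# union-find helpers
.uf_new <- function(n) seq_len(n)
.uf_find <- function(p, i) { while (p[i] != i) i <- p[i]; i }
.uf_union <- function(p, i, j) { p[.uf_find(p, i)] <- .uf_find(p, j); p }

#' Aggregate suborders into a layered alternative-progression graph
#'
#' Pairwise-tests the suborders' thresholds for left-/right-shared
#' equivalence, merges equivalent boundaries by transitive closure, and
#' derives layers: boundary groups crossed by no class segment become
#' global cuts, and the classes between consecutive cuts form one layer
#' in which chains from different suborders are parallel alternatives.
#' Suborders over disjoint class sets stay in separate components.
#'
#' @param suborders list of `suborder` objects from the *same* projection.
#' @param projected the shared [fit_projection()] result.
#' @param theta misclassification budget used for the shared regions
#'   (default 0, i.e. sensitivity floor 1).
#' @return An object of class `alternative_graph`: fields `components`
#'   (each with `classes`, `layers` — lists of units, a unit being an
#'   ordered class chain — and `cuts`), `edges` (data frame of precedence
#'   links with threshold intervals), `suborders`, `pair`, `theta`.
#' @export
aggregate_alternatives <- function(suborders, projected, theta = 0) {
  stopifnot(inherits(projected, "projected_dataset"))
  if (!length(suborders)) stop2("no suborders to aggregate")
  for (s in suborders) stopifnot(inherits(s, "suborder"))
  pairs_src <- unique(vapply(suborders, function(s) paste(s$source_pair, collapse = "|"),
                             character(1)))
  if (length(pairs_src) > 1L)
    stop2("suborders come from different projections: ",
          paste(pairs_src, collapse = " vs "))
  if (pairs_src != paste(projected$pair, collapse = "|"))
    stop2("suborders do not match the supplied projection")

  seqs <- lapply(suborders, `[[`, "sequence")
  ns <- length(suborders)

  # components: suborders linked by any common class
  comp <- .uf_new(ns)
  if (ns > 1L) for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns)
    if (length(intersect(seqs[[i]], seqs[[j]])))
      comp <- .uf_union(comp, i, j)
  comp_id <- vapply(seq_len(ns), function(i) .uf_find(comp, i), integer(1))

  bt <- .boundary_table(suborders)
  nb <- nrow(bt)
  class_mean <- vapply(unique(unlist(seqs)), function(l)
    mean(.class_values(projected, l)), numeric(1))

  # boundary equivalence by shared thresholds (within components)
  buf <- .uf_new(nb)
  shared <- list()
  if (nb > 1L) for (i in seq_len(nb - 1L)) for (j in (i + 1L):nb) {
    si <- bt$suborder[i]; sj <- bt$suborder[j]
    if (si == sj || comp_id[si] != comp_id[sj]) next
    same_transition <- bt$left[i] == bt$left[j] && bt$right[i] == bt$right[j]
    if (same_transition) { buf <- .uf_union(buf, i, j); next }
    eq <- NULL
    if (bt$left[i] == bt$left[j] &&
        bt$right[i] %in% setdiff(seqs[[si]], seqs[[sj]]) &&
        bt$right[j] %in% setdiff(seqs[[sj]], seqs[[si]])) {
      eq <- thresholds_equivalent(
        suborders[[si]]$cascade$classifiers[[bt$position[i]]],
        suborders[[sj]]$cascade$classifiers[[bt$position[j]]],
        list(anchor = bt$left[i], branch_a = bt$right[i],
             branch_b = bt$right[j], side = "left",
             suborder_a = seqs[[si]], suborder_b = seqs[[sj]]),
        projected, theta)
    } else if (bt$right[i] == bt$right[j] &&
               bt$left[i] %in% setdiff(seqs[[si]], seqs[[sj]]) &&
               bt$left[j] %in% setdiff(seqs[[sj]], seqs[[si]])) {
      eq <- thresholds_equivalent(
        suborders[[si]]$cascade$classifiers[[bt$position[i]]],
        suborders[[sj]]$cascade$classifiers[[bt$position[j]]],
        list(anchor = bt$right[i], branch_a = bt$left[i],
             branch_b = bt$left[j], side = "right",
             suborder_a = seqs[[si]], suborder_b = seqs[[sj]]),
        projected, theta)
    }
    if (!is.null(eq)) {
      buf <- .uf_union(buf, i, j)
      shared[[length(shared) + 1L]] <- eq
    }
  }
  bt$group <- vapply(seq_len(nb), function(i) .uf_find(buf, i), integer(1))
  gpos <- tapply(bt$point, bt$group, mean)

  components <- list()
  for (cid in sort(unique(comp_id))) {
    sub_idx <- which(comp_id == cid)
    crows <- bt[bt$suborder %in% sub_idx, , drop = FALSE]
    groups <- unique(crows$group)
    pos <- gpos[as.character(groups)]
    # class segments: each class occurrence spans (left boundary group
    # position, right boundary group position), +-Inf at sequence ends
    seg <- list()
    for (i in sub_idx) {
      s <- seqs[[i]]
      brows <- crows[crows$suborder == i, , drop = FALSE]
      bpos <- gpos[as.character(brows$group[order(brows$position)])]
      for (ci in seq_along(s)) {
        lo <- if (ci == 1L) -Inf else bpos[ci - 1L]
        hi <- if (ci == length(s)) Inf else bpos[ci]
        seg[[length(seg) + 1L]] <- list(class = s[ci], lo = lo, hi = hi)
      }
    }
    # cuts: groups crossed by no segment
    tol <- .region_tol * max(1, max(abs(crows$point)))
    crossed <- vapply(groups, function(g) {
      p <- gpos[as.character(g)]
      any(vapply(seg, function(sg) sg$lo < p - tol && p + tol < sg$hi,
                 logical(1)))
    }, logical(1))
    cuts <- sort(pos[!crossed])
    layer_of <- function(lo) sum(cuts <= lo + tol) + 1L
    cls_layer <- new.env(parent = emptyenv())
    for (sg in seg) {
      li <- layer_of(sg$lo)
      prev <- cls_layer[[sg$class]]
      cls_layer[[sg$class]] <- if (is.null(prev)) li else min(prev, li)
    }
    comp_classes <- unique(unlist(seqs[sub_idx]))
    lidx <- vapply(comp_classes, function(cl) cls_layer[[cl]], integer(1))
    # units: within a layer, classes adjacent in some suborder chain up
    layers <- list()
    for (li in sort(unique(lidx))) {
      in_layer <- comp_classes[lidx == li]
      up <- .uf_new(length(in_layer))
      for (i in sub_idx) {
        s <- seqs[[i]]
        for (j in seq_len(length(s) - 1L)) {
          ai <- match(s[j], in_layer); bi <- match(s[j + 1L], in_layer)
          if (!is.na(ai) && !is.na(bi)) up <- .uf_union(up, ai, bi)
        }
      }
      roots <- vapply(seq_along(in_layer), function(i) .uf_find(up, i), integer(1))
      units <- lapply(unique(roots), function(r) {
        u <- in_layer[roots == r]
        u[order(class_mean[u])]
      })
      units <- units[order(vapply(units, `[`, character(1), 1))]
      layers[[length(layers) + 1L]] <- units
    }
    components[[length(components) + 1L]] <-
      list(classes = comp_classes[order(class_mean[comp_classes])],
           layers = layers, cuts = unname(cuts),
           suborders = sub_idx)
  }

  edges <- unique(bt[, c("left", "right", "lower", "upper", "point", "group")])
  edges <- edges[order(edges$point, edges$left), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(components = components, edges = edges,
                 suborders = suborders, shared = shared,
                 pair = projected$pair, theta = theta),
            class = "alternative_graph")
}

#' @export
print.alternative_graph <- function(x, ...) {
  cat("alternative_graph: pair (", paste(x$pair, collapse = ","), "), ",
      length(x$components), " component(s), ",
      length(x$suborders), " suborder(s)\n", sep = "")
  for (ci in seq_along(x$components)) {
    comp <- x$components[[ci]]
    cat(" component ", ci, ": ", paste(vapply(comp$layers, function(units)
      paste0("{", paste(vapply(units, function(u)
        paste0("(", paste(u, collapse = "<"), ")"), character(1)),
        collapse = " | "), "}"), character(1)), collapse = " -> "), "\n",
      sep = "")
  }
  invisible(x)
}

#' Is a class sequence a path through an alternative graph?
#'
#' Checks that every consecutive pair of the sequence is an edge of the
#' graph (path conservation: every contributing suborder must satisfy
#' this).
#'
#' @param graph an [aggregate_alternatives()] result.
#' @param sequence character vector of class labels.
#' @return Logical.
#' @export
graph_contains_path <- function(graph, sequence) {
  stopifnot(inherits(graph, "alternative_graph"))
  if (length(sequence) < 2L) return(TRUE)
  e <- paste(graph$edges$left, graph$edges$right, sep = "\r")
  all(paste(sequence[-length(sequence)], sequence[-1], sep = "\r") %in% e)
}

#' Render an alternative graph in DOT format
#'
#' Layers are written as `cluster_comp<i>_layer<j>` subgraphs with
#' `rank=same`; edges carry the threshold point as a label.
#'
#' @param graph an [aggregate_alternatives()] result.
#' @return A single character string containing the DOT source.
#' @export
as_dot <- function(graph) {
  stopifnot(inherits(graph, "alternative_graph"))
  q <- function(x) paste0('"', x, '"')
  out <- c("digraph alternatives {", "  rankdir=LR;")
  for (ci in seq_along(graph$components)) {
    comp <- graph$components[[ci]]
    for (li in seq_along(comp$layers)) {
      units <- comp$layers[[li]]
      out <- c(out,
        sprintf("  subgraph cluster_comp%d_layer%d {", ci, li),
        sprintf('    label="layer %d";', li),
        paste0("    ", paste(q(unlist(units)), collapse = "; "), ";"),
        "  }")
    }
  }
  for (i in seq_len(nrow(graph$edges))) {
    e <- graph$edges[i, ]
    out <- c(out, sprintf('  %s -> %s [label="%.4g"];',
                          q(e$left), q(e$right), e$point))
  }
  paste(c(out, "}"), collapse = "\n")
}
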