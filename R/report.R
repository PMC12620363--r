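# Structured-text results: suborder report (JSON, full double precision so
# a round-trip reconstructs sequences and thresholds exactly), a
# human-readable text table, and the alternative graph as DOT + JSON.

.suborder_to_record <- function(s) {
  list(sequence = as.list(s$sequence),
       source_pair = as.list(s$source_pair),
       min_sensitivity = s$min_sensitivity,
       is_maximal = isTRUE(s$is_maximal),
       has_reverse = isTRUE(s$has_reverse %||% FALSE),
       sensitivities = as.list(s$cascade$sensitivities),
       thresholds = lapply(s$cascade$classifiers, function(d)
         list(left = d$left_label, right = d$right_label,
              lower = d$interval$lower, upper = d$interval$upper,
              point = d$interval$point,
              left_sens = d$left_sens, right_sens = d$right_sens)))
}

#' Write screening and aggregation results to a directory
#'
#' Emits `suborders.json` (exact-precision structured report; reloading
#' it with [read_suborder_report()] reconstructs every sequence and
#' threshold), `suborders.txt` (human-readable), and — when a graph is
#' supplied — `graph.dot` and `graph.json`.
#'
#' @param suborders list of `suborder` objects.
#' @param graph optional [aggregate_alternatives()] result.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(suborders, graph = NULL, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop2("cannot create output directory: ", out_dir)
  records <- lapply(suborders, .suborder_to_record)
  jsonlite::write_json(records, file.path(out_dir, "suborders.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  txt <- c(sprintf("# %d maximal suborder(s)", length(suborders)),
           vapply(suborders, function(s)
             sprintf("%s\tmin_sens=%s\tpair=(%s)",
                     paste(s$sequence, collapse = "<"),
                     format(s$min_sensitivity),
                     paste(s$source_pair, collapse = ",")), character(1)))
  writeLines(txt, file.path(out_dir, "suborders.txt"))
  if (!is.null(graph)) {
    writeLines(as_dot(graph), file.path(out_dir, "graph.dot"))
    gj <- list(pair = as.list(graph$pair), theta = graph$theta,
               components = lapply(graph$components, function(comp)
                 list(classes = as.list(comp$classes),
                      cuts = as.list(comp$cuts),
                      layers = lapply(comp$layers, function(units)
                        lapply(units, as.list)))),
               edges = graph$edges)
    jsonlite::write_json(gj, file.path(out_dir, "graph.json"),
                         auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  }
  invisible(out_dir)
}

#' Reload a structured suborder report
#'
#' Inverse of the `suborders.json` part of [write_results()]: returns a
#' list of records with `sequence`, `source_pair`, `min_sensitivity`,
#' `sensitivities` and per-transition `thresholds` identical to the
#' written values.
#'
#' @param path path to `suborders.json`.
#' @return List of suborder records.
#' @export
read_suborder_report <- function(path) {
  recs <- jsonlite::read_json(path)
  lapply(recs, function(r) {
    r$sequence <- as.character(unlist(r$sequence))
    r$source_pair <- as.character(unlist(r$source_pair))
    r$sensitivities <- unlist(r$sensitivities)
    r$thresholds <- lapply(r$thresholds, function(th) {
      th[c("lower", "upper", "point", "left_sens", "right_sens")] <-
        lapply(th[c("lower", "upper", "point", "left_sens", "right_sens")],
               as.numeric)
      th
    })
    r
  })
}
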