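# shared test helpers: in-code fixtures and independent oracles

# projected_dataset built directly from 1-D values, bypassing the
# projection stage (tests DTC / cascade / screening logic in isolation)
projected_from_values <- function(values, y, pair = c(NA, NA),
                                  labels = unique(y)) {
  structure(list(values = as.numeric(values), y = as.character(y),
                 sample_ids = paste0("s", seq_along(values)),
                 labels = labels, pair = as.character(pair),
                 direction_norm = 1, training_error = 0),
            class = "projected_dataset")
}

# sample a labeled 1-D dataset from an interval layout (plus optional noise
# feature) and return the projected view on feature 1
projected_from_intervals <- function(intervals, n_per_class = 8L, seed = 1L) {
  set.seed(seed)
  labs <- names(intervals)
  vals <- unlist(lapply(intervals, function(iv) runif(n_per_class, iv[1], iv[2])))
  projected_from_values(vals, rep(labs, each = n_per_class), labels = labs)
}

# random interval layout: k classes, random centers/widths, some overlaps
random_interval_layout <- function(k, seed) {
  set.seed(seed)
  centers <- sort(runif(k, 0, 10))
  widths <- runif(k, 0.3, 3)
  iv <- lapply(seq_len(k), function(i)
    c(centers[i] - widths[i] / 2, centers[i] + widths[i] / 2))
  names(iv) <- paste0("c", seq_len(k))
  iv
}

# brute-force feasibility oracle for a single DTC: counts misclassified
# samples at a candidate threshold directly from the definition
dtc_feasible_at <- function(tau, left, right, theta) {
  sum(left >= tau) <= floor(theta * length(left)) &&
    sum(right < tau) <= floor(theta * length(right))
}

# dense candidate grid covering every decision-relevant threshold:
# all data values, midpoints between consecutive distinct values, and
# points just outside the data range
dtc_candidate_grid <- function(left, right) {
  v <- sort(unique(c(left, right)))
  mids <- (utils::head(v, -1) + utils::tail(v, -1)) / 2
  eps <- max(diff(range(v)), 1) * 1e-7
  sort(unique(c(v, mids, v - eps, v + eps, min(v) - 1, max(v) + 1)))
}

# sequence keys for set comparison
seq_keys <- function(suborders)
  sort(vapply(suborders, function(s) paste(s$sequence, collapse = "<"),
              character(1)))

# layer signature of an alternative graph component:
# "unit|unit" per layer, units as a<b chains
layer_signature <- function(component) {
  vapply(component$layers, function(units)
    paste(sort(vapply(units, paste, character(1), collapse = "<")),
          collapse = "|"), character(1))
}

figure4_caption_len6 <- list(
  c("l0", "l1", "l2", "l3", "l4", "l5"),
  c("l0", "l1", "l2", "l8", "l4", "l5"),
  c("l0", "l1", "l7", "l3", "l4", "l5"),
  c("l0", "l1", "l7", "l8", "l4", "l5"))

# length-5 set: (l0,l1) -> l6 and (l4,l5) -> l9, one replacement at a time
figure4_caption_len5 <- local({
  out <- list()
  for (s in figure4_caption_len6) {
    out[[length(out) + 1L]] <- c("l6", s[3:6])
    out[[length(out) + 1L]] <- c(s[1:4], "l9")
  }
  out
})
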