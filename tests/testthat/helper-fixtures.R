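# shared fixtures
test_beam <- function(photon_mode = "two-photon")
  beam_geometry(0.4, 2.0, photon_mode)

water25 <- function() physical_conditions(298.15, 0.89)

# independent brute-force greedy clustering oracle: recompute neighbour
# counts by explicit loops at every extraction step
brute_daura <- function(dm, cutoff) {
  nf <- nrow(dm)
  remaining <- seq_len(nf)
  clusters <- list()
  centers <- integer(0)
  while (length(remaining) > 0) {
    best_count <- -1L
    best_frame <- NA_integer_
    for (f in remaining) {
      cnt <- 0L
      for (g in remaining) if (dm[f, g] <= cutoff) cnt <- cnt + 1L
      if (cnt > best_count) {  # strict >: first (lowest) frame wins ties
        best_count <- cnt
        best_frame <- f
      }
    }
    members <- remaining[vapply(remaining, function(g)
      dm[best_frame, g] <= cutoff, logical(1))]
    clusters[[length(clusters) + 1L]] <- sort(members)
    centers <- c(centers, best_frame)
    remaining <- setdiff(remaining, members)
  }
  list(clusters = clusters, centers = centers)
}

cluster_sets <- function(cl) {
  unname(lapply(split(seq_along(cl$assignments), cl$assignments), sort))
}
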