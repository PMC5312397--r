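# Shared fixtures and independent oracles. Oracles deliberately use naive
# per-element logic so they stay independent of the vectorized paths they
# check.

tiny_config <- function(n_loci = 8, ...) sim_config(n_loci = n_loci, ...)

noiseless_config <- function(n_loci = 8, ...) {
  sim_config(n_loci = n_loci, plateau_cv = 0, ct_sd = 0, baseline_sd = 0, ...)
}

# single-sample slice of a calls table
one_profile <- function(calls, id) calls[calls$sample_id == id, ]

# Exhaustive per-locus comparison oracle: explicit decision per call pair.
oracle_compare <- function(ca, cb, y_linked) {
  det <- c("HOM1", "HOM2", "HET")
  hom <- c("HOM1", "HOM2")
  n_inf <- n_match <- n_strong <- n_weak <- n_undet <- 0L
  for (i in seq_along(ca)) {
    a <- ca[i]; b <- cb[i]
    if (y_linked[i] && a == "NOAMP" && b == "NOAMP") next
    if (!(a %in% det) || !(b %in% det)) {
      n_undet <- n_undet + 1L
      next
    }
    n_inf <- n_inf + 1L
    if (a == b) {
      n_match <- n_match + 1L
    } else if (a %in% hom && b %in% hom) {
      n_strong <- n_strong + 1L
    } else {
      n_weak <- n_weak + 1L
    }
  }
  list(n_informative = n_inf, n_match = n_match,
       n_strong_mismatch = n_strong, n_weak_mismatch = n_weak,
       n_undetermined = n_undet,
       concordance = if (n_inf > 0) n_match / n_inf else NA_real_)
}

# Naive agglomerative clustering: repeatedly merge the closest pair of
# clusters under average or complete linkage computed from the original
# distance matrix. Returns the sorted merge heights.
oracle_agglomerate <- function(dmat, linkage = "average") {
  clusters <- as.list(seq_len(nrow(dmat)))
  heights <- numeric(0)
  link <- function(ci, cj) {
    vals <- dmat[ci, cj, drop = FALSE]
    if (linkage == "average") mean(vals) else max(vals)
  }
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- link(clusters[[i]], clusters[[j]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Build a two-reference male cohort plus registry for mixture experiments.
mixture_fixture <- function(config = sim_config(), seed = 11) {
  cohort <- simulate_profiles(2, config, sex = c("MALE", "MALE"),
                              prefix = "REF", seed = seed)
  list(cohort = cohort,
       registry = assign_references(cohort$calls, panel = config$panel))
}
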