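# Pairwise barcode comparison: the unit the validator, the clustering
# distance and the registry duplicate check are all built on.

# Per-locus classification of a pair of call vectors (same assay order).
# Y-linked loci where both calls are NOAMP are concordant sex dropout and
# are excluded from every count.
pair_counts <- function(ca, cb, y_linked) {
  stopifnot(length(ca) == length(cb), length(y_linked) == length(ca))
  y_concordant <- y_linked & ca == "NOAMP" & cb == "NOAMP"
  det_a <- ca %in% .determined
  det_b <- cb %in% .determined
  informative <- det_a & det_b & !y_concordant
  hom_a <- ca %in% c("HOM1", "HOM2")
  hom_b <- cb %in% c("HOM1", "HOM2")
  strong <- informative & hom_a & hom_b & ca != cb
  weak <- informative & (xor(hom_a, hom_b))
  match <- informative & ca == cb
  undet <- !y_concordant & (!det_a | !det_b)
  tibble::tibble(
    n_informative = sum(informative),
    n_match = sum(match),
    n_strong_mismatch = sum(strong),
    n_weak_mismatch = sum(weak),
    n_undetermined = sum(undet),
    concordance = if (sum(informative) > 0) {
      sum(match) / sum(informative)
    } else NA_real_
  )
}

#' Compare two barcode profiles
#'
#' Counts, over the loci where both profiles carry a determined genotype
#' (`HOM1`/`HET`/`HOM2`): exact matches, strong mismatches (opposite
#' homozygotes — impossible without a genotype difference), and weak
#' mismatches (homozygote vs heterozygote — a single-allele discrepancy
#' that copy-number imbalance can also produce). Loci where either call is
#' `NOAMP`/`UNDET` count as undetermined, except Y-linked loci at which both
#' profiles show concordant no-amplification (matching female samples),
#' which are excluded entirely. The comparison is symmetric.
#'
#' @param calls_a,calls_b Calls tibbles, one sample each, covering `panel`.
#' @param panel Assay panel tibble.
#' @return One-row tibble: `n_informative`, `n_match`, `n_strong_mismatch`,
#'   `n_weak_mismatch`, `n_undetermined`, `concordance`.
#' @examples
#' cfg <- sim_config(n_loci = 8)
#' co <- simulate_profiles(2, cfg, seed = 1)
#' compare_profiles(co$calls[co$calls$sample_id == "S001", ],
#'                  co$calls[co$calls$sample_id == "S002", ], cfg$panel)
#' @export
compare_profiles <- function(calls_a, calls_b, panel = snp_panel()) {
  for (x in list(calls_a, calls_b)) {
    if (length(unique(x$sample_id)) != 1) {
      stop("compare_profiles() takes exactly one sample per side",
           call. = FALSE)
    }
  }
  check_calls(calls_a, panel, "calls_a")
  check_calls(calls_b, panel, "calls_b")
  ord <- panel$assay_id
  ca <- calls_a$call[match(ord, calls_a$assay_id)]
  cb <- calls_b$call[match(ord, calls_b$assay_id)]
  pair_counts(ca, cb, panel$y_linked)
}

# Compare every sample in `calls` against every registry reference.
# Returns one row per sample x reference. Vectorized across the call
# matrices so validating a cohort stays fast.
compare_to_registry <- function(calls, registry) {
  panel <- registry$panel
  m_s <- calls_matrix(calls, panel)
  m_r <- calls_matrix(
    registry$calls |> dplyr::rename(sample_id = "reference_id"), panel)
  out <- vector("list", nrow(m_s) * nrow(m_r))
  k <- 1L
  for (i in seq_len(nrow(m_s))) {
    for (j in seq_len(nrow(m_r))) {
      cc <- pair_counts(m_s[i, ], m_r[j, ], panel$y_linked)
      cc$sample_id <- rownames(m_s)[i]
      cc$reference_id <- rownames(m_r)[j]
      out[[k]] <- cc
      k <- k + 1L
    }
  }
  dplyr::bind_rows(out) |>
    dplyr::relocate("sample_id", "reference_id")
}
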