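# Integrated 32-SNP contamination detection: per-locus signal evidence is
# aggregated across the whole panel to separate true mixtures from
# amplification failure, name the likely second contributor, and estimate
# the contaminant fraction.

dispositions <- c("CONTAMINATED", "INEFFICIENT_AMPLIFICATION", "CLEAN")

# Panel loci covered by a reference's karyotype regions (1-based inclusive).
cnv_loci <- function(registry, reference_id) {
  kt <- registry$karyotype[registry$karyotype$reference_id == reference_id, ]
  if (nrow(kt) == 0) return(character())
  p <- registry$panel
  hit <- rep(FALSE, nrow(p))
  for (i in seq_len(nrow(kt))) {
    hit <- hit | (p$chromosome == as.character(kt$chromosome[i]) &
                    p$position >= kt$start[i] & p$position <= kt$end[i])
  }
  p$assay_id[hit]
}

# Allele implicated as foreign at a flagged locus: the minor allele for an
# expected homozygote, the enriched allele for a deviated heterozygote.
implicated_allele <- function(expected, angle) {
  dplyr::case_when(
    expected == "HOM1" ~ 2L,
    expected == "HOM2" ~ 1L,
    expected == "HET" & angle > 45 ~ 2L,
    expected == "HET" ~ 1L,
    TRUE ~ NA_integer_
  )
}

carries_allele <- function(call, allele) {
  (allele == 1L & call %in% c("HOM1", "HET")) |
    (allele == 2L & call %in% c("HOM2", "HET"))
}

#' Detect cross-contamination from the integrated panel signal
#'
#' Computes [locus_evidence()] for every locus against the expected
#' reference profile and aggregates it across the panel. A locus is flagged
#' when, at adequate magnitude, it shows late amplification of the
#' unexpected allele's channel (expected homozygote) or an endpoint angle
#' deviating more than `deviation_min` degrees from the nearest canonical
#' cluster. Loci inside the expected reference's annotated copy-number
#' regions are exempt from angle-deviation evidence, since allelic imbalance
#' there is a stable property of the line, not contamination.
#'
#' Disposition: `CONTAMINATED` when at least `k_flagged` loci are flagged
#' (multi-locus corroboration guards against single-probe artifacts);
#' `INEFFICIENT_AMPLIFICATION` when weakly amplified or undetermined loci
#' exist but angles stay canonical; `CLEAN` otherwise. For contaminated
#' samples the registry reference most consistent with the implicated minor
#' alleles is reported as the implied second contributor — only when its
#' consistency beats the runner-up by `contributor_margin` — together with a
#' median per-locus estimate of the contaminant fraction.
#'
#' @param traces Trace tibble (one or more samples); must cover at least
#'   75\% of panel loci per sample.
#' @param expected A reference ID applied to all samples, or a tibble with
#'   `sample_id` and `expected_reference`.
#' @param registry A `pas_registry`.
#' @param thresholds A [pas_thresholds()].
#' @return One row per sample: `disposition`, `n_flagged`, `n_weak_undet`,
#'   `implied_second_contributor`, `contributor_consistency`,
#'   `estimated_fraction`, and the per-locus `evidence` tibble as a
#'   list-column.
#' @export
detect_contamination <- function(traces, expected, registry,
                                 thresholds = pas_thresholds()) {
  stopifnot(inherits(registry, "pas_registry"))
  th <- thresholds
  ids <- unique(traces$sample_id)
  if (is.character(expected) && is.null(dim(expected)) &&
      length(expected) == 1) {
    expected <- tibble::tibble(sample_id = ids, expected_reference = expected)
  }
  unknown <- setdiff(expected$expected_reference,
                     registry$metadata$reference_id)
  if (length(unknown) > 0) {
    stop(sprintf("expected reference(s) not in registry: %s",
                 paste(unique(unknown), collapse = ", ")), call. = FALSE)
  }
  panel <- registry$panel
  cover <- traces |>
    dplyr::distinct(.data$sample_id, .data$assay_id) |>
    dplyr::count(.data$sample_id)
  low <- cover$sample_id[cover$n < 0.75 * nrow(panel)]
  if (length(low) > 0) {
    stop(sprintf(
      "traces cover fewer than 75%% of panel loci for sample(s): %s",
      paste(low, collapse = ", ")), call. = FALSE)
  }

  rows <- lapply(ids, function(sid) {
    exp_ref <- expected$expected_reference[match(sid, expected$sample_id)]
    ref_calls <- registry$calls[registry$calls$reference_id == exp_ref, ]
    ev <- locus_evidence(
      traces[traces$sample_id == sid, ],
      tibble::tibble(assay_id = ref_calls$assay_id, call = ref_calls$call),
      th
    ) |>
      estimate_allele_fraction(th)
    exempt <- cnv_loci(registry, exp_ref)
    ev <- dplyr::mutate(
      ev,
      cnv_exempt = .data$assay_id %in% exempt,
      adequate = .data$magnitude >= th$noamp,
      flagged = .data$adequate &
        .data$expected %in% .determined &
        (.data$late_minor_amplification |
           (!.data$cnv_exempt & .data$deviation_deg > th$deviation_min))
    )
    n_flagged <- sum(ev$flagged)
    n_weak_undet <- sum(ev$weak_amplification |
                          (ev$call %in% c("UNDET", "NOAMP") &
                             ev$expected %in% .determined))
    disposition <- if (n_flagged >= th$k_flagged) {
      "CONTAMINATED"
    } else if (n_weak_undet > 0) {
      "INEFFICIENT_AMPLIFICATION"
    } else {
      "CLEAN"
    }

    implied <- NA_character_
    consistency <- NA_real_
    est_fraction <- NA_real_
    if (disposition == "CONTAMINATED") {
      fl <- ev[ev$flagged, ]
      fl$allele <- implicated_allele(fl$expected, fl$angle_deg)
      fl <- fl[!is.na(fl$allele), ]
      cand <- setdiff(registry$metadata$reference_id, exp_ref)
      if (nrow(fl) > 0 && length(cand) > 0) {
        scores <- vapply(cand, function(cid) {
          cc <- registry$calls[registry$calls$reference_id == cid, ]
          obs <- cc$call[match(fl$assay_id, cc$assay_id)]
          mean(carries_allele(obs, fl$allele))
        }, numeric(1))
        ord <- order(scores, decreasing = TRUE)
        best <- cand[ord[1]]
        gap <- if (length(scores) > 1) {
          scores[ord[1]] - scores[ord[2]]
        } else Inf
        if (gap >= th$contributor_margin) {
          implied <- best
          consistency <- unname(scores[ord[1]])
        }
      }
      # contaminant fraction from expected-homozygous flagged loci: the
      # minor-allele template fraction maps to sample fraction through the
      # contributor's allele dosage (2 copies assumed when unknown)
      hom_fl <- fl[fl$expected %in% c("HOM1", "HOM2"), ]
      if (nrow(hom_fl) > 0) {
        minor_frac <- ifelse(hom_fl$expected == "HOM1",
                             hom_fl$allele2_fraction,
                             1 - hom_fl$allele2_fraction)
        copies <- rep(2, nrow(hom_fl))
        if (!is.na(implied)) {
          cc <- registry$calls[registry$calls$reference_id == implied, ]
          obs <- cc$call[match(hom_fl$assay_id, cc$assay_id)]
          copies <- ifelse(obs == "HET", 1,
                           ifelse(carries_allele(obs, hom_fl$allele), 2, NA))
        }
        f_loc <- 2 * minor_frac / copies
        f_loc <- f_loc[!is.na(f_loc)]
        if (length(f_loc) > 0) {
          est_fraction <- min(1, stats::median(f_loc))
        }
      }
    }

    tibble::tibble(
      sample_id = sid,
      expected_reference = exp_ref,
      disposition = disposition,
      n_flagged = n_flagged,
      n_weak_undet = n_weak_undet,
      implied_second_contributor = implied,
      contributor_consistency = consistency,
      estimated_fraction = est_fraction,
      evidence = list(ev)
    )
  })
  dplyr::bind_rows(rows)
}

#' Estimate the mixture fraction of a two-contributor sample
#'
#' Uses the loci at which the two hypothesized contributors are homozygous
#' for opposite alleles — there, the minor-allele template fraction equals
#' the second contributor's sample fraction directly. The estimate is the
#' median across informative loci of the per-locus allele-fraction estimate
#' (rise-cycle based, see [estimate_allele_fraction()]).
#'
#' @param traces Trace tibble for one sample.
#' @param calls_a Calls of the assumed major contributor (reference).
#' @param calls_b Calls of the hypothesized second contributor.
#' @param panel Assay panel tibble.
#' @param thresholds A [pas_thresholds()].
#' @return One-row tibble: `estimate` (fraction of `calls_b`'s DNA, `NA`
#'   when no informative locus exists), `n_informative_loci`, `note`.
#' @export
estimate_mixture_fraction <- function(traces, calls_a, calls_b,
                                      panel = snp_panel(),
                                      thresholds = pas_thresholds()) {
  th <- thresholds
  a <- calls_a$call[match(panel$assay_id, calls_a$assay_id)]
  b <- calls_b$call[match(panel$assay_id, calls_b$assay_id)]
  informative <- (a == "HOM1" & b == "HOM2") | (a == "HOM2" & b == "HOM1")
  informative[is.na(informative)] <- FALSE
  if (!any(informative)) {
    return(tibble::tibble(
      estimate = NA_real_, n_informative_loci = 0L,
      note = "no locus with opposite homozygotes between the two references"))
  }
  loci <- panel$assay_id[informative]
  s <- summarize_traces(traces[traces$assay_id %in% loci, ],
                        rise_threshold = th$rise,
                        noamp_threshold = th$noamp) |>
    estimate_allele_fraction(th)
  minor <- ifelse(a[match(s$assay_id, panel$assay_id)] == "HOM1",
                  s$allele2_fraction, 1 - s$allele2_fraction)
  minor <- minor[!is.na(minor)]
  tibble::tibble(
    estimate = if (length(minor) > 0) stats::median(minor) else NA_real_,
    n_informative_loci = length(loci),
    note = NA_character_
  )
}

#' Track barcode drift across serial passages
#'
#' Estimates, for every locus, the deviation of the allele fraction from
#' the value the expected reference call implies (0 for `HOM1`, 0.5 for
#' `HET`, 1 for `HOM2`), in passage order. A locus drifts when its
#' deviation increases monotonically across passages and ends above
#' `min_final`; panel-level drift (a contaminant out-competing the original
#' line) is declared when at least `k_flagged` loci drift.
#'
#' @param traces Trace tibble covering all passage samples.
#' @param passages Character vector of sample IDs in passage order (length
#'   two or more).
#' @param expected_calls Expected reference profile (`assay_id`, `call`).
#' @param thresholds A [pas_thresholds()].
#' @param min_increase Minimum total increase in deviation counted as drift.
#' @param min_final Minimum final deviation counted as drift.
#' @return A list of class `pas_drift`: `trajectory` (per passage x locus
#'   fraction estimates and deviations), `loci` (per-locus drift flags),
#'   and `drift_detected`.
#' @export
serial_drift_report <- function(traces, passages, expected_calls,
                                thresholds = pas_thresholds(),
                                min_increase = 0.1, min_final = 0.1) {
  stopifnot(length(passages) >= 2)
  th <- thresholds
  target <- c(HOM1 = 0, HET = 0.5, HOM2 = 1)
  traj <- summarize_traces(
    traces[traces$sample_id %in% passages, ],
    rise_threshold = th$rise, noamp_threshold = th$noamp) |>
    estimate_allele_fraction(th) |>
    dplyr::inner_join(
      dplyr::select(expected_calls, "assay_id", expected = "call"),
      by = "assay_id") |>
    dplyr::filter(.data$expected %in% names(target)) |>
    dplyr::mutate(
      passage_rank = match(.data$sample_id, passages),
      deviation = abs(.data$allele2_fraction -
                        target[.data$expected])
    ) |>
    dplyr::arrange(.data$assay_id, .data$passage_rank)
  loci <- traj |>
    dplyr::group_by(.data$assay_id) |>
    dplyr::summarise(
      monotone = all(diff(.data$deviation) >= -1e-9) &&
        dplyr::n() == length(passages),
      increase = .data$deviation[dplyr::n()] - .data$deviation[1],
      final_deviation = .data$deviation[dplyr::n()],
      drifting = .data$monotone & .data$increase >= min_increase &
        .data$final_deviation >= min_final,
      .groups = "drop"
    )
  structure(
    list(trajectory = traj, loci = loci,
         n_drifting = sum(loci$drifting),
         drift_detected = sum(loci$drifting) >= th$k_flagged),
    class = "pas_drift"
  )
}

#' @export
print.pas_drift <- function(x, ...) {
  cat(sprintf("<pas_drift> %d locus/loci drifting; drift %sdetected\n",
              x$n_drifting, if (x$drift_detected) "" else "not "))
  invisible(x)
}
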