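# Sample validation against the reference registry: the decision layer that
# assigns VALIDATED / MISMATCHED / CONTAMINATION_SUSPECT / INCONCLUSIVE.

verdict_levels <- c("VALIDATED", "MISMATCHED", "CONTAMINATION_SUSPECT",
                    "INCONCLUSIVE")

#' Validate samples against their expected references
#'
#' For each sample, the best-fitting reference is the registry profile with
#' the highest concordance (ties are reported as ambiguous, never silently
#' broken). A sample is `VALIDATED` when the best reference is the expected
#' one with no opposite-homozygote mismatch and at most `max_weak`
#' hom-vs-het mismatches; `MISMATCHED` when a different reference fits with
#' zero strong mismatches while the expected one does not — the mis-label
#' scenario; `INCONCLUSIVE` when undetermined genotypes are enriched
#' (`undet_trigger` or more) without signal-level contamination evidence, or
#' when no reference fits. When `traces` are supplied, every sample
#' additionally goes through [detect_contamination()]; a `CONTAMINATED`
#' disposition upgrades the verdict to `CONTAMINATION_SUSPECT`.
#'
#' @param calls Calls tibble (any number of samples).
#' @param expected Tibble with `sample_id` and `expected_reference`, or a
#'   single reference ID applied to every sample.
#' @param registry A `pas_registry`.
#' @param traces Optional trace tibble covering the same samples; enables
#'   signal-level triage of contamination vs inefficient amplification.
#' @param thresholds A [pas_thresholds()].
#' @return One row per sample: `sample_id`, `expected_reference`,
#'   `best_reference`, `status`, `disposition` (`NA` without traces), the
#'   comparison counts against the expected reference, and a `notes`
#'   list-column.
#' @export
validate_samples <- function(calls, expected, registry,
                             traces = NULL, thresholds = pas_thresholds()) {
  stopifnot(inherits(registry, "pas_registry"))
  th <- thresholds
  ids <- unique(calls$sample_id)
  if (is.character(expected) && is.null(dim(expected)) &&
      length(expected) == 1) {
    expected <- tibble::tibble(sample_id = ids, expected_reference = expected)
  }
  stopifnot(all(c("sample_id", "expected_reference") %in% names(expected)))
  unknown <- setdiff(expected$expected_reference,
                     registry$metadata$reference_id)
  if (length(unknown) > 0) {
    stop(sprintf("expected reference(s) not in registry: %s",
                 paste(unique(unknown), collapse = ", ")), call. = FALSE)
  }
  if (length(ids) == 0) {
    return(tibble::tibble(
      sample_id = character(), expected_reference = character(),
      best_reference = character(), status = character(),
      disposition = character(), n_informative = integer(),
      n_match = integer(), n_strong_mismatch = integer(),
      n_weak_mismatch = integer(), n_undetermined = integer(),
      concordance = double(), estimated_fraction = double(),
      implied_second_contributor = character(), notes = list()))
  }
  check_calls(calls, registry$panel, "sample calls")

  cmp <- compare_to_registry(calls, registry)
  reports <- NULL
  if (!is.null(traces)) {
    reports <- detect_contamination(
      traces,
      expected = expected, registry = registry, thresholds = th)
  }

  rows <- lapply(ids, function(sid) {
    exp_ref <- expected$expected_reference[match(sid, expected$sample_id)]
    if (is.na(exp_ref)) {
      stop(sprintf("no expected reference given for sample %s", sid),
           call. = FALSE)
    }
    ci <- cmp[cmp$sample_id == sid, ]
    fits <- ci$n_strong_mismatch <= th$max_strong &
      ci$n_weak_mismatch <= th$max_weak & !is.na(ci$concordance)
    best_conc <- max(ci$concordance, na.rm = TRUE)
    best_ids <- ci$reference_id[!is.na(ci$concordance) &
                                  ci$concordance == best_conc]
    ce <- ci[ci$reference_id == exp_ref, ]
    notes <- character()

    disposition <- NA_character_
    est_fraction <- NA_real_
    implied <- NA_character_
    if (!is.null(reports)) {
      rr <- reports[reports$sample_id == sid, ]
      if (nrow(rr) == 1) {
        disposition <- rr$disposition
        est_fraction <- rr$estimated_fraction
        implied <- rr$implied_second_contributor
      }
    }

    ambiguous <- length(best_ids) > 1
    expected_best <- !ambiguous && identical(best_ids, exp_ref)
    expected_fits <- isTRUE(fits[ci$reference_id == exp_ref])
    other_fit <- ci$reference_id[fits & ci$reference_id != exp_ref &
                                   ci$concordance > ce$concordance]

    status <- if (identical(disposition, "CONTAMINATED")) {
      notes <- c(notes, sprintf(
        "signal-level mixture evidence at %d loci%s", rr$n_flagged,
        if (!is.na(implied)) paste0("; implied second contributor ", implied)
        else ""))
      "CONTAMINATION_SUSPECT"
    } else if (expected_best && expected_fits &&
               ce$n_undetermined < th$undet_trigger) {
      "VALIDATED"
    } else if (length(other_fit) > 0 && !expected_fits) {
      notes <- c(notes, sprintf("best fit is %s, not the expected %s",
                                other_fit[1], exp_ref))
      "MISMATCHED"
    } else if (ce$n_undetermined >= th$undet_trigger) {
      notes <- c(notes, sprintf(
        "%d undetermined loci (trigger %d)%s", ce$n_undetermined,
        th$undet_trigger,
        if (is.na(disposition)) "; no traces available for signal review"
        else paste0("; signal review: ", disposition)))
      "INCONCLUSIVE"
    } else if (ambiguous && exp_ref %in% best_ids && expected_fits) {
      notes <- c(notes, sprintf("tie for best reference among: %s",
                                paste(best_ids, collapse = ", ")))
      "INCONCLUSIVE"
    } else {
      notes <- c(notes, "no registry reference fits within thresholds")
      "INCONCLUSIVE"
    }

    tibble::tibble(
      sample_id = sid,
      expected_reference = exp_ref,
      best_reference = if (ambiguous) NA_character_ else best_ids,
      status = status,
      disposition = disposition,
      n_informative = ce$n_informative,
      n_match = ce$n_match,
      n_strong_mismatch = ce$n_strong_mismatch,
      n_weak_mismatch = ce$n_weak_mismatch,
      n_undetermined = ce$n_undetermined,
      concordance = ce$concordance,
      estimated_fraction = est_fraction,
      implied_second_contributor = implied,
      notes = list(notes)
    )
  })
  dplyr::bind_rows(rows)
}

#' Validate a single sample
#'
#' Convenience wrapper around [validate_samples()] for one profile.
#'
#' @param calls Calls tibble for one sample.
#' @param expected Reference ID the sample is believed to be.
#' @param registry A `pas_registry`.
#' @param traces Optional traces for the sample.
#' @param thresholds A [pas_thresholds()].
#' @return One-row verdict tibble (see [validate_samples()]).
#' @export
validate_sample <- function(calls, expected, registry, traces = NULL,
                            thresholds = pas_thresholds()) {
  validate_samples(calls, expected, registry, traces = traces,
                   thresholds = thresholds)
}
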