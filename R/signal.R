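# Endpoint summaries, genotype calling and per-locus mixture evidence from
# two-channel amplification traces.

first_crossing <- function(f, thr) {
  idx <- which(f > thr)
  if (length(idx) == 0) return(c(NA_real_, NA_real_))
  i <- idx[1]
  interp <- if (i == 1) {
    1
  } else {
    (i - 1) + (thr - f[i - 1]) / (f[i] - f[i - 1])
  }
  c(i, interp)
}

#' Summarize amplification traces per locus
#'
#' Reduces each `sample_id` x `assay_id` trace to its endpoint summary: the
#' allelic-discrimination angle (degrees; 0 = pure allele 1 on the x axis,
#' 90 = pure allele 2, 45 = balanced heterozygote), the endpoint magnitude
#' (sum of both channels), and each channel's rise cycle — the first cycle
#' the channel exceeds `rise_threshold` (`NA` if never). Fractional
#' (interpolated) crossing cycles are also reported; downstream fraction
#' estimates use those for precision.
#'
#' @param traces Long trace tibble (`sample_id`, `assay_id`, `cycle`, `f1`,
#'   `f2`).
#' @param rise_threshold Rise threshold in fluorescence units (> 0).
#' @param noamp_threshold Magnitude below which a locus is treated as
#'   non-amplified (carried through for callers; > 0).
#' @return Tibble with one row per sample x assay: `f1_end`, `f2_end`,
#'   `magnitude`, `angle_deg`, `rise1`, `rise2`, `rise1_x`, `rise2_x`.
#' @export
summarize_traces <- function(traces, rise_threshold = 10,
                             noamp_threshold = 200) {
  stopifnot(rise_threshold > 0, noamp_threshold > 0)
  traces |>
    dplyr::arrange(.data$sample_id, .data$assay_id, .data$cycle) |>
    dplyr::group_by(.data$sample_id, .data$assay_id) |>
    dplyr::summarise(
      f1_end = .data$f1[dplyr::n()],
      f2_end = .data$f2[dplyr::n()],
      rise1 = first_crossing(.data$f1, rise_threshold)[1],
      rise1_x = first_crossing(.data$f1, rise_threshold)[2],
      rise2 = first_crossing(.data$f2, rise_threshold)[1],
      rise2_x = first_crossing(.data$f2, rise_threshold)[2],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      magnitude = .data$f1_end + .data$f2_end,
      angle_deg = atan2(.data$f2_end, .data$f1_end) * 180 / pi
    ) |>
    dplyr::relocate("magnitude", "angle_deg", .after = "f2_end")
}

#' Angular deviation from the nearest canonical genotype cluster
#'
#' Distance in degrees from the closest of the three canonical
#' allelic-discrimination angles (0, 45, 90). Being angular, it is
#' invariant to overall signal intensity.
#'
#' @param angle Endpoint angle(s) in degrees.
#' @return Deviation(s) in degrees, at most 22.5.
#' @export
deviation_deg <- function(angle) {
  pmin(abs(angle), abs(angle - 45), abs(angle - 90))
}

#' Call genotypes from endpoint summaries
#'
#' Applies the magnitude and angle rules of [pas_thresholds()]: `NOAMP`
#' below the no-amplification magnitude, `UNDET` below the weak-signal
#' magnitude (whatever the angle — faint signal cannot be called
#' confidently), otherwise the angle bands assign `HOM1` / `HET` / `HOM2`
#' with `UNDET` in the gaps. Quality decreases with angular distance from
#' the band center and with low magnitude.
#'
#' @param summaries Output of [summarize_traces()].
#' @param thresholds A [pas_thresholds()].
#' @return `summaries` with `call` and `quality` columns appended.
#' @export
call_genotypes <- function(summaries, thresholds = pas_thresholds()) {
  th <- thresholds
  a <- summaries$angle_deg
  m <- summaries$magnitude
  call <- dplyr::case_when(
    m < th$noamp ~ "NOAMP",
    m < th$weak ~ "UNDET",
    a < th$hom1_max ~ "HOM1",
    a >= th$het_min & a <= th$het_max ~ "HET",
    a > th$hom2_min ~ "HOM2",
    TRUE ~ "UNDET"
  )
  center <- c(HOM1 = 0, HET = 45, HOM2 = 90)[call]
  halfw <- c(HOM1 = th$hom1_max, HET = (th$het_max - th$het_min) / 2,
             HOM2 = 90 - th$hom2_min)[call]
  mag_fac <- pmin(1, m / (2 * th$weak))
  quality <- dplyr::case_when(
    call == "NOAMP" ~ pmax(0, 1 - m / th$noamp),
    call == "UNDET" ~ 0.25 * pmin(1, m / th$weak),
    TRUE ~ pmax(0, 1 - abs(a - center) / halfw) * mag_fac
  )
  dplyr::mutate(summaries, call = call, quality = quality)
}

#' Per-locus evidence against an expected profile
#'
#' Compares each locus's trace to the call expected from a reference
#' profile. The contamination signature at a homozygous locus is late
#' amplification of the opposite allele's channel: `late_minor_amplification`
#' is `TRUE` when the expected call is homozygous and the opposite channel
#' crosses the rise threshold within the cycle budget. `weak_amplification`
#' marks loci whose magnitude sits between the no-amplification and
#' confident-call cutoffs (the inefficient-amplification signature), and
#' `deviation_deg` is the angular distance from the nearest canonical
#' cluster — invariant to overall signal intensity.
#'
#' @param traces Trace tibble (may hold several samples).
#' @param expected_calls Tibble with `assay_id` and `call` (applied to every
#'   sample in `traces`), e.g. one reference profile's calls.
#' @param thresholds A [pas_thresholds()].
#' @return Tibble with one row per sample x assay: observed `call`,
#'   `expected`, `angle_deg`, `magnitude`, `deviation_deg`,
#'   `late_minor_amplification`, `weak_amplification`, `minor_rise`,
#'   `major_rise`.
#' @export
locus_evidence <- function(traces, expected_calls,
                           thresholds = pas_thresholds()) {
  th <- thresholds
  ev <- summarize_traces(traces, rise_threshold = th$rise,
                         noamp_threshold = th$noamp) |>
    call_genotypes(th) |>
    dplyr::inner_join(
      dplyr::select(expected_calls, "assay_id", expected = "call"),
      by = "assay_id"
    )
  minor_rise <- ifelse(ev$expected == "HOM1", ev$rise2_x,
                       ifelse(ev$expected == "HOM2", ev$rise1_x, NA_real_))
  major_rise <- ifelse(ev$expected == "HOM1", ev$rise1_x,
                       ifelse(ev$expected == "HOM2", ev$rise2_x, NA_real_))
  dplyr::mutate(
    ev,
    deviation_deg = deviation_deg(.data$angle_deg),
    minor_rise = minor_rise,
    major_rise = major_rise,
    late_minor_amplification = .data$expected %in% c("HOM1", "HOM2") &
      !is.na(minor_rise),
    weak_amplification = .data$magnitude >= th$noamp &
      .data$magnitude < th$weak
  )
}

#' Estimate the allele-2 template fraction per locus
#'
#' Converts the rise-cycle difference between the two channels into an
#' allele-2 fraction via the Ct law (one cycle of delay per template
#' halving): `f2 / f1 = 2^(rise1 - rise2)` on interpolated crossings. When
#' only one channel amplifies the estimate is exactly 0 or 1; when neither
#' channel yields a usable rise but the endpoint is adequate, the endpoint
#' ratio is used as a fallback. Loci below the no-amplification magnitude
#' return `NA`.
#'
#' @param summaries Output of [summarize_traces()].
#' @param thresholds A [pas_thresholds()].
#' @return `summaries` with an `allele2_fraction` column appended.
#' @export
estimate_allele_fraction <- function(summaries,
                                     thresholds = pas_thresholds()) {
  th <- thresholds
  s <- summaries
  frac <- dplyr::case_when(
    s$magnitude < th$noamp ~ NA_real_,
    !is.na(s$rise1_x) & !is.na(s$rise2_x) ~
      1 / (1 + 2^(s$rise2_x - s$rise1_x)),
    !is.na(s$rise1_x) & is.na(s$rise2_x) ~ 0,
    is.na(s$rise1_x) & !is.na(s$rise2_x) ~ 1,
    TRUE ~ s$f2_end / pmax(s$magnitude, .Machine$double.eps)
  )
  dplyr::mutate(s, allele2_fraction = frac)
}
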