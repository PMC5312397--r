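#' Simulation configuration
#'
#' Parameters of the synthetic two-channel amplification model and of the
#' Hardy-Weinberg genotype generator. Each channel of a biallelic assay
#' amplifies logistically and crosses a fixed instrument detection level at
#' cycle \eqn{Ct = ct0 - log2(q)}, where \eqn{q} is the channel's template
#' fraction normalized so a pure diploid homozygote has \eqn{q = 1}; channel
#' plateaus are proportional to allele fraction, so the endpoint angle of the
#' allelic-discrimination plot encodes the allele ratio. Template halving
#' therefore delays the rise by one cycle, which is the lever the package
#' uses to expose minor contributors in a mixture.
#'
#' @param n_loci Panel size (default 32).
#' @param allele_freqs Allele-1 frequency per locus, recycled to `n_loci`.
#'   Default 0.5 everywhere (maximum-entropy human-ID panel assumption).
#' @param panel Assay panel tibble; defaults to [snp_panel()] of `n_loci`.
#' @param cycles Amplification cycles recorded per trace (default 40).
#' @param ct0 Threshold-crossing cycle of a pure homozygote (default 22).
#' @param growth_rate Logistic growth rate per cycle (default 0.7).
#' @param plateau Endpoint fluorescence of a pure homozygote, arbitrary
#'   units (default 2000).
#' @param detect_level Instrument detection level the Ct law is anchored to
#'   (default 10 a.u.).
#' @param plateau_cv Coefficient of variation of the per-channel plateau
#'   (multiplicative log-normal noise, default 0.05).
#' @param ct_sd Cycle-timing jitter on each channel's threshold crossing
#'   (default 0.15 cycles).
#' @param baseline_sd Additive baseline fluorescence noise per cycle
#'   (default 1.5 a.u.).
#' @param female_prob Probability a simulated sample is female (default 0.5).
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_loci = 8)
#' cfg$panel
#' @export
sim_config <- function(n_loci = 32L,
                       allele_freqs = 0.5,
                       panel = snp_panel(n_loci),
                       cycles = 40L,
                       ct0 = 22,
                       growth_rate = 0.7,
                       plateau = 2000,
                       detect_level = 10,
                       plateau_cv = 0.05,
                       ct_sd = 0.15,
                       baseline_sd = 1.5,
                       female_prob = 0.5) {
  n_loci <- as.integer(n_loci)
  stopifnot(nrow(panel) == n_loci, cycles >= 2L,
            plateau > 0, detect_level > 0, detect_level < plateau,
            growth_rate > 0, plateau_cv >= 0, ct_sd >= 0, baseline_sd >= 0,
            female_prob >= 0, female_prob <= 1)
  allele_freqs <- rep_len(allele_freqs, n_loci)
  if (any(!is.finite(allele_freqs)) || any(allele_freqs <= 0) ||
      any(allele_freqs > 1)) {
    stop("allele_freqs must be finite and in (0, 1]", call. = FALSE)
  }
  structure(
    list(
      n_loci = n_loci, allele_freqs = allele_freqs, panel = panel,
      cycles = as.integer(cycles), ct0 = ct0, growth_rate = growth_rate,
      plateau = plateau, detect_level = detect_level,
      plateau_cv = plateau_cv, ct_sd = ct_sd, baseline_sd = baseline_sd,
      female_prob = female_prob
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d loci, %d cycles; ct0=%g, plateau=%g, growth=%g\n",
    x$n_loci, x$cycles, x$ct0, x$plateau, x$growth_rate))
  cat(sprintf("  noise: plateau_cv=%g, ct_sd=%g, baseline_sd=%g\n",
              x$plateau_cv, x$ct_sd, x$baseline_sd))
  invisible(x)
}

#' Calling and decision thresholds
#'
#' One configuration object for genotype calling, per-locus mixture evidence,
#' and sample-level verdicts.
#'
#' Calling defaults: a locus is `NOAMP` below `noamp` endpoint magnitude,
#' `UNDET` below `weak` (signal too faint to call confidently, the
#' "inefficient amplification" signature), otherwise called from the endpoint
#' angle: `HOM1` under `hom1_max` degrees, `HET` inside
#' `[het_min, het_max]`, `HOM2` above `hom2_min`, `UNDET` in the gaps.
#'
#' Verdict defaults follow the registry's observed separation between
#' patients (closest pair 12 discordant SNPs): a match tolerates no opposite
#' homozygotes (`max_strong`) and up to `max_weak` hom-vs-het discrepancies
#' (which copy-number imbalance can create); four or more undetermined loci
#' (`undet_trigger`) trigger signal-level review; contamination requires
#' corroboration at `k_flagged` or more adequately amplified loci.
#'
#' @param noamp Endpoint magnitude below which a locus is `NOAMP` (a.u.).
#' @param weak Endpoint magnitude below which a call is demoted to `UNDET`
#'   and the locus marked weakly amplified (a.u.).
#' @param rise Rise threshold for per-channel crossing cycles (a.u.).
#' @param hom1_max,het_min,het_max,hom2_min Angle band edges in degrees.
#' @param deviation_min Angular deviation (degrees) from the nearest
#'   canonical cluster (0/45/90) counted as mixture evidence.
#' @param k_flagged Minimum number of flagged loci for a `CONTAMINATED`
#'   disposition.
#' @param max_strong Maximum opposite-homozygote mismatches in a validated
#'   match.
#' @param max_weak Maximum hom-vs-het mismatches in a validated match.
#' @param undet_trigger Undetermined-locus count that makes a verdict
#'   `INCONCLUSIVE` pending signal review.
#' @param contributor_margin Minimum consistency margin over the runner-up
#'   before a second contributor is named.
#' @param alpha Target false-positive rate for per-locus mixture evidence on
#'   pure samples.
#' @return A list of class `pas_thresholds`.
#' @export
pas_thresholds <- function(noamp = 200, weak = 800, rise = 10,
                           hom1_max = 15, het_min = 35, het_max = 55,
                           hom2_min = 75, deviation_min = 10,
                           k_flagged = 3L, max_strong = 0L, max_weak = 2L,
                           undet_trigger = 4L, contributor_margin = 0.1,
                           alpha = 0.01) {
  stopifnot(noamp > 0, weak >= noamp, rise > 0,
            hom1_max < het_min, het_min < het_max, het_max < hom2_min,
            deviation_min > 0, k_flagged >= 1L)
  structure(
    list(noamp = noamp, weak = weak, rise = rise, hom1_max = hom1_max,
         het_min = het_min, het_max = het_max, hom2_min = hom2_min,
         deviation_min = deviation_min, k_flagged = as.integer(k_flagged),
         max_strong = as.integer(max_strong), max_weak = as.integer(max_weak),
         undet_trigger = as.integer(undet_trigger),
         contributor_margin = contributor_margin, alpha = alpha),
    class = "pas_thresholds"
  )
}

# Seed handling: all stochastic entry points take `seed`; NULL leaves the
# caller's RNG stream untouched, otherwise the draw is made in an isolated
# stream so the global RNG state is preserved.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}
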