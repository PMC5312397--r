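# Panel-level discriminatory power: random-match probability, biobank
# collision risk (birthday bound) and the mixture detection-limit power
# curve.

#' Random match probability of a genotype panel
#'
#' The probability that two unrelated individuals share an identical
#' barcode: independently per locus, the chance both draw the same genotype
#' is the sum of squared genotype frequencies, and loci multiply:
#' \deqn{p = \prod_i \sum_j g_{ij}^2.}
#' At a locus in Hardy-Weinberg equilibrium with both alleles at frequency
#' 0.5 the per-locus match probability is
#' \eqn{0.25^2 + 0.5^2 + 0.25^2 = 0.375}.
#'
#' @param genotype_freqs Numeric matrix (or data frame) with one row per
#'   locus and one column per genotype class (e.g. HOM1/HET/HOM2); each row
#'   must sum to 1.
#' @return The pairwise match probability.
#' @examples
#' random_match_probability(matrix(rep(c(0.25, 0.5, 0.25), 32),
#'                                 ncol = 3, byrow = TRUE))
#' @export
random_match_probability <- function(genotype_freqs) {
  g <- as.matrix(genotype_freqs)
  if (any(!is.finite(g)) || any(g < 0)) {
    stop("genotype frequencies must be finite and non-negative",
         call. = FALSE)
  }
  if (any(abs(rowSums(g) - 1) > 1e-8)) {
    stop("each locus's genotype frequencies must sum to 1", call. = FALSE)
  }
  prod(rowSums(g^2))
}

#' Genotype frequencies under Hardy-Weinberg equilibrium
#'
#' @param p Allele-1 frequency (vector, one per locus).
#' @return Matrix with columns `HOM1`, `HET`, `HOM2`.
#' @export
hwe_genotype_freqs <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  cbind(HOM1 = p^2, HET = 2 * p * (1 - p), HOM2 = (1 - p)^2)
}

#' Probability of any barcode collision in a biobank
#'
#' Birthday bound: with pairwise match probability `p` and `n` samples,
#' \eqn{P = 1 - (1 - p)^{\binom{n}{2}}}, evaluated stably through
#' `log1p`/`expm1` so that probabilities of order `1e-14` do not underflow.
#'
#' @param p Pairwise random match probability.
#' @param n_samples Biobank size.
#' @return Probability at least two samples share a barcode.
#' @examples
#' p <- random_match_probability(hwe_genotype_freqs(rep(0.5, 32)))
#' collision_probability(p, 10000)
#' @export
collision_probability <- function(p, n_samples) {
  stopifnot(p >= 0, p <= 1, n_samples >= 0)
  n_pairs <- choose(n_samples, 2)
  if (n_pairs == 0 || p == 0) return(0)
  -expm1(n_pairs * log1p(-p))
}

#' Mixture detection-limit power curve
#'
#' Simulates two-contributor mixtures of a fixed, seeded reference pair at
#' each requested fraction, runs [detect_contamination()] on every
#' replicate, and records the detection rate, together with the
#' false-positive rate on pure (fraction 0) samples. Reports the smallest
#' fraction whose power reaches `power_target`.
#'
#' @param fractions Contaminant fractions to probe (default the serial
#'   dilution 1/2 ... 1/32).
#' @param n_replicates Replicates per fraction and for the pure condition.
#' @param config A [sim_config()].
#' @param thresholds A [pas_thresholds()].
#' @param power_target Required detection rate (default 0.95).
#' @param seed Integer seed (drives the reference pair and every replicate).
#' @return A list of class `pas_power`: `power_curve` tibble (`fraction`,
#'   `n`, `n_detected`, `power`), `false_positive_rate`,
#'   `detection_limit` (smallest fraction with power >= target, `NA` if
#'   none), plus the generating settings.
#' @export
detection_limit <- function(fractions = c(1/2, 1/4, 1/8, 1/16, 1/32),
                            n_replicates = 200, config = sim_config(),
                            thresholds = pas_thresholds(),
                            power_target = 0.95, seed = 1) {
  stopifnot(all(fractions > 0 & fractions <= 1), n_replicates >= 1)
  th <- thresholds
  with_seed_opt(seed, {
    cohort <- simulate_profiles(2, config, sex = c("MALE", "MALE"),
                                prefix = "REF")
    registry <- assign_references(cohort$calls, panel = config$panel)
    ref_id <- "REF001"
    contam_id <- "REF002"
    run_one <- function(f) {
      tr <- if (f > 0) {
        simulate_mixture(
          cohort$genotypes,
          tibble::tibble(sample_id = c(ref_id, contam_id),
                         fraction = c(1 - f, f)),
          mix_id = "Q", config = config)
      } else {
        simulate_traces(
          dplyr::mutate(
            cohort$genotypes[cohort$genotypes$sample_id == ref_id, ],
            sample_id = "Q"),
          config)
      }
      detect_contamination(tr, ref_id, registry, th)$disposition ==
        "CONTAMINATED"
    }
    curve <- purrr::map_dfr(sort(fractions), function(f) {
      hits <- vapply(seq_len(n_replicates), function(i) run_one(f),
                     logical(1))
      tibble::tibble(fraction = f, n = n_replicates,
                     n_detected = sum(hits), power = mean(hits))
    })
    fp <- mean(vapply(seq_len(n_replicates), function(i) run_one(0),
                      logical(1)))
    ok <- curve$fraction[curve$power >= power_target]
    structure(
      list(power_curve = curve,
           false_positive_rate = fp,
           detection_limit = if (length(ok) > 0) min(ok) else NA_real_,
           power_target = power_target,
           n_replicates = n_replicates,
           reference_pair = c(ref_id, contam_id)),
      class = "pas_power"
    )
  })
}

#' @export
print.pas_power <- function(x, ...) {
  cat(sprintf(
    "<pas_power> detection limit: %s (power target %.2f); FPR %.3f\n",
    if (is.na(x$detection_limit)) "not reached" else
      sprintf("%.4g (%.3g%%)", x$detection_limit, 100 * x$detection_limit),
    x$power_target, x$false_positive_rate))
  print(x$power_curve)
  invisible(x)
}

#' @describeIn detection_limit Tidy power curve (one row per fraction).
#' @param x A `pas_power`.
#' @param ... Unused.
#' @method tidy pas_power
#' @export
tidy.pas_power <- function(x, ...) x$power_curve

#' @describeIn detection_limit One-row summary: detection limit, false
#'   positive rate, replicates.
#' @method glance pas_power
#' @export
glance.pas_power <- function(x, ...) {
  tibble::tibble(
    detection_limit = x$detection_limit,
    detection_limit_pct = 100 * x$detection_limit,
    false_positive_rate = x$false_positive_rate,
    power_target = x$power_target,
    n_replicates = x$n_replicates
  )
}

#' Plot a detection power curve
#'
#' @param object A `pas_power` from [detection_limit()].
#' @param ... Unused.
#' @return A ggplot object: power against contaminant fraction (log2 x
#'   axis), with the power target as a dashed line.
#' @export
autoplot.pas_power <- function(object, ...) {
  ggplot2::ggplot(object$power_curve,
                  ggplot2::aes(x = .data$fraction, y = .data$power)) +
    ggplot2::geom_hline(yintercept = object$power_target,
                        linetype = "dashed", color = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log2",
                                labels = function(f) sprintf("1/%d",
                                                             round(1 / f))) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Contaminant fraction", y = "Detection power") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
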