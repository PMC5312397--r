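# Synthetic-data generator: HWE genotype cohorts, two-channel amplification
# traces, multi-contributor mixtures, and amplification inefficiency.

#' Simulate a cohort of SNP barcode profiles
#'
#' Draws genotypes per locus under Hardy-Weinberg equilibrium at the
#' configured allele frequencies. Sex is drawn per sample; females carry no
#' template at Y-linked assays (their calls are `NOAMP`), males are
#' hemizygous (one Y allele, called as a homozygote).
#'
#' @param n_samples Number of samples to draw.
#' @param config A [sim_config()].
#' @param sex Optional character vector (`"FEMALE"`/`"MALE"`) recycled to
#'   `n_samples`; by default sex is drawn with `config$female_prob`.
#' @param prefix Sample-ID prefix (IDs are `<prefix>001`, ...).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A list of class `pas_cohort` with tibbles `samples`
#'   (`sample_id`, `sex`), `genotypes` (`sample_id`, `assay_id`, `a1`, `a2`
#'   allele copies per diploid genome) and `calls` (`sample_id`, `assay_id`,
#'   `call`, `quality`).
#' @examples
#' co <- simulate_profiles(4, sim_config(n_loci = 8), seed = 1)
#' co$calls
#' @export
simulate_profiles <- function(n_samples, config = sim_config(),
                              sex = NULL, prefix = "S", seed = NULL) {
  stopifnot(n_samples >= 1)
  n_samples <- as.integer(n_samples)
  panel <- config$panel
  ids <- sprintf("%s%03d", prefix, seq_len(n_samples))

  with_seed_opt(seed, {
    if (is.null(sex)) {
      sex <- ifelse(stats::runif(n_samples) < config$female_prob,
                    "FEMALE", "MALE")
    } else {
      sex <- rep_len(toupper(sex), n_samples)
      stopifnot(all(sex %in% c("FEMALE", "MALE")))
    }

    n_loci <- nrow(panel)
    p1 <- matrix(rep(config$allele_freqs, each = n_samples),
                 nrow = n_samples)  # allele-1 frequency
    # autosomal: allele-1 copies ~ Binomial(2, p1); Y: hemizygous or absent
    a1 <- matrix(stats::rbinom(n_samples * n_loci, 2L, as.vector(p1)),
                 nrow = n_samples)
    a2 <- 2 - a1
    ylin <- panel$y_linked
    if (any(ylin)) {
      for (j in which(ylin)) {
        male <- sex == "MALE"
        a1[, j] <- ifelse(male,
                          stats::rbinom(n_samples, 1L, config$allele_freqs[j]),
                          0L)
        a2[, j] <- ifelse(male, 1L - a1[, j], 0L)
      }
    }
    geno <- tibble::tibble(
      sample_id = rep(ids, times = n_loci),
      assay_id = rep(panel$assay_id, each = n_samples),
      a1 = as.numeric(as.vector(a1)),
      a2 = as.numeric(as.vector(a2))
    ) |> dplyr::arrange(.data$sample_id, .data$assay_id)

    structure(
      list(
        samples = tibble::tibble(sample_id = ids, sex = sex),
        genotypes = geno,
        calls = calls_from_genotypes(geno)
      ),
      class = "pas_cohort"
    )
  })
}

#' @export
print.pas_cohort <- function(x, ...) {
  cat(sprintf("<pas_cohort> %d samples x %d assays (%d female)\n",
              nrow(x$samples), length(unique(x$genotypes$assay_id)),
              sum(x$samples$sex == "FEMALE")))
  invisible(x)
}

#' Categorical calls implied by true allele copy numbers
#'
#' @param genotypes Tibble with `sample_id`, `assay_id`, `a1`, `a2` (allele
#'   copies; need not be diploid).
#' @return Calls tibble (`sample_id`, `assay_id`, `call`, `quality`).
#' @export
calls_from_genotypes <- function(genotypes) {
  dplyr::mutate(
    genotypes[, c("sample_id", "assay_id")],
    call = dplyr::case_when(
      genotypes$a1 > 0 & genotypes$a2 > 0 ~ "HET",
      genotypes$a1 > 0 ~ "HOM1",
      genotypes$a2 > 0 ~ "HOM2",
      TRUE ~ "NOAMP"
    ),
    quality = 1
  )
}

# Core curve generator. q1, q2: per-row template fractions (pure diploid
# homozygote = 1). Returns cycles x n matrices for the two channels.
trace_curves <- function(q1, q2, config) {
  n <- length(q1)
  cyc <- seq_len(config$cycles)
  one_channel <- function(q) {
    m <- matrix(0, nrow = config$cycles, ncol = n)
    amp <- which(q > 0)
    if (length(amp) > 0) {
      p <- config$plateau * q[amp] *
        exp(stats::rnorm(length(amp), 0, config$plateau_cv))
      ct <- config$ct0 - log2(q[amp]) +
        stats::rnorm(length(amp), 0, config$ct_sd)
      live <- p > config$detect_level
      # channels whose realized plateau never reaches the detection level
      # stay at baseline
      idx <- amp[live]
      if (length(idx) > 0) {
        pl <- p[live]
        mid <- ct[live] + log(pl / config$detect_level - 1) / config$growth_rate
        m[, idx] <- pl[col(m[, idx, drop = FALSE])] /
          (1 + exp(-config$growth_rate *
                     (cyc - mid[col(m[, idx, drop = FALSE])])))
      }
    }
    m <- m + matrix(stats::rnorm(config$cycles * n, 0, config$baseline_sd),
                    nrow = config$cycles)
    pmax(m, 0)
  }
  list(f1 = one_channel(q1), f2 = one_channel(q2))
}

#' Simulate amplification traces from true allele copy numbers
#'
#' Realizes the logistic two-channel model for each `sample_id` x `assay_id`
#' row of `truth`. Copy numbers are per diploid genome, so an ordinary
#' homozygote is `(2, 0)` and a balanced heterozygote `(1, 1)`; copy-number
#' variants and mixtures supply fractional or non-diploid values. An
#' optional `template` column scales total input template (default 1).
#'
#' @param truth Tibble with `sample_id`, `assay_id`, `a1`, `a2` and optional
#'   `template`.
#' @param config A [sim_config()].
#' @param seed Integer seed or `NULL`.
#' @return Long trace tibble: `sample_id`, `assay_id`, `cycle`, `f1`, `f2`.
#' @examples
#' cfg <- sim_config(n_loci = 4)
#' tr <- simulate_traces(
#'   tibble::tibble(sample_id = "S1", assay_id = cfg$panel$assay_id,
#'                  a1 = c(2, 1, 0, 0), a2 = c(0, 1, 2, 0)),
#'   cfg, seed = 1)
#' @export
simulate_traces <- function(truth, config = sim_config(), seed = NULL) {
  stopifnot(all(c("sample_id", "assay_id", "a1", "a2") %in% names(truth)))
  if (any(is.na(truth$a1) | is.na(truth$a2)) ||
      any(truth$a1 < 0 | truth$a2 < 0)) {
    stop("allele copy numbers must be non-negative and non-missing",
         call. = FALSE)
  }
  template <- if ("template" %in% names(truth)) truth$template else 1
  template <- rep_len(template, nrow(truth))
  with_seed_opt(seed, {
    cur <- trace_curves(truth$a1 / 2 * template, truth$a2 / 2 * template,
                        config)
    n <- nrow(truth)
    tibble::tibble(
      sample_id = rep(truth$sample_id, each = config$cycles),
      assay_id = rep(truth$assay_id, each = config$cycles),
      cycle = rep(seq_len(config$cycles), times = n),
      f1 = as.vector(cur$f1),
      f2 = as.vector(cur$f2)
    )
  })
}

#' Simulate a multi-contributor DNA mixture
#'
#' Mixes purified-DNA template: the per-locus allele template fractions of
#' the mixture are the fraction-weighted averages of the contributors'
#' allele copy numbers, exactly as mixing genomic DNA at fixed mass ratios
#' would produce. One to three contributors are supported (two-source
#' contamination and three-source post-transplant chimerism).
#'
#' @param genotypes Tibble of true allele copies (`sample_id`, `assay_id`,
#'   `a1`, `a2`), e.g. `cohort$genotypes`, covering every contributor.
#' @param contributors Tibble with `sample_id` and `fraction`; fractions
#'   must sum to 1.
#' @param mix_id Sample ID given to the mixture.
#' @param config A [sim_config()].
#' @param seed Integer seed or `NULL`.
#' @return Trace tibble as [simulate_traces()], with the mixed copy-number
#'   truth attached as attribute `"truth"`.
#' @export
simulate_mixture <- function(genotypes, contributors, mix_id = "MIX",
                             config = sim_config(), seed = NULL) {
  stopifnot(all(c("sample_id", "fraction") %in% names(contributors)))
  if (nrow(contributors) < 1 || nrow(contributors) > 3) {
    stop("1-3 contributors are supported", call. = FALSE)
  }
  if (abs(sum(contributors$fraction) - 1) > 1e-9) {
    stop("contributor fractions must sum to 1", call. = FALSE)
  }
  missing_ids <- setdiff(contributors$sample_id, unique(genotypes$sample_id))
  if (length(missing_ids) > 0) {
    stop(sprintf("no genotypes for contributor(s): %s",
                 paste(missing_ids, collapse = ", ")), call. = FALSE)
  }
  mixed <- genotypes |>
    dplyr::inner_join(contributors, by = "sample_id") |>
    dplyr::group_by(.data$assay_id) |>
    dplyr::summarise(a1 = sum(.data$a1 * .data$fraction),
                     a2 = sum(.data$a2 * .data$fraction),
                     .groups = "drop") |>
    dplyr::mutate(sample_id = mix_id, .before = 1)
  tr <- simulate_traces(mixed, config, seed = seed)
  attr(tr, "truth") <- mixed
  tr
}

#' Inject amplification inefficiency into traces
#'
#' Attenuates endpoint magnitude at selected loci without changing the
#' allele ratio, emulating poor amplification (degraded template, pipetting
#' shortfalls). Attenuated heterozygous loci keep their canonical diagonal
#' angle but drop below the confident-call magnitude, producing undetermined
#' or no-amplification calls with no contamination signature.
#'
#' @param traces Trace tibble.
#' @param dropout_rate Per-locus probability of attenuation (ignored when
#'   `loci` is given).
#' @param attenuation Multiplicative magnitude factor applied to affected
#'   loci (default 0.2).
#' @param loci Optional tibble (`sample_id`, `assay_id`) naming the loci to
#'   attenuate deterministically.
#' @param seed Integer seed or `NULL`.
#' @return Trace tibble with attribute `"attenuated"` listing affected loci.
#' @export
simulate_inefficiency <- function(traces, dropout_rate = 0,
                                  attenuation = 0.2, loci = NULL,
                                  seed = NULL) {
  stopifnot(dropout_rate >= 0, dropout_rate <= 1,
            attenuation >= 0, attenuation <= 1)
  keys <- dplyr::distinct(traces[, c("sample_id", "assay_id")])
  hit <- with_seed_opt(seed, {
    if (is.null(loci)) {
      keys[stats::runif(nrow(keys)) < dropout_rate, ]
    } else {
      dplyr::semi_join(keys, loci, by = c("sample_id", "assay_id"))
    }
  })
  if (nrow(hit) == 0) {
    attr(traces, "attenuated") <- hit
    return(traces)
  }
  hit$._att <- TRUE
  out <- traces |>
    dplyr::left_join(hit, by = c("sample_id", "assay_id")) |>
    dplyr::mutate(
      f1 = ifelse(is.na(.data$._att), .data$f1, .data$f1 * attenuation),
      f2 = ifelse(is.na(.data$._att), .data$f2, .data$f2 * attenuation)
    ) |>
    dplyr::select(-"._att")
  attr(out, "attenuated") <- hit[, c("sample_id", "assay_id")]
  out
}
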