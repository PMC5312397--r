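test_that("a mixed sample is CONTAMINATED with the correct second contributor", {
  cfg <- sim_config()
  co <- simulate_profiles(5, cfg, sex = "MALE", prefix = "ETP", seed = 81)
  reg <- assign_references(co$calls, panel = cfg$panel)
  tr <- simulate_mixture(
    co$genotypes,
    tibble::tibble(sample_id = c("ETP004", "ETP005"),
                   fraction = c(0.7, 0.3)),
    mix_id = "ETP-4-P2", config = cfg, seed = 82)
  rep <- detect_contamination(tr, "ETP004", reg)
  expect_equal(rep$disposition, "CONTAMINATED")
  expect_gte(rep$n_flagged, pas_thresholds()$k_flagged)
  expect_equal(rep$implied_second_contributor, "ETP005")
  expect_lte(abs(rep$estimated_fraction - 0.3), 0.07)
})

test_that("attenuated loci triage as INEFFICIENT_AMPLIFICATION, not contamination", {
  cfg <- sim_config()
  co <- simulate_profiles(3, cfg, sex = "MALE", seed = 83)
  reg <- assign_references(co$calls, panel = cfg$panel)
  g <- dplyr::mutate(one_profile(co$genotypes, "S001"), sample_id = "Q")
  tr <- simulate_traces(g, cfg, seed = 84)
  att <- simulate_inefficiency(
    tr, loci = tibble::tibble(sample_id = "Q",
                              assay_id = cfg$panel$assay_id[c(2, 5, 9)]),
    attenuation = 0.2)
  rep <- detect_contamination(att, "S001", reg)
  expect_equal(rep$disposition, "INEFFICIENT_AMPLIFICATION")
  expect_equal(rep$n_flagged, 0L)
  expect_gte(rep$n_weak_undet, 3L)
})

test_that("pure samples are CLEAN in at least 99% of seeded replicates", {
  cfg <- sim_config()
  fx <- mixture_fixture(cfg, seed = 85)
  g0 <- one_profile(fx$cohort$genotypes, "REF001")
  clean <- withr::with_seed(86, vapply(1:300, function(i) {
    tr <- simulate_traces(dplyr::mutate(g0, sample_id = "Q"), cfg)
    detect_contamination(tr, "REF001", fx$registry)$disposition == "CLEAN"
  }, logical(1)))
  expect_gte(mean(clean), 0.99)
})

test_that("insufficient trace coverage is rejected", {
  cfg <- sim_config()
  fx <- mixture_fixture(cfg, seed = 87)
  g0 <- one_profile(fx$cohort$genotypes, "REF001")
  tr <- simulate_traces(dplyr::mutate(g0, sample_id = "Q"), cfg, seed = 88)
  partial <- tr[tr$assay_id %in% cfg$panel$assay_id[1:10], ]
  expect_error(detect_contamination(partial, "REF001", fx$registry), "75%")
})

test_that("karyotype-annotated CNV loci are exempt from deviation evidence", {
  cfg <- sim_config()
  co <- simulate_profiles(2, cfg, sex = "MALE", prefix = "ALL", seed = 91)
  # give ALL001 a chr6 amplification: HET loci in the region go (1, 2)
  kt <- tibble::tibble(reference_id = "ALL001", chromosome = "6",
                       start = 30466936L, end = 170792391L,
                       total_copies = 3L, allele2_copies = 2L)
  region_loci <- cfg$panel$assay_id[cfg$panel$chromosome == "6" &
                                      cfg$panel$position >= kt$start &
                                      cfg$panel$position <= kt$end]
  g <- one_profile(co$genotypes, "ALL001")
  g$a2[g$assay_id %in% region_loci & g$a1 == 1] <- 2
  g$a1[g$assay_id %in% region_loci & g$a1 == 2 & g$a2 == 0] <- 3
  reg_plain <- assign_references(co$calls, panel = cfg$panel)
  reg_kt <- assign_references(co$calls, panel = cfg$panel, karyotype = kt)
  tr <- simulate_traces(dplyr::mutate(g, sample_id = "Q"), cfg, seed = 92)
  with_kt <- detect_contamination(tr, "ALL001", reg_kt)
  without_kt <- detect_contamination(tr, "ALL001", reg_plain)
  ev_kt <- with_kt$evidence[[1]]
  expect_true(all(ev_kt$cnv_exempt[ev_kt$assay_id %in% region_loci]))
  expect_lte(with_kt$n_flagged, without_kt$n_flagged)
  expect_false(any(ev_kt$flagged[ev_kt$assay_id %in% region_loci] &
                     !ev_kt$late_minor_amplification[
                       ev_kt$assay_id %in% region_loci]))
})

test_that("mixture-fraction estimation tracks the serial dilution", {
  cfg <- sim_config()
  fx <- mixture_fixture(cfg, seed = 95)
  co <- fx$cohort
  a_calls <- one_profile(co$calls, "REF001")
  b_calls <- one_profile(co$calls, "REF002")
  mix_traces <- function(f, seed) {
    simulate_mixture(
      co$genotypes,
      tibble::tibble(sample_id = c("REF001", "REF002"),
                     fraction = c(1 - f, f)),
      mix_id = "Q", config = cfg, seed = seed)
  }
  est11 <- estimate_mixture_fraction(mix_traces(0.5, 96), a_calls, b_calls,
                                     cfg$panel)
  expect_lte(abs(est11$estimate - 0.5), 0.07)
  pure <- simulate_traces(
    dplyr::mutate(one_profile(co$genotypes, "REF001"), sample_id = "Q"),
    cfg, seed = 97)
  est0 <- estimate_mixture_fraction(pure, a_calls, b_calls, cfg$panel)
  expect_lte(est0$estimate, 0.02)
  # f = 1/16 over 100 replicates: median within +/-0.03
  ests <- withr::with_seed(98, vapply(1:100, function(i) {
    estimate_mixture_fraction(mix_traces(1 / 16, NULL), a_calls, b_calls,
                              cfg$panel)$estimate
  }, numeric(1)))
  expect_lte(abs(stats::median(ests) - 1 / 16), 0.03)
})

test_that("no informative locus yields NA with an explanatory note", {
  panel <- snp_panel(2, 0)
  cfg <- sim_config(2, panel = panel)
  het <- tibble::tibble(sample_id = "A", assay_id = panel$assay_id,
                        call = "HET")
  tr <- simulate_traces(tibble::tibble(sample_id = "Q",
                                       assay_id = panel$assay_id,
                                       a1 = 1, a2 = 1), cfg, seed = 99)
  est <- estimate_mixture_fraction(tr, het,
                                   dplyr::mutate(het, sample_id = "B"),
                                   panel)
  expect_true(is.na(est$estimate))
  expect_match(est$note, "opposite homozygotes")
})

test_that("serial passages flag a contaminant takeover but not noise", {
  cfg <- sim_config()
  fx <- mixture_fixture(cfg, seed = 103)
  co <- fx$cohort
  expected <- one_profile(co$calls, "REF001")[, c("assay_id", "call")]
  mk <- function(id, f, seed) {
    if (f == 0) {
      simulate_traces(dplyr::mutate(one_profile(co$genotypes, "REF001"),
                                    sample_id = id), cfg, seed = seed)
    } else {
      simulate_mixture(co$genotypes,
                       tibble::tibble(sample_id = c("REF001", "REF002"),
                                      fraction = c(1 - f, f)),
                       mix_id = id, config = cfg, seed = seed)
    }
  }
  takeover <- dplyr::bind_rows(mk("P2", 0.3, 104), mk("P3", 0.8, 105))
  dr <- serial_drift_report(takeover, c("P2", "P3"), expected)
  expect_true(dr$drift_detected)
  same <- dplyr::bind_rows(mk("P2", 0, 106), mk("P3", 0, 107))
  dr0 <- serial_drift_report(same, c("P2", "P3"), expected)
  expect_false(dr0$drift_detected)
  flags <- withr::with_seed(108, vapply(1:50, function(i) {
    trs <- dplyr::bind_rows(mk("P2", 0, NULL), mk("P3", 0, NULL))
    serial_drift_report(trs, c("P2", "P3"), expected)$drift_detected
  }, logical(1)))
  expect_gte(mean(!flags), 0.99)
})
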