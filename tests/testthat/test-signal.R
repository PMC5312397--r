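make_trace <- function(f1_end, f2_end, cycles = 10, assay = "A1") {
  tibble::tibble(sample_id = "S", assay_id = assay,
                 cycle = seq_len(cycles),
                 f1 = seq(0, f1_end, length.out = cycles),
                 f2 = seq(0, f2_end, length.out = cycles))
}

test_that("endpoint angles hit the axes and the diagonal", {
  s <- summarize_traces(make_trace(1000, 0))
  expect_equal(s$angle_deg, 0)
  expect_equal(s$magnitude, 1000)
  s <- summarize_traces(make_trace(0, 1000))
  expect_equal(s$angle_deg, 90)
  s <- summarize_traces(make_trace(800, 800))
  expect_equal(s$angle_deg, 45)
})

test_that("an all-zero trace summarizes to zero magnitude with no rise", {
  tr <- make_trace(0, 0)
  s <- summarize_traces(tr)
  expect_equal(s$magnitude, 0)
  expect_true(is.na(s$rise1) && is.na(s$rise2))
  expect_equal(call_genotypes(s)$call, "NOAMP")
})

test_that("rise cycles are the first threshold crossing", {
  tr <- tibble::tibble(sample_id = "S", assay_id = "A1", cycle = 1:5,
                       f1 = c(0, 5, 20, 80, 100), f2 = c(0, 0, 0, 0, 0))
  s <- summarize_traces(tr, rise_threshold = 10)
  expect_equal(s$rise1, 3)
  expect_true(is.na(s$rise2))
  # interpolated crossing sits between cycles 2 and 3
  expect_equal(s$rise1_x, 2 + (10 - 5) / (20 - 5))
})

test_that("endpoint angle is monotone in the allele-2 fraction", {
  cfg <- noiseless_config(n_loci = 1, panel = snp_panel(1, 0))
  fr <- seq(0, 1, by = 0.1)
  truth <- tibble::tibble(sample_id = sprintf("S%02d", seq_along(fr)),
                          assay_id = cfg$panel$assay_id,
                          a1 = 2 * (1 - fr), a2 = 2 * fr)
  s <- summarize_traces(simulate_traces(truth, cfg)) |>
    dplyr::arrange(sample_id)
  expect_true(all(diff(s$angle_deg) >= -1e-9))
  expect_equal(s$angle_deg[1], 0, tolerance = 1e-6)
  expect_equal(s$angle_deg[6], 45, tolerance = 1e-6)
  expect_equal(s$angle_deg[11], 90, tolerance = 1e-6)
})

test_that("pure genotypes are called correctly in >=99% of 10,000 draws", {
  cfg <- sim_config(n_loci = 3, panel = snp_panel(3, 0))
  n <- 10000
  per <- ceiling(n / 3)
  truth <- tibble::tibble(
    sample_id = rep(sprintf("S%05d", seq_len(per)), each = 3),
    assay_id = rep(cfg$panel$assay_id, per),
    a1 = rep(c(2, 1, 0), per),
    a2 = rep(c(0, 1, 2), per))
  calls <- simulate_traces(truth, cfg, seed = 77) |>
    summarize_traces() |>
    call_genotypes() |>
    dplyr::inner_join(
      dplyr::mutate(truth,
                    expected = c("HOM1", "HET", "HOM2")[match(
                      paste(a1, a2), c("2 0", "1 1", "0 2"))]),
      by = c("sample_id", "assay_id"))
  expect_gte(mean(calls$call == calls$expected), 0.99)
})

test_that("a 1:2 allele imbalance lands between the HET and HOM2 bands", {
  cfg <- sim_config(n_loci = 1, panel = snp_panel(1, 0))
  truth <- tibble::tibble(sample_id = sprintf("S%03d", 1:50),
                          assay_id = cfg$panel$assay_id, a1 = 1, a2 = 2)
  s <- simulate_traces(truth, cfg, seed = 5) |>
    summarize_traces() |>
    call_genotypes()
  # atan2(2, 1) = 63.4 degrees: above the HET band, below the HOM2 band
  expect_true(all(s$angle_deg > 45 & s$angle_deg < 90))
  expect_gte(mean(s$call == "UNDET"), 0.95)
  expect_true(all(s$magnitude > pas_thresholds()$weak))
})

test_that("minor-channel rise lags by about log2(1/f) cycles at informative loci", {
  cfg <- sim_config(n_loci = 1, panel = snp_panel(1, 0))
  aid <- cfg$panel$assay_id
  for (f in c(1/2, 1/4, 1/8, 1/16, 1/32)) {
    truth <- tibble::tibble(sample_id = sprintf("S%03d", 1:40),
                            assay_id = aid,
                            a1 = 2 * (1 - f), a2 = 2 * f)
    s <- summarize_traces(simulate_traces(truth, cfg, seed = round(100 * f)))
    lag <- stats::median(s$rise2 - s$rise1, na.rm = TRUE)
    expect_lte(abs(lag - log2(1 / f)), 1)
  }
})

test_that("late minor amplification flags diluted contaminants, not noise", {
  cfg <- sim_config(n_loci = 1, panel = snp_panel(1, 0))
  aid <- cfg$panel$assay_id
  expected <- tibble::tibble(assay_id = aid, call = "HOM1")
  th <- pas_thresholds()
  # 1/32 contaminant at a ref-HOM1 / contaminant-HOM2 locus
  mix <- tibble::tibble(sample_id = sprintf("S%03d", 1:100),
                        assay_id = aid, a1 = 2 * 31 / 32, a2 = 2 / 32)
  ev <- locus_evidence(simulate_traces(mix, cfg, seed = 41), expected, th)
  expect_gte(mean(ev$late_minor_amplification), 0.99)
  expect_equal(stats::median(ev$minor_rise - ev$major_rise), log2(31),
               tolerance = 0.1)
  # pure samples: false-positive rate below alpha
  pure <- tibble::tibble(sample_id = sprintf("P%04d", 1:1000),
                         assay_id = aid, a1 = 2, a2 = 0)
  ev0 <- locus_evidence(simulate_traces(pure, cfg, seed = 42), expected, th)
  expect_lte(mean(ev0$late_minor_amplification), th$alpha)
  # matched heterozygote expectation deviates negligibly
  het <- tibble::tibble(sample_id = sprintf("H%03d", 1:50),
                        assay_id = aid, a1 = 1, a2 = 1)
  evh <- locus_evidence(simulate_traces(het, cfg, seed = 43),
                        tibble::tibble(assay_id = aid, call = "HET"), th)
  expect_lt(stats::median(evh$deviation_deg), 3)
})

test_that("allele-fraction estimates recover balanced, imbalanced and mixed truths", {
  cfg <- sim_config(n_loci = 1, panel = snp_panel(1, 0))
  aid <- cfg$panel$assay_id
  est <- function(truth, seed) {
    simulate_traces(truth, cfg, seed = seed) |>
      summarize_traces() |>
      estimate_allele_fraction()
  }
  het <- est(tibble::tibble(sample_id = sprintf("S%03d", 1:100),
                            assay_id = aid, a1 = 1, a2 = 1), 51)
  expect_lte(abs(stats::median(het$allele2_fraction) - 0.5), 0.05)
  cnv <- est(tibble::tibble(sample_id = sprintf("S%03d", 1:100),
                            assay_id = aid, a1 = 1, a2 = 2), 52)
  expect_lte(abs(stats::median(cnv$allele2_fraction) - 2 / 3), 0.1)
  mix13 <- est(tibble::tibble(sample_id = sprintf("S%03d", 1:100),
                              assay_id = aid, a1 = 2 * 0.75, a2 = 2 * 0.25),
               53)
  expect_lte(abs(stats::median(mix13$allele2_fraction) - 0.25), 0.05)
  hom <- est(tibble::tibble(sample_id = "S", assay_id = aid, a1 = 2, a2 = 0),
             54)
  expect_identical(hom$allele2_fraction, 0)
})
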