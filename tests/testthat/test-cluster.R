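test_that("genotype distance hits its closed-form anchors", {
  panel <- snp_panel(32, 0)
  prof <- function(id, call) tibble::tibble(sample_id = id,
                                            assay_id = panel$assay_id,
                                            call = call)
  expect_equal(genotype_distance(prof("A", "HOM1"), prof("B", "HOM1"),
                                 panel), 0)
  expect_equal(genotype_distance(prof("A", "HOM1"), prof("B", "HOM2"),
                                 panel), 1)
  expect_equal(genotype_distance(prof("A", "HOM1"), prof("B", "HET"),
                                 panel), 0.5)
  expect_equal(genotype_distance(prof("A", "NOAMP"), prof("B", "HOM1"),
                                 panel), 1)
})

test_that("the distance matrix equals the per-pair recount", {
  cfg <- sim_config()
  co <- simulate_profiles(6, cfg, seed = 111)
  d <- profile_dist(co$calls, cfg$panel)
  m <- as.matrix(d)
  ids <- labels(d)
  for (k in 1:6) {
    pick <- withr::with_seed(120 + k, sample(ids, 2))
    expect_equal(m[pick[1], pick[2]],
                 genotype_distance(one_profile(co$calls, pick[1]),
                                   one_profile(co$calls, pick[2]),
                                   cfg$panel))
  }
})

test_that("identical profiles merge first at height zero", {
  cfg <- tiny_config()
  co <- simulate_profiles(2, cfg, seed = 131)
  twin <- dplyr::mutate(one_profile(co$calls, "S001"), sample_id = "S001b")
  calls <- dplyr::bind_rows(co$calls, twin)
  hc <- cluster_profiles(calls, panel = cfg$panel)
  expect_equal(min(hc$height), 0)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("S001", "S001b"))
})

test_that("clustering agrees with a naive agglomeration oracle (n <= 6)", {
  for (linkage in c("average", "complete")) {
    for (s in 1:3) {
      n <- 5
      dmat <- withr::with_seed(140 + s, {
        m <- matrix(stats::runif(n * n), n)
        m <- (m + t(m)) / 2
        diag(m) <- 0
        m
      })
      hc <- stats::hclust(stats::as.dist(dmat), method = linkage)
      expect_equal(sort(hc$height), oracle_agglomerate(dmat, linkage),
                   tolerance = 1e-12)
    }
  }
  # and through the package path on real barcodes
  cfg <- sim_config()
  co <- simulate_profiles(6, cfg, seed = 151)
  d <- profile_dist(co$calls, cfg$panel)
  hc <- cluster_profiles(d, linkage = "average")
  expect_equal(sort(hc$height), oracle_agglomerate(as.matrix(d), "average"),
               tolerance = 1e-12)
})

test_that("clustering is invariant to the input ordering of samples", {
  cfg <- sim_config()
  co <- simulate_profiles(10, cfg, seed = 161)
  perm <- withr::with_seed(162, sample(unique(co$calls$sample_id)))
  shuffled <- co$calls |>
    dplyr::mutate(sample_id = factor(sample_id, levels = perm)) |>
    dplyr::arrange(sample_id) |>
    dplyr::mutate(sample_id = as.character(sample_id))
  hc1 <- cluster_profiles(co$calls, panel = cfg$panel)
  hc2 <- cluster_profiles(shuffled, panel = cfg$panel)
  expect_equal(sort(hc1$height), sort(hc2$height), tolerance = 1e-12)
  for (k in 2:4) {
    p1 <- stats::cutree(hc1, k)
    p2 <- stats::cutree(hc2, k)[names(p1)]
    # same partition up to label renumbering
    expect_equal(length(unique(paste(p1, p2))), k)
  }
})

test_that("mixed samples cluster away from the validated group", {
  cfg <- sim_config()
  co <- simulate_profiles(2, cfg, sex = "MALE", prefix = "REF", seed = 171)
  mk_calls <- function(id, f, seed) {
    tr <- if (f == 0) {
      simulate_traces(dplyr::mutate(one_profile(co$genotypes, "REF001"),
                                    sample_id = id), cfg, seed = seed)
    } else {
      simulate_mixture(co$genotypes,
                       tibble::tibble(sample_id = c("REF001", "REF002"),
                                      fraction = c(1 - f, f)),
                       mix_id = id, config = cfg, seed = seed)
    }
    tr |> summarize_traces() |> call_genotypes() |>
      dplyr::select(sample_id, assay_id, call)
  }
  calls <- dplyr::bind_rows(
    purrr::map2_dfr(sprintf("V%02d", 1:8), 201:208,
                    function(id, s) mk_calls(id, 0, s)),
    purrr::map2_dfr(sprintf("M%02d", 1:3), 211:213,
                    function(id, s) mk_calls(id, 0.4, s)))
  hc <- cluster_profiles(calls, panel = cfg$panel)
  grp <- stats::cutree(hc, 2)
  expect_equal(length(unique(grp[startsWith(names(grp), "V")])), 1L)
  expect_true(all(grp[startsWith(names(grp), "M")] !=
                    grp[["V01"]]))
})

test_that("heatmap export round-trips the call matrix and rejects empties", {
  cfg <- tiny_config()
  co <- simulate_profiles(5, cfg, seed = 181)
  img <- withr::local_tempfile(fileext = ".png")
  paths <- heatmap_export(co$calls, img, cfg$panel)
  expect_true(file.exists(paths$image))
  back <- read_heatmap_tsv(paths$tsv)
  ord <- function(x) dplyr::arrange(x[, c("sample_id", "assay_id", "call")],
                                    sample_id, assay_id)
  expect_equal(ord(back), ord(co$calls))
  empty <- co$calls[0, ]
  expect_error(heatmap_export(empty, img, cfg$panel), "no profiles")
  p <- plot_barcode(co$calls, cfg$panel)
  expect_s3_class(p, "ggplot")
})
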