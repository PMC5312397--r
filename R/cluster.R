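# Categorical barcode distance, hierarchical clustering and the heatmap
# rendering of call matrices.

#' Genotype distance between two profiles
#'
#' `d = (strong + 0.5 * weak) / n_informative`: opposite homozygotes count
#' fully, hom-vs-het discrepancies half. Identical profiles have distance 0;
#' pairs with no informative locus are maximally distant (1).
#'
#' @param calls_a,calls_b Single-sample calls tibbles.
#' @param panel Assay panel tibble.
#' @return A scalar in `[0, 1]`.
#' @export
genotype_distance <- function(calls_a, calls_b, panel = snp_panel()) {
  cmp <- compare_profiles(calls_a, calls_b, panel)
  if (cmp$n_informative == 0) return(1)
  (cmp$n_strong_mismatch + 0.5 * cmp$n_weak_mismatch) / cmp$n_informative
}

#' Pairwise genotype distance matrix
#'
#' @param calls Calls tibble with two or more samples.
#' @param panel Assay panel tibble.
#' @return A [stats::dist] object labeled with sample IDs, in the order the
#'   samples first appear in `calls`.
#' @export
profile_dist <- function(calls, panel = snp_panel()) {
  check_calls(calls, panel, "calls")
  m <- calls_matrix(calls, panel)
  ids0 <- unique(calls$sample_id)
  m <- m[ids0, , drop = FALSE]
  n <- nrow(m)
  hom <- function(v) v %in% c("HOM1", "HOM2")
  det <- function(v) v %in% .determined
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  yl <- panel$y_linked
  for (i in seq_len(n - 1)) {
    vi <- m[i, ]
    for (j in (i + 1):n) {
      vj <- m[j, ]
      excl <- yl & vi == "NOAMP" & vj == "NOAMP"
      inf <- det(vi) & det(vj) & !excl
      if (!any(inf)) {
        d[i, j] <- d[j, i] <- 1
        next
      }
      strong <- inf & hom(vi) & hom(vj) & vi != vj
      weak <- inf & xor(hom(vi), hom(vj))
      d[i, j] <- d[j, i] <- (sum(strong) + 0.5 * sum(weak)) / sum(inf)
    }
  }
  stats::as.dist(d)
}

#' Hierarchically cluster barcode profiles
#'
#' Agglomerative clustering on the categorical genotype distance with
#' average (UPGMA) or complete linkage. Identical profiles — same-patient
#' pairs — merge at height zero. The merge heights and the resulting
#' partition are invariant to the input ordering of samples (tie-breaking
#' follows the lowest pair index).
#'
#' @param x A `dist` from [profile_dist()], or a calls tibble.
#' @param linkage `"average"` or `"complete"`.
#' @param panel Assay panel (used when `x` is a calls tibble).
#' @return A [stats::hclust] object; leaf order via `$order`/`$labels`.
#' @export
cluster_profiles <- function(x, linkage = c("average", "complete"),
                             panel = snp_panel()) {
  linkage <- match.arg(linkage)
  d <- if (inherits(x, "dist")) x else profile_dist(x, panel)
  n <- attr(d, "Size")
  if (n < 2) stop("need at least two profiles to cluster", call. = FALSE)
  stats::hclust(d, method = linkage)
}

call_colors <- c(HOM1 = "#d73027", HOM2 = "#4575b4", HET = "#1a9850",
                 NOAMP = "#ffffff", UNDET = "#ffffff")

#' Barcode heatmap
#'
#' The classic call-matrix rendering: samples as columns, assays as rows,
#' homozygous allele 1 red, homozygous allele 2 blue, heterozygous green,
#' no-amplification/undetermined white.
#'
#' @param calls Calls tibble.
#' @param panel Assay panel tibble.
#' @param sample_order Optional character vector ordering the samples (e.g.
#'   `labels(d)[hc$order]` from [cluster_profiles()]).
#' @return A ggplot object.
#' @export
plot_barcode <- function(calls, panel = snp_panel(), sample_order = NULL) {
  if (nrow(calls) == 0) stop("no profiles to plot", call. = FALSE)
  if (is.null(sample_order)) sample_order <- unique(calls$sample_id)
  df <- dplyr::mutate(
    calls,
    sample_id = factor(.data$sample_id, levels = sample_order),
    assay_id = factor(.data$assay_id, levels = rev(panel$assay_id)),
    call = factor(.data$call, levels = call_levels())
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$assay_id,
                                   fill = .data$call)) +
    ggplot2::geom_tile(color = "grey70", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = call_colors, drop = FALSE,
                               name = "Call") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Export a clustered barcode heatmap
#'
#' Writes a raster rendering of the ordered call matrix and a TSV of the
#' same matrix (assays as rows, samples as columns, in leaf order) that
#' round-trips the calls exactly.
#'
#' @param calls Calls tibble (at least one profile).
#' @param path Output image path (extension decides the device, e.g.
#'   `.png` or `.pdf`).
#' @param panel Assay panel tibble.
#' @param sample_order Optional explicit sample order; by default samples
#'   are clustered with [cluster_profiles()] (average linkage) when there
#'   are three or more.
#' @param tsv_path Path of the matrix TSV (default: `path` with `.tsv`
#'   extension).
#' @return Invisibly, a list with `image` and `tsv` paths.
#' @export
heatmap_export <- function(calls, path, panel = snp_panel(),
                           sample_order = NULL, tsv_path = NULL) {
  if (nrow(calls) == 0) stop("no profiles to export", call. = FALSE)
  ids <- unique(calls$sample_id)
  if (is.null(sample_order)) {
    sample_order <- if (length(ids) >= 3) {
      d <- profile_dist(calls, panel)
      hc <- cluster_profiles(d)
      labels(d)[hc$order]
    } else ids
  }
  if (is.null(tsv_path)) tsv_path <- sub("\\.[A-Za-z]+$", ".tsv", path)
  m <- t(calls_matrix(calls, panel))[, sample_order, drop = FALSE]
  out <- tibble::as_tibble(m) |>
    dplyr::mutate(assay_id = rownames(m), .before = 1)
  readr::write_tsv(out, tsv_path)
  p <- plot_barcode(calls, panel, sample_order)
  ggplot2::ggsave(path, p,
                  width = max(4, 0.18 * length(ids) + 2),
                  height = max(3, 0.15 * nrow(panel) + 1), limitsize = FALSE)
  invisible(list(image = path, tsv = tsv_path))
}

#' Read back a heatmap matrix TSV as long calls
#'
#' @param tsv_path Path written by [heatmap_export()].
#' @return Calls tibble (`sample_id`, `assay_id`, `call`).
#' @export
read_heatmap_tsv <- function(tsv_path) {
  m <- readr::read_tsv(tsv_path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  tidyr::pivot_longer(m, -"assay_id", names_to = "sample_id",
                      values_to = "call") |>
    dplyr::select("sample_id", "assay_id", "call")
}
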