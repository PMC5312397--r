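#' Genotype call vocabulary
#'
#' The five call categories produced by a biallelic allelic-discrimination
#' assay: homozygous allele 1 (`HOM1`), homozygous allele 2 (`HOM2`),
#' heterozygous (`HET`), no amplification (`NOAMP`), and undetermined
#' (`UNDET`, low or angle-ambiguous signal).
#'
#' @return Character vector of the five call levels, in canonical order.
#' @export
call_levels <- function() c("HOM1", "HOM2", "HET", "NOAMP", "UNDET")

# calls carrying genotype information (both alleles resolved)
.determined <- c("HOM1", "HOM2", "HET")

#' Construct a SNP assay panel
#'
#' Builds the assay table the rest of the package works against: one row per
#' biallelic SNP assay with its chromosome, 1-based position and whether the
#' assay is Y-linked. The default 32-assay panel mirrors a commercial human-ID
#' OpenArray barcode: the three Y-chromosome probes and the five probes with
#' published rs IDs and positions are real; the remaining assay IDs are
#' synthetic placeholders (prefix `SYN_`) spread across the autosomes, since
#' the full commercial probe list is proprietary.
#'
#' @param n_loci Total number of assays in the panel (default 32).
#' @param n_y Number of Y-linked assays (default 3; must be `<= n_loci`).
#' @return A tibble with columns `assay_id`, `rs_id`, `chromosome`,
#'   `position`, `y_linked`.
#' @examples
#' snp_panel()
#' snp_panel(n_loci = 6, n_y = 1)
#' @export
snp_panel <- function(n_loci = 32L, n_y = 3L) {
  n_loci <- as.integer(n_loci)
  n_y <- as.integer(n_y)
  stopifnot(n_loci >= 1L, n_y >= 0L, n_y <= n_loci)

  y_probes <- tibble::tibble(
    assay_id  = c("C___1027548_10", "C___8938211_10", "C___1083232_10"),
    rs_id     = "",
    chromosome = "Y",
    position  = c(2787012L, 6845821L, 14869076L),
    y_linked  = TRUE
  )
  named_auto <- tibble::tibble(
    assay_id = c("C___1801627_10", "C___7421900_10", "C__27402849_10",
                 "C__29619553_10", "C___1902433_10"),
    rs_id = c("rs10869955", "rs1415762", "rs6927758", "rs9396715",
              "rs10771010"),
    chromosome = c("9", "6", "6", "6", "12"),
    position = c(77523211L, 125081641L, 163689526L, 10022280L, 23660716L),
    y_linked = FALSE
  )

  n_named_auto <- min(nrow(named_auto), n_loci - n_y)
  n_syn <- n_loci - n_y - n_named_auto
  syn <- tibble::tibble(
    assay_id = sprintf("SYN_A%02d", seq_len(max(n_syn, 0L))),
    rs_id = "",
    chromosome = as.character(rep(c(1:5, 7, 8, 10, 11, 13:22),
                                  length.out = max(n_syn, 0L))),
    position = 10000000L + 1000000L * seq_len(max(n_syn, 0L)),
    y_linked = FALSE
  )

  panel <- dplyr::bind_rows(
    named_auto[seq_len(n_named_auto), ],
    syn,
    y_probes[seq_len(n_y), ]
  )
  stopifnot(!anyDuplicated(panel$assay_id))
  panel
}

#' Y-linked assay IDs of a panel
#'
#' @param panel A panel tibble from [snp_panel()].
#' @return Character vector of Y-linked `assay_id`s.
#' @export
y_assays <- function(panel) panel$assay_id[panel$y_linked]

# Validate a long call table against a panel: every sample must carry exactly
# one call per panel assay, with calls drawn from call_levels().
check_calls <- function(calls, panel, what = "calls") {
  req <- c("sample_id", "assay_id", "call")
  miss <- setdiff(req, names(calls))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  bad <- setdiff(unique(calls$call), call_levels())
  if (length(bad) > 0) {
    stop(sprintf("%s contains unknown call categories: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  per <- table(calls$sample_id, factor(calls$assay_id, levels = panel$assay_id))
  extra <- setdiff(unique(calls$assay_id), panel$assay_id)
  if (length(extra) > 0) {
    stop(sprintf("%s contains assays not in the panel: %s", what,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  if (any(per != 1L)) {
    off <- which(per != 1L, arr.ind = TRUE)
    ex <- sprintf("%s x %s", rownames(per)[off[1, 1]], colnames(per)[off[1, 2]])
    stop(sprintf(
      "%s must cover every panel assay exactly once per sample (first offender: %s)",
      what, ex), call. = FALSE)
  }
  invisible(calls)
}

# Wide sample x assay character matrix of calls, panel column order.
calls_matrix <- function(calls, panel) {
  wide <- tidyr::pivot_wider(
    calls[, c("sample_id", "assay_id", "call")],
    names_from = "assay_id", values_from = "call"
  )
  m <- as.matrix(wide[, panel$assay_id, drop = FALSE])
  rownames(m) <- wide$sample_id
  m
}

# Allele copy numbers per diploid genome implied by a categorical call.
# HOM1 = (2,0), HET = (1,1), HOM2 = (0,2); NOAMP/UNDET carry no dosage (NA).
call_dosage <- function(call) {
  a2 <- c(HOM1 = 0, HET = 1, HOM2 = 2, NOAMP = NA_real_, UNDET = NA_real_)[call]
  tibble::tibble(a1 = ifelse(is.na(a2), NA_real_, 2 - unname(a2)),
                 a2 = unname(a2))
}
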