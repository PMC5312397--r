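# Readers and writers for the instrument-style export dialects and the
# run-report files.
#
# calls_csv:  sample_id, assay_id, call   (one row per sample x assay)
# traces_csv: sample_id, assay_id, cycle, f1, f2 (one row per cycle)
# Spreadsheet users: export/save-as CSV (UTF-8, header row) before import.

#' Read a genotype-call export
#'
#' Parses the `calls_csv` dialect. Unknown call strings map to `UNDET` and
#' assays missing for a sample are filled in as `NOAMP`, both with a
#' warning; duplicate `(sample, assay)` rows and empty files are rejected.
#' A vendor-vocabulary table can translate instrument call strings (e.g.
#' "Homozygous Allele 1") to the package's categories first.
#'
#' @param path CSV path.
#' @param panel Assay panel tibble; profiles are completed against it.
#' @param call_map Optional named character vector translating foreign call
#'   strings to `call_levels()` (names = foreign strings).
#' @return Calls tibble (`sample_id`, `assay_id`, `call`).
#' @export
read_genotype_calls <- function(path, panel = snp_panel(), call_map = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("no such file: %s", path), call. = FALSE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  req <- c("sample_id", "assay_id", "call")
  if (nrow(raw) == 0) {
    stop(sprintf("empty calls file: %s", path), call. = FALSE)
  }
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0) {
    stop(sprintf("calls file lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  dup <- raw |>
    dplyr::count(.data$sample_id, .data$assay_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop(sprintf("duplicate rows for sample %s, assay %s",
                 dup$sample_id[1], dup$assay_id[1]), call. = FALSE)
  }
  calls <- raw[, req]
  if (!is.null(call_map)) {
    hit <- calls$call %in% names(call_map)
    calls$call[hit] <- unname(call_map[calls$call[hit]])
  }
  unknown <- !(calls$call %in% call_levels())
  if (any(unknown)) {
    warning(sprintf("%d unknown call string(s) (e.g. '%s') mapped to UNDET",
                    sum(unknown), calls$call[which(unknown)[1]]),
            call. = FALSE)
    calls$call[unknown] <- "UNDET"
  }
  extra <- setdiff(unique(calls$assay_id), panel$assay_id)
  if (length(extra) > 0) {
    stop(sprintf("calls file contains assays not in the panel: %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  full <- tidyr::expand_grid(sample_id = unique(calls$sample_id),
                             assay_id = panel$assay_id)
  out <- dplyr::left_join(full, calls, by = c("sample_id", "assay_id"))
  n_missing <- sum(is.na(out$call))
  if (n_missing > 0) {
    warning(sprintf("%d missing sample x assay row(s) filled as NOAMP",
                    n_missing), call. = FALSE)
    out$call[is.na(out$call)] <- "NOAMP"
  }
  out
}

#' Write genotype calls in the `calls_csv` dialect
#'
#' @param calls Calls tibble.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_calls <- function(calls, path) {
  readr::write_csv(calls[, c("sample_id", "assay_id", "call")], path)
  invisible(path)
}

#' Read / write amplification traces (`traces_csv` dialect)
#'
#' @param path CSV path.
#' @return Trace tibble (`sample_id`, `assay_id`, `cycle`, `f1`, `f2`).
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("no such file: %s", path), call. = FALSE)
  }
  tr <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          sample_id = "c", assay_id = "c",
                          cycle = "i", f1 = "d", f2 = "d"))
  req <- c("sample_id", "assay_id", "cycle", "f1", "f2")
  miss <- setdiff(req, names(tr))
  if (length(miss) > 0) {
    stop(sprintf("traces file lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  tr[, req]
}

#' @rdname read_traces
#' @param traces Trace tibble.
#' @export
write_traces <- function(traces, path) {
  readr::write_csv(traces[, c("sample_id", "assay_id", "cycle", "f1", "f2")],
                   path)
  invisible(path)
}

#' Write the three run-report files plus a machine-readable verdict CSV
#'
#' Mirrors the classic validation-run output: `summary.txt` lists every
#' sample with its status (and disposition when signal review ran),
#' `validated.txt` the validated samples, `contaminated.txt` every flagged
#' (non-validated) sample with the reason. Every sample appears in exactly
#' one of the two list files; `verdicts.csv` holds the full verdict table.
#'
#' @param verdicts Verdict tibble from [validate_samples()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_reports <- function(verdicts, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(summary = file.path(out_dir, "summary.txt"),
             contaminated = file.path(out_dir, "contaminated.txt"),
             validated = file.path(out_dir, "validated.txt"),
             verdicts = file.path(out_dir, "verdicts.csv"))

  ok <- verdicts$status == "VALIDATED"
  line <- function(v) {
    sprintf("%s\texpected=%s\tstatus=%s%s", v$sample_id,
            v$expected_reference, v$status,
            ifelse(is.na(v$disposition), "",
                   paste0("\tdisposition=", v$disposition)))
  }
  writeLines(c(
    sprintf("Genotyping validation summary: %d sample(s), %d validated, %d flagged",
            nrow(verdicts), sum(ok), sum(!ok)),
    if (nrow(verdicts) > 0) line(verdicts)
  ), paths["summary"])
  writeLines(if (any(!ok)) line(verdicts[!ok, ]) else character(),
             paths["contaminated"])
  writeLines(if (any(ok)) verdicts$sample_id[ok] else character(),
             paths["validated"])
  flat <- verdicts |>
    dplyr::mutate(notes = vapply(.data$notes, paste, character(1),
                                 collapse = "; "))
  if ("evidence" %in% names(flat)) flat$evidence <- NULL
  readr::write_csv(flat, paths["verdicts"])
  invisible(paths)
}

#' Plot amplification traces
#'
#' Per-cycle curves for both channels of each assay, faceted by assay — the
#' multicomponent view in which a late-rising minor channel betrays a
#' contaminant.
#'
#' @param traces Trace tibble (one or a few samples).
#' @return A ggplot object.
#' @export
plot_traces <- function(traces) {
  df <- tidyr::pivot_longer(traces, c("f1", "f2"), names_to = "channel",
                            values_to = "fluorescence")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle,
                                   y = .data$fluorescence,
                                   color = .data$channel,
                                   linetype = .data$sample_id)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~assay_id, scales = "free_y") +
    ggplot2::scale_color_manual(values = c(f1 = "#d73027", f2 = "#4575b4"),
                                labels = c("allele 1", "allele 2"),
                                name = "Channel") +
    ggplot2::labs(x = "Cycle", y = "Fluorescence (a.u.)",
                  linetype = "Sample") +
    ggplot2::theme_minimal()
}

#' Endpoint allelic-discrimination plot
#'
#' Endpoint fluorescence of channel 1 against channel 2 for each sample at
#' each assay: homozygotes sit on the axes, heterozygotes near the
#' diagonal, mixtures in between.
#'
#' @param summaries Output of [summarize_traces()] (optionally after
#'   [call_genotypes()], in which case points are colored by call).
#' @return A ggplot object.
#' @export
plot_discrimination <- function(summaries) {
  has_call <- "call" %in% names(summaries)
  p <- ggplot2::ggplot(summaries,
                       ggplot2::aes(x = .data$f1_end, y = .data$f2_end))
  p <- if (has_call) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$call)) +
      ggplot2::scale_color_manual(
        values = c(HOM1 = "#d73027", HOM2 = "#4575b4", HET = "#1a9850",
                   NOAMP = "grey70", UNDET = "grey30"),
        name = "Call")
  } else {
    p + ggplot2::geom_point()
  }
  p + ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                           color = "grey60") +
    ggplot2::labs(x = "Allele 1 fluorescence (a.u.)",
                  y = "Allele 2 fluorescence (a.u.)") +
    ggplot2::theme_minimal()
}
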