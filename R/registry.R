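# Reference registry: building, growing, persisting and inspecting the
# table of reference SNP barcodes that samples are authenticated against.

#' Build a reference registry from barcode profiles
#'
#' Assembles the registry of reference profiles (one per patient, taken from
#' the patient sample or, when unavailable, the earliest available xenograft
#' passage). Same-patient duplicates (e.g. diagnosis/relapse pairs) are
#' permitted; they are expected to match each other exactly and are treated
#' identically in matching.
#'
#' @param calls Long calls tibble (`sample_id`, `assay_id`, `call`); each
#'   `sample_id` becomes a `reference_id` and must cover the panel exactly
#'   once.
#' @param metadata Optional tibble with `reference_id` and any of
#'   `patient_id`, `sex`, `provenance` (`"patient"` or
#'   `"earliest-passage"`). Missing fields are filled: `patient_id`
#'   defaults to the reference ID, `sex` is inferred from the Y assays.
#' @param panel Assay panel tibble.
#' @param karyotype Optional tibble of copy-number regions:
#'   `reference_id`, `chromosome`, `start`, `end` (1-based inclusive),
#'   `total_copies`, `allele2_copies`. Panel loci inside a region are exempt
#'   from angle-deviation contamination evidence for that reference.
#' @return A `pas_registry` object (list with `panel`, `calls`, `metadata`,
#'   `karyotype`).
#' @examples
#' co <- simulate_profiles(3, sim_config(n_loci = 8), seed = 1)
#' reg <- assign_references(co$calls, panel = sim_config(n_loci = 8)$panel)
#' reg
#' @export
assign_references <- function(calls, metadata = NULL, panel = snp_panel(),
                              karyotype = NULL) {
  if (nrow(calls) > 0) {
    dup <- calls |>
      dplyr::count(.data$sample_id, .data$assay_id) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup) > 0) {
      stop(sprintf("duplicate reference entries for %s at %s",
                   dup$sample_id[1], dup$assay_id[1]), call. = FALSE)
    }
    per <- calls |> dplyr::count(.data$sample_id)
    short <- per$sample_id[per$n != nrow(panel)]
    if (length(short) > 0) {
      missing_assays <- setdiff(
        panel$assay_id, calls$assay_id[calls$sample_id == short[1]])
      stop(sprintf("profile %s does not cover the panel (missing: %s)",
                   short[1], paste(missing_assays, collapse = ", ")),
           call. = FALSE)
    }
    check_calls(calls, panel, "reference calls")
  }
  ids <- unique(calls$sample_id)
  sex_tab <- if (length(ids) > 0) infer_sex(calls, panel) else
    tibble::tibble(sample_id = character(), inferred_sex = character())
  md <- tibble::tibble(reference_id = ids) |>
    dplyr::left_join(
      dplyr::rename(sex_tab, reference_id = "sample_id"),
      by = "reference_id")
  if (!is.null(metadata)) {
    stopifnot("reference_id" %in% names(metadata))
    md <- dplyr::left_join(md, metadata, by = "reference_id")
  }
  if (!"patient_id" %in% names(md)) md$patient_id <- md$reference_id
  md$patient_id <- dplyr::coalesce(md$patient_id, md$reference_id)
  if (!"sex" %in% names(md)) md$sex <- md$inferred_sex
  md$sex <- dplyr::coalesce(md$sex, md$inferred_sex)
  if (!"provenance" %in% names(md)) md$provenance <- "patient"
  md$provenance <- dplyr::coalesce(md$provenance, "patient")
  md <- md[, c("reference_id", "patient_id", "sex", "provenance")]

  kt <- if (is.null(karyotype)) {
    tibble::tibble(reference_id = character(), chromosome = character(),
                   start = integer(), end = integer(),
                   total_copies = integer(), allele2_copies = integer())
  } else {
    stopifnot(all(c("reference_id", "chromosome", "start", "end",
                    "total_copies", "allele2_copies") %in% names(karyotype)))
    if (any(karyotype$start > karyotype$end) ||
        any(karyotype$allele2_copies > karyotype$total_copies) ||
        any(karyotype$allele2_copies < 0)) {
      stop("invalid karyotype region (start > end or allele2 > total copies)",
           call. = FALSE)
    }
    karyotype
  }

  structure(
    list(panel = panel,
         calls = calls |>
           dplyr::rename(reference_id = "sample_id") |>
           dplyr::select(dplyr::any_of(
             c("reference_id", "assay_id", "call", "quality"))),
         metadata = md,
         karyotype = kt),
    class = "pas_registry"
  )
}

#' @export
print.pas_registry <- function(x, ...) {
  cat(sprintf("<pas_registry> %d reference profile(s), %d-assay panel\n",
              nrow(x$metadata), nrow(x$panel)))
  if (nrow(x$karyotype) > 0) {
    cat(sprintf("  %d karyotype region annotation(s)\n", nrow(x$karyotype)))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn assign_references Long tidy view of the registry calls joined
#'   with their metadata.
#' @param x A `pas_registry`.
#' @param ... Unused.
#' @method tidy pas_registry
#' @export
tidy.pas_registry <- function(x, ...) {
  dplyr::left_join(x$calls, x$metadata, by = "reference_id")
}

#' @describeIn assign_references One-row summary of the registry.
#' @method glance pas_registry
#' @export
glance.pas_registry <- function(x, ...) {
  tibble::tibble(
    n_references = nrow(x$metadata),
    n_patients = length(unique(x$metadata$patient_id)),
    n_assays = nrow(x$panel),
    n_female = sum(x$metadata$sex == "FEMALE", na.rm = TRUE),
    n_karyotype_regions = nrow(x$karyotype)
  )
}

#' Add a new reference profile to an existing registry
#'
#' The registry grows by one profile; existing entries are untouched. If the
#' new profile matches an existing reference at every locus where both are
#' determined, a warning names the match — expected for same-patient pairs,
#' suspicious otherwise.
#'
#' @param registry A `pas_registry`.
#' @param calls Calls tibble for exactly one new profile.
#' @param metadata Optional one-row metadata tibble (see
#'   [assign_references()]).
#' @return The enlarged `pas_registry`.
#' @export
add_calls <- function(registry, calls, metadata = NULL) {
  stopifnot(inherits(registry, "pas_registry"))
  new_ids <- unique(calls$sample_id)
  if (length(new_ids) != 1) {
    stop("add_calls() adds exactly one profile at a time", call. = FALSE)
  }
  if (new_ids %in% registry$metadata$reference_id) {
    stop(sprintf("reference_id collision: '%s' already registered", new_ids),
         call. = FALSE)
  }
  check_calls(calls, registry$panel, "new profile")

  if (nrow(registry$metadata) > 0) {
    old <- registry$calls |> dplyr::rename(sample_id = "reference_id")
    for (rid in unique(old$sample_id)) {
      cmp <- compare_profiles(
        calls, old[old$sample_id == rid, ], registry$panel)
      if (cmp$n_informative > 0 && cmp$concordance == 1) {
        warning(sprintf(
          "new reference '%s' matches existing reference '%s' at all %d informative loci (same-patient duplicate?)",
          new_ids, rid, cmp$n_informative), call. = FALSE)
      }
    }
  }

  merged <- dplyr::bind_rows(
    registry$calls,
    calls |> dplyr::rename(reference_id = "sample_id") |>
      dplyr::select(dplyr::any_of(
        c("reference_id", "assay_id", "call", "quality")))
  )
  sex_tab <- infer_sex(calls, registry$panel)
  md_new <- tibble::tibble(reference_id = new_ids,
                           inferred_sex = sex_tab$inferred_sex)
  if (!is.null(metadata)) {
    md_new <- dplyr::left_join(md_new, metadata, by = "reference_id")
  }
  if (!"patient_id" %in% names(md_new)) md_new$patient_id <- NA_character_
  if (!"sex" %in% names(md_new)) md_new$sex <- NA_character_
  if (!"provenance" %in% names(md_new)) md_new$provenance <- NA_character_
  md_new <- md_new |>
    dplyr::mutate(
      patient_id = dplyr::coalesce(.data$patient_id, .data$reference_id),
      sex = dplyr::coalesce(.data$sex, .data$inferred_sex),
      provenance = dplyr::coalesce(.data$provenance, "patient")
    ) |>
    dplyr::select("reference_id", "patient_id", "sex", "provenance")

  registry$calls <- merged
  registry$metadata <- dplyr::bind_rows(registry$metadata, md_new)
  registry
}

#' Infer sex from the Y-linked assays
#'
#' A pure function of the Y-assay calls: `FEMALE` when all Y assays fail to
#' amplify, `MALE` when all amplify with a determined genotype,
#' `INCONSISTENT` otherwise (the signature of, e.g., a male/female chimera
#' with partial Y amplification), `UNKNOWN` when the panel has no Y assays.
#'
#' @param calls Calls tibble (one or more samples).
#' @param panel Assay panel tibble.
#' @return Tibble with `sample_id` and `inferred_sex`.
#' @export
infer_sex <- function(calls, panel = snp_panel()) {
  ya <- y_assays(panel)
  ids <- unique(calls$sample_id)
  if (length(ya) == 0) {
    return(tibble::tibble(sample_id = ids, inferred_sex = "UNKNOWN"))
  }
  calls |>
    dplyr::filter(.data$assay_id %in% ya) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      inferred_sex = dplyr::case_when(
        all(.data$call == "NOAMP") ~ "FEMALE",
        all(.data$call %in% .determined) ~ "MALE",
        TRUE ~ "INCONSISTENT"
      ),
      .groups = "drop"
    ) |>
    dplyr::right_join(tibble::tibble(sample_id = ids), by = "sample_id") |>
    dplyr::mutate(inferred_sex = dplyr::coalesce(.data$inferred_sex,
                                                 "UNKNOWN"))
}

#' Write a registry to CSV
#'
#' The reference table is one row per reference — `reference_id`,
#' `patient_id`, `sex`, `provenance`, then one column per assay — so it
#' round-trips bit-exactly and diffs cleanly. Karyotype annotations, if any,
#' go to a companion CSV.
#'
#' @param registry A `pas_registry`.
#' @param path Output CSV path for the reference table.
#' @param karyotype_path Optional CSV path for karyotype regions (defaults
#'   to `<path minus .csv>_karyotype.csv` when regions exist).
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path, karyotype_path = NULL) {
  wide <- registry$metadata
  if (nrow(registry$calls) > 0) {
    wide <- dplyr::left_join(
      wide,
      tidyr::pivot_wider(
        registry$calls[, c("reference_id", "assay_id", "call")],
        names_from = "assay_id", values_from = "call"),
      by = "reference_id"
    )[, c(names(registry$metadata), registry$panel$assay_id)]
  }
  readr::write_csv(wide, path)
  if (nrow(registry$karyotype) > 0) {
    if (is.null(karyotype_path)) {
      karyotype_path <- sub("\\.csv$", "_karyotype.csv", path)
    }
    readr::write_csv(registry$karyotype, karyotype_path)
  }
  invisible(path)
}

#' Read a registry written by [write_registry()]
#'
#' @param path Reference-table CSV.
#' @param panel Assay panel tibble; assay columns in the file must match it.
#' @param karyotype_path Optional karyotype CSV.
#' @return A `pas_registry`.
#' @export
read_registry <- function(path, panel = snp_panel(), karyotype_path = NULL) {
  wide <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  meta_cols <- intersect(c("reference_id", "patient_id", "sex", "provenance"),
                         names(wide))
  assay_cols <- setdiff(names(wide), meta_cols)
  missing_assays <- setdiff(panel$assay_id, assay_cols)
  if (nrow(wide) > 0 && length(missing_assays) > 0) {
    stop(sprintf("reference table lacks assay column(s): %s",
                 paste(missing_assays, collapse = ", ")), call. = FALSE)
  }
  calls <- if (nrow(wide) == 0) {
    tibble::tibble(sample_id = character(), assay_id = character(),
                   call = character())
  } else {
    tidyr::pivot_longer(wide[, c("reference_id", panel$assay_id)],
                        -"reference_id", names_to = "assay_id",
                        values_to = "call") |>
      dplyr::rename(sample_id = "reference_id")
  }
  kt <- NULL
  if (!is.null(karyotype_path) && file.exists(karyotype_path)) {
    kt <- readr::read_csv(karyotype_path, show_col_types = FALSE)
  }
  assign_references(calls, metadata = wide[, meta_cols], panel = panel,
                    karyotype = kt)
}
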