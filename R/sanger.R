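#' Read a Sanger read-call table
#'
#' Tab-separated with header `variant_id individual_id fwd rev`; `fwd` and
#' `rev` are per-strand calls relative to the NGS genotype: `C` concordant,
#' `D` discordant, `N` no usable read (reads failing trace quality control
#' enter as `N`).
#'
#' @param path Path to the TSV.
#' @return A tibble of Sanger observations.
#' @export
read_sanger <- function(path) {
  obs <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default =
                                                   readr::col_character()))
  validate_sanger(obs)
  obs
}

validate_sanger <- function(obs) {
  need <- c("variant_id", "individual_id", "fwd", "rev")
  if (!all(need %in% names(obs))) {
    abort("Sanger table needs columns variant_id, individual_id, fwd, rev")
  }
  bad <- setdiff(unique(c(obs$fwd, obs$rev)), c("C", "D", "N"))
  if (length(bad) > 0) {
    abort(paste0("Sanger calls must be C, D or N; found: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(obs)
}

#' Write a Sanger observation tibble
#' @param obs Sanger observation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sanger <- function(obs, path) {
  readr::write_tsv(obs, path)
  invisible(path)
}

#' Classify the Sanger verification status of interrogated variants
#'
#' The decision rule quotes affected individuals only. For each variant the
#' expected evidence set is its sequenced affected NGS carriers:
#' * `fully_verified` — every expected carrier has concordant forward AND
#'   reverse reads;
#' * `partially_validated` — at least one expected carrier has both strands
#'   concordant, but not all do;
#' * `design_failed` — no expected carrier has both strands concordant
#'   (covers assays with no usable reads at all, e.g. failed primer
#'   design, and assays whose reads never confirmed the call).
#'
#' Observations for individuals who are not expected carriers of the
#' variant raise a validation error; reads from unaffected relatives never
#' enter the status.
#'
#' @param sanger Sanger observation tibble (see [read_sanger()]).
#' @param cohort A [cohort()].
#' @param variant_ids Variants interrogated (default: all variants with a
#'   Sanger observation).
#' @return A tibble with columns `variant_id`, `status`, `n_expected`,
#'   `n_confirmed` (expected carriers with both strands concordant).
#' @export
verify_variants <- function(sanger, cohort, variant_ids = NULL) {
  validate_sanger(sanger)
  variant_ids <- variant_ids %||% unique(sanger$variant_id)
  expected <- cohort$genotypes |>
    filter(is_carrier(.data$call),
           .data$variant_id %in% variant_ids) |>
    semi_join(filter(cohort$pedigree, .data$affected, .data$sequenced),
              by = "individual_id") |>
    select("variant_id", "individual_id")

  stray <- sanger |>
    filter(.data$variant_id %in% variant_ids) |>
    anti_join(expected, by = c("variant_id", "individual_id"))
  if (nrow(stray) > 0) {
    abort(paste0(
      "Sanger observation for a non-carrier or unaffected individual: ",
      paste(head(paste(stray$variant_id, stray$individual_id), 3),
            collapse = "; ")))
  }

  per_carrier <- expected |>
    left_join(sanger, by = c("variant_id", "individual_id")) |>
    mutate(confirmed = !is.na(.data$fwd) & .data$fwd == "C" &
             !is.na(.data$rev) & .data$rev == "C")
  per_carrier |>
    summarise(n_expected = n(), n_confirmed = sum(.data$confirmed),
              .by = "variant_id") |>
    right_join(tibble(variant_id = variant_ids), by = "variant_id") |>
    mutate(
      n_expected = coalesce(.data$n_expected, 0L),
      n_confirmed = coalesce(.data$n_confirmed, 0L),
      status = case_when(
        .data$n_expected > 0 & .data$n_confirmed == .data$n_expected ~
          "fully_verified",
        .data$n_confirmed >= 1 ~ "partially_validated",
        .default = "design_failed"
      )
    ) |>
    select("variant_id", "status", "n_expected", "n_confirmed")
}

#' Summarise verification statuses
#'
#' @param verification Tibble with a `status` column (from
#'   [verify_variants()]).
#' @return One-row tibble: `n_interrogated`, `n_fully_verified`,
#'   `n_partially_validated`, `n_design_failed`, `n_validated_at_least_partially`
#'   (fully + partially).
#' @export
verification_summary <- function(verification) {
  stopifnot(nrow(verification) > 0)
  tibble(
    n_interrogated = nrow(verification),
    n_fully_verified = sum(verification$status == "fully_verified"),
    n_partially_validated = sum(verification$status == "partially_validated"),
    n_design_failed = sum(verification$status == "design_failed")
  ) |>
    mutate(n_validated_at_least_partially =
             .data$n_fully_verified + .data$n_partially_validated)
}
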