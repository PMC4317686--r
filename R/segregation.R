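# Carrier ratios, sharing/novelty/privacy classification, and multi-family
# gene detection over the final candidate list.

#' Carrier ratios for one variant in one family
#'
#' Numerators count carrier calls among sequenced members of each stratum
#' (affected / unaffected); denominators count all sequenced members of the
#' stratum. A missing genotype counts as non-carrier in the numerator while
#' the individual stays in the denominator.
#'
#' @param cohort A [cohort()].
#' @param variant_id Variant key.
#' @param family_id Family identifier.
#' @return A one-row candidate-record tibble: `family_id`, `variant_id`,
#'   `affected_carriers`, `affected_sequenced`, `unaffected_carriers`,
#'   `unaffected_sequenced`.
#' @export
carrier_ratios <- function(cohort, variant_id, family_id) {
  members <- cohort$pedigree |>
    filter(.data$family_id == !!family_id, .data$sequenced)
  if (nrow(members) == 0) abort("family has no sequenced members")
  carriers <- cohort$genotypes |>
    filter(.data$variant_id == !!variant_id, is_carrier(.data$call)) |>
    pull(.data$individual_id)
  tibble(
    family_id = family_id,
    variant_id = variant_id,
    affected_carriers =
      sum(members$affected & members$individual_id %in% carriers),
    affected_sequenced = sum(members$affected),
    unaffected_carriers =
      sum(!members$affected & members$individual_id %in% carriers),
    unaffected_sequenced = sum(!members$affected)
  )
}

#' Candidate records for final-list variants
#'
#' One record per (variant, segregating family), with carrier ratios and
#' the variant annotation columns joined on.
#'
#' @param cohort A [cohort()].
#' @param variant_ids Final-list variant keys.
#' @return A candidate-record tibble.
#' @export
candidate_records <- function(cohort, variant_ids) {
  seg <- family_segregation_filter(cohort, variant_ids) |>
    filter(.data$keep) |>
    select("variant_id", "segregating_families") |>
    tidyr::unnest_longer("segregating_families",
                         values_to = "family_id")
  if (nrow(seg) == 0) {
    return(tibble(
      family_id = character(), variant_id = character(),
      affected_carriers = integer(), affected_sequenced = integer(),
      unaffected_carriers = integer(), unaffected_sequenced = integer()
    ) |>
      left_join(cohort$variants, by = "variant_id"))
  }
  map2(seg$variant_id, seg$family_id,
       function(v, f) carrier_ratios(cohort, v, f)) |>
    list_rbind() |>
    left_join(cohort$variants, by = "variant_id")
}

#' Classify candidate sharing
#'
#' A final-list candidate is `shared` when its family has at least two
#' sequenced affected members (all of whom carry it, by the segregation
#' guarantee); with exactly one sequenced affected carrier it is
#' `single_affected`.
#'
#' @param records Candidate-record tibble (final list: affected numerator
#'   equals denominator, at least 1).
#' @return The records with a `sharing` column
#'   (`"shared"`/`"single_affected"`).
#' @export
classify_sharing <- function(records) {
  if (any(records$affected_sequenced == 0)) {
    abort("final-list records must have >= 1 sequenced affected carrier")
  }
  mutate(records, sharing = ifelse(.data$affected_sequenced >= 2,
                                   "shared", "single_affected"))
}

#' Is a variant novel?
#'
#' Novel means never reported in a public database: no dbSNP identifier and
#' no ESP or 1000 Genomes frequency.
#'
#' @param variants Tibble with `dbsnp`, `esp_pct`, `kg_pct` (and optionally
#'   `kg_ceu_pct`) columns.
#' @return Logical vector.
#' @export
is_novel <- function(variants) {
  kg_ceu <- if ("kg_ceu_pct" %in% names(variants)) variants$kg_ceu_pct
            else NA_real_
  is.na(variants$dbsnp) & is.na(variants$esp_pct) & is.na(variants$kg_pct) &
    is.na(kg_ceu)
}

#' Is a candidate variant private to one family?
#'
#' @param variant_id Variant keys to test.
#' @param records Final candidate-record tibble.
#' @return Logical vector: `TRUE` iff exactly one family holds a record for
#'   the variant.
#' @export
is_private <- function(variant_id, records) {
  fam_counts <- records |>
    distinct(.data$variant_id, .data$family_id) |>
    count(.data$variant_id)
  n <- fam_counts$n[match(variant_id, fam_counts$variant_id)]
  !is.na(n) & n == 1
}

#' Genes implicated in more than one family
#'
#' @param records Final candidate-record tibble with `gene` and `family_id`.
#' @return Sorted character vector of gene symbols appearing in records of
#'   at least two distinct families.
#' @export
genes_in_multiple_families <- function(records) {
  records |>
    filter(!is.na(.data$gene)) |>
    distinct(.data$gene, .data$family_id) |>
    count(.data$gene) |>
    filter(.data$n >= 2) |>
    pull(.data$gene) |>
    sort()
}
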