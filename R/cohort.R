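#' Assemble a family cohort
#'
#' A cohort bundles the three tables the triage operates on: the pedigree
#' (families, affected/sequenced flags), the annotated variants, and the
#' per-(variant, individual) genotype calls. Genotype entries may exist only
#' for sequenced individuals.
#'
#' @param pedigree Pedigree tibble (see [read_pedigree()]).
#' @param variants Variant tibble (see [read_variants()]).
#' @param genotypes Genotype tibble.
#' @return An object of class `glioseg_cohort` (a named list of the three
#'   tibbles).
#' @export
cohort <- function(pedigree, variants, genotypes) {
  validate_pedigree(pedigree)
  if (anyDuplicated(pedigree$individual_id)) {
    abort("individual IDs must be unique across the cohort")
  }
  validate_variants(variants)
  bad_call <- setdiff(unique(genotypes$call), genotype_calls())
  if (length(bad_call) > 0) {
    abort(paste0("unknown genotype call: ", paste(bad_call, collapse = ", ")))
  }
  orphan_v <- setdiff(unique(genotypes$variant_id), variants$variant_id)
  if (length(orphan_v) > 0) {
    abort(paste0("genotypes reference unknown variants: ",
                 paste(head(orphan_v, 3), collapse = ", ")))
  }
  seq_ids <- pedigree$individual_id[pedigree$sequenced]
  orphan_i <- setdiff(unique(genotypes$individual_id), seq_ids)
  if (length(orphan_i) > 0) {
    abort(paste0("genotypes reference individuals that are not sequenced ",
                 "pedigree members: ", paste(head(orphan_i, 3),
                                             collapse = ", ")))
  }
  structure(
    list(pedigree = as_tibble(pedigree), variants = as_tibble(variants),
         genotypes = as_tibble(genotypes)),
    class = "glioseg_cohort"
  )
}

#' @export
print.glioseg_cohort <- function(x, ...) {
  ped <- x$pedigree
  cat(sprintf(
    "<glioseg_cohort> %d famil%s, %d individuals (%d sequenced; %d affected sequenced), %d variants\n",
    n_distinct(ped$family_id),
    if (n_distinct(ped$family_id) == 1) "y" else "ies",
    nrow(ped), sum(ped$sequenced), sum(ped$sequenced & ped$affected),
    nrow(x$variants)
  ))
  invisible(x)
}

#' Write a cohort to PED + VCF + annotation TSV
#'
#' Writes `cohort.ped`, `cohort.vcf` and `annotations.tsv` into `dir`; the
#' files round-trip through [read_cohort()].
#'
#' @param x A `glioseg_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_files <- function(x, dir) {
  stopifnot(inherits(x, "glioseg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pedigree(x$pedigree, file.path(dir, "cohort.ped"))
  write_vcf(x$variants, x$genotypes, file.path(dir, "cohort.vcf"))
  write_annotations(x$variants, file.path(dir, "annotations.tsv"))
  invisible(dir)
}

#' Read a cohort back from a directory written by [write_cohort_files()]
#'
#' @param dir Directory containing `cohort.ped`, `cohort.vcf`,
#'   `annotations.tsv`.
#' @return A `glioseg_cohort`.
#' @export
read_cohort <- function(dir) {
  ped <- read_pedigree(file.path(dir, "cohort.ped"))
  vg <- read_variants(file.path(dir, "cohort.vcf"),
                      file.path(dir, "annotations.tsv"), pedigree = ped)
  cohort(ped, vg$variants, vg$genotypes)
}

#' Packaged final-candidate variant table
#'
#' The 21 very rare or novel missense candidate variants on chromosome 17q,
#' one row per (family, variant), with the published population frequencies
#' (percent), dbSNP identifiers, affected/unaffected carrier ratios and
#' CADD scaled C-scores.
#'
#' @return A tibble with columns `family_id`, `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `esp_pct`, `kg_pct`, `dbsnp`,
#'   `affected_carriers`, `affected_sequenced`, `unaffected_carriers`,
#'   `unaffected_sequenced`, `cadd_scaled`.
#' @export
gliogene_candidates <- function() {
  path <- system.file("extdata", "gliogene_candidates.tsv",
                      package = "glioseg", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    family_id = readr::col_character(),
                    dbsnp = readr::col_character(),
                    ref = readr::col_character(),
                    alt = readr::col_character(),
                    gene = readr::col_character(),
                    affected_ratio = readr::col_character(),
                    unaffected_ratio = readr::col_character()
                  )) |>
    mutate(
      variant_id = variant_key("17", .data$pos, .data$ref, .data$alt),
      chrom = "17",
      affected_carriers = ratio_part(.data$affected_ratio, 1),
      affected_sequenced = ratio_part(.data$affected_ratio, 2),
      unaffected_carriers = ratio_part(.data$unaffected_ratio, 1),
      unaffected_sequenced = ratio_part(.data$unaffected_ratio, 2)
    ) |>
    select("family_id", "variant_id", "chrom", "pos", "ref", "alt", "gene",
           "esp_pct", "kg_pct", "dbsnp", "affected_carriers",
           "affected_sequenced", "unaffected_carriers",
           "unaffected_sequenced", "cadd_scaled")
}

ratio_part <- function(ratio, i) {
  as.integer(vapply(strsplit(ratio, "/", fixed = TRUE), `[[`, "", i))
}

#' Reconstruct a cohort around the packaged candidate table
#'
#' Builds a `glioseg_cohort` in which the packaged candidate variants have
#' exactly the published carrier structure: the affected sequenced members
#' come from [gliogene_pedigree()], and synthetic unaffected sequenced
#' members are added per family to match the published unaffected
#' denominators (the unaffected relatives themselves are not published).
#' Genotypes assign carrier calls so every printed affected and unaffected
#' ratio is reproduced. All candidate variants are annotated missense.
#'
#' @return A list with elements `cohort` (a `glioseg_cohort`), `targets`
#'   (synthetic exonic capture intervals of ±10 bp around each candidate
#'   position), and `sanger` (a Sanger observation tibble with concordant
#'   forward/reverse reads for every affected carrier).
#' @export
gliogene_cohort <- function() {
  cand <- gliogene_candidates()
  ped <- gliogene_pedigree()

  # synthetic unaffected sequenced members to match printed denominators
  denom <- cand |>
    distinct(.data$family_id, .data$unaffected_sequenced)
  denom <- denom |>
    summarise(n_unaff = max(.data$unaffected_sequenced),
              .by = "family_id")
  unaff <- denom |>
    mutate(members = map2(.data$family_id, .data$n_unaff, function(f, n) {
      if (n == 0) return(empty_pedigree())
      tibble(
        family_id = f, individual_id = paste0(f, "-U", seq_len(n)),
        father_id = NA_character_, mother_id = NA_character_,
        sex = "unknown", affected = FALSE, sequenced = TRUE,
        histology = NA_character_, age_at_diagnosis = NA_real_
      )
    })) |>
    pull(.data$members) |>
    list_rbind()
  ped <- bind_rows(ped, unaff)

  variants <- cand |>
    distinct(.data$variant_id, .data$chrom, .data$pos, .data$ref, .data$alt,
             .data$gene, .data$esp_pct, .data$kg_pct, .data$dbsnp) |>
    mutate(func = "missense", kg_ceu_pct = NA_real_) |>
    left_join(distinct(cand, .data$variant_id, .data$cadd_scaled),
              by = "variant_id") |>
    select("variant_id", "chrom", "pos", "ref", "alt", "gene", "func",
           "dbsnp", "esp_pct", "kg_pct", "kg_ceu_pct", "cadd_scaled")

  seq_members <- filter(ped, .data$sequenced)
  genotypes <- purrr::pmap(
    list(cand$variant_id, cand$family_id, cand$unaffected_carriers),
    function(vid, fam, n_unaff_carr) {
      fam_members <- filter(seq_members, .data$family_id == fam)
      aff_ids <- fam_members$individual_id[fam_members$affected]
      unaff_ids <- sort(fam_members$individual_id[!fam_members$affected])
      carriers <- c(aff_ids, head(unaff_ids, n_unaff_carr))
      tibble(variant_id = vid, individual_id = carriers, call = "carrier-het")
    }
  ) |>
    list_rbind()
  # everyone else sequenced in the cohort is a non-carrier
  full <- tidyr::expand_grid(variant_id = variants$variant_id,
                             individual_id = seq_members$individual_id)
  genotypes <- full |>
    left_join(genotypes, by = c("variant_id", "individual_id")) |>
    mutate(call = coalesce(.data$call, "non-carrier"))

  targets <- genomic_intervals("17", variants$pos - 10, variants$pos + 10) |>
    mutate(exonic = TRUE)

  sanger <- genotypes |>
    filter(is_carrier(.data$call)) |>
    semi_join(filter(ped, .data$affected), by = "individual_id") |>
    transmute(variant_id = .data$variant_id,
              individual_id = .data$individual_id,
              fwd = "C", rev = "C")

  list(cohort = cohort(ped, variants, genotypes), targets = targets,
       sanger = sanger)
}
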