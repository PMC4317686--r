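# Shared fixture builders for the test suite. Everything is constructed in
# code; no binary fixtures.

suppressMessages({
  library(dplyr)
  library(tibble)
})

# A minimal two-family cohort: family FA has two sequenced affected members
# (sibs, parents unsequenced founders) and one sequenced unaffected; family
# FB has one sequenced affected. Variants are placed inside the default
# linkage locus on synthetic exonic targets.
toy_pedigree <- function() {
  tribble(
    ~family_id, ~individual_id, ~father_id, ~mother_id, ~sex, ~affected, ~sequenced,
    "FA", "FA1", NA, NA, "male", FALSE, FALSE,
    "FA", "FA2", NA, NA, "female", FALSE, FALSE,
    "FA", "FA3", "FA1", "FA2", "male", TRUE, TRUE,
    "FA", "FA4", "FA1", "FA2", "female", TRUE, TRUE,
    "FA", "FA5", "FA1", "FA2", "female", FALSE, TRUE,
    "FB", "FB1", NA, NA, "female", TRUE, TRUE,
    "FB", "FB2", NA, NA, "male", FALSE, TRUE
  ) |>
    mutate(histology = NA_character_, age_at_diagnosis = NA_real_)
}

toy_variant <- function(pos, ref = "G", alt = "A", gene = "GENEX",
                        func = "missense", dbsnp = NA_character_,
                        esp_pct = NA_real_, kg_pct = NA_real_,
                        kg_ceu_pct = NA_real_, cadd_scaled = NA_real_) {
  tibble(
    variant_id = variant_key("17", pos, ref, alt),
    chrom = "17", pos = pos, ref = ref, alt = alt, gene = gene, func = func,
    dbsnp = dbsnp, esp_pct = esp_pct, kg_pct = kg_pct,
    kg_ceu_pct = kg_ceu_pct, cadd_scaled = cadd_scaled
  )
}

toy_genotypes <- function(variant_id, carriers,
                          all_ids = c("FA3", "FA4", "FA5", "FB1", "FB2")) {
  tibble(
    variant_id = variant_id, individual_id = all_ids,
    call = ifelse(all_ids %in% carriers, "carrier-het", "non-carrier")
  )
}

toy_targets <- function(positions) {
  genomic_intervals("17", positions - 20, positions + 20) |>
    mutate(exonic = TRUE)
}

toy_cohort <- function(variants, genotypes) {
  cohort(toy_pedigree(), variants, genotypes)
}

# independent brute-force oracle for the post-Sanger survivor set: plain
# base-R per-variant evaluation of the conjunction of all final predicates
post_stage_oracle <- function(variants, statuses, locus, exonic_targets,
                              maf_threshold = 0.1) {
  keep <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    if (statuses[[v$variant_id]] != "fully_verified") return(FALSE)
    in_locus <- any(locus$start <= v$pos & v$pos <= locus$end &
                      locus$chrom == v$chrom)
    if (!in_locus) return(FALSE)
    freqs <- c(v$esp_pct, v$kg_pct, v$kg_ceu_pct)
    if (any(!is.na(freqs) & freqs > maf_threshold)) return(FALSE)
    in_exon <- any(exonic_targets$start <= v$pos & v$pos <= exonic_targets$end &
                     exonic_targets$chrom == v$chrom)
    if (!in_exon) return(FALSE)
    v$func %in% c("missense", "nonsense", "frameshift", "splice")
  }, logical(1))
  variants$variant_id[keep]
}

# small deterministic sim config for fast end-to-end runs
fast_sim_config <- function(seed, ...) {
  sim_config(seed = seed, n_families = 6, n_planted_candidates = 4,
             background_variant_count = 8, ...)
}
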