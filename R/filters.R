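#' Configuration for the staged variant triage
#'
#' Bundles the positional gates and thresholds the filters use. Defaults
#' reproduce the published schema: the two-interval chromosome 17q linkage
#' locus, a 200 bp pad around capture targets, a 5% common-variant cutoff
#' for the initial stage and a 0.1% very-rare cutoff for the final stage,
#' with the 23-gene chromosome 17 Cancer Gene Census list as the waiver set.
#' Both cutoffs are strict: a variant at exactly the threshold is kept.
#'
#' @param linkage_locus Interval tibble (default [linkage_locus_17q()]).
#' @param targets Target tibble with `chrom`, `start`, `end` and an
#'   `exonic` logical column (see [read_targets()]).
#' @param target_pad_bases Pad in bases around targets for the initial
#'   targeted-region filter (default 200).
#' @param cgc_genes Character vector of waiver genes (default
#'   [load_cgc_genes()]).
#' @param initial_maf_threshold_percent Initial common-variant cutoff in
#'   percent (default 5).
#' @param final_maf_threshold_percent Final very-rare cutoff in percent
#'   (default 0.1).
#' @param protein_altering Functional classes kept by the
#'   protein-alteration filter (default [protein_altering_classes()]).
#' @return A `glioseg_config` list.
#' @export
filter_config <- function(linkage_locus = linkage_locus_17q(),
                          targets = NULL,
                          target_pad_bases = 200,
                          cgc_genes = load_cgc_genes(),
                          initial_maf_threshold_percent = 5,
                          final_maf_threshold_percent = 0.1,
                          protein_altering = protein_altering_classes()) {
  stopifnot(target_pad_bases >= 0,
            initial_maf_threshold_percent > 0,
            initial_maf_threshold_percent < 100,
            final_maf_threshold_percent > 0,
            final_maf_threshold_percent < 100)
  structure(
    list(
      linkage_locus = linkage_locus,
      targets = targets,
      target_pad_bases = target_pad_bases,
      cgc_genes = cgc_genes,
      initial_maf_threshold_percent = initial_maf_threshold_percent,
      final_maf_threshold_percent = final_maf_threshold_percent,
      protein_altering = protein_altering
    ),
    class = "glioseg_config"
  )
}

#' Linked-locus filter
#'
#' Keeps variants inside the linkage locus; outside it, only variants in
#' Cancer Gene Census genes are kept (when `waive_cgc = TRUE`, the initial
#' stage). The post-Sanger stage applies the same gate with no waiver.
#'
#' @param variants Variant tibble.
#' @param config A [filter_config()].
#' @param waive_cgc Waive the gate for CGC genes (initial stage).
#' @return Logical keep vector, one element per variant row.
#' @export
linked_locus_filter <- function(variants, config, waive_cgc = TRUE) {
  inside <- in_linkage_locus(variants$pos, config$linkage_locus,
                             chrom = variants$chrom)
  if (!waive_cgc) return(inside)
  waived <- !is.na(variants$gene) & variants$gene %in% config$cgc_genes
  inside | waived
}

#' Targeted-region filter
#'
#' `padded` mode (initial stage) keeps variants within
#' `config$target_pad_bases` bases of any capture target (distance 0
#' inside; a tie at exactly the pad is kept), waived for CGC genes when
#' `waive_cgc = TRUE`. `exonic` mode (post-Sanger "Targeted Exome") keeps
#' only variants strictly inside an exonic-flagged target, with no pad and
#' no waiver.
#'
#' @inheritParams linked_locus_filter
#' @param mode `"padded"` or `"exonic"`.
#' @param waive_cgc Waive the padded-mode gate for CGC genes.
#' @return Logical keep vector.
#' @export
targeted_region_filter <- function(variants, config,
                                   mode = c("padded", "exonic"),
                                   waive_cgc = (mode == "padded")) {
  mode <- match.arg(mode)
  targets <- config$targets
  if (is.null(targets) || nrow(targets) == 0) {
    abort("filter_config has no capture targets")
  }
  if (mode == "padded") {
    d <- interval_distance(variants$pos, targets, chrom = variants$chrom)
    keep <- d <= config$target_pad_bases
    if (isTRUE(waive_cgc)) {
      keep <- keep |
        (!is.na(variants$gene) & variants$gene %in% config$cgc_genes)
    }
    keep
  } else {
    ex <- filter(targets, .data$exonic)
    interval_distance(variants$pos, ex, chrom = variants$chrom) == 0
  }
}

#' Population-frequency filter
#'
#' Drops a variant iff any tested, present frequency field is strictly
#' greater than the threshold; absent frequencies never trigger a drop
#' (novel variants survive). Frequencies are percentages, as published.
#'
#' @param variants Variant tibble.
#' @param threshold_percent Cutoff in percent.
#' @param fields Frequency columns to test (default all three:
#'   `esp_pct`, `kg_pct`, `kg_ceu_pct`).
#' @return Logical keep vector.
#' @export
maf_filter <- function(variants, threshold_percent,
                       fields = c("esp_pct", "kg_pct", "kg_ceu_pct")) {
  stopifnot(threshold_percent > 0, threshold_percent < 100)
  vals <- as.matrix(variants[, fields, drop = FALSE])
  if (any(!is.na(vals) & vals < 0)) abort("negative population frequency")
  drop <- apply(vals, 1, function(x) any(!is.na(x) & x > threshold_percent))
  if (nrow(variants) == 0) return(logical(0))
  !drop
}

#' Family co-segregation filter
#'
#' A family segregates a variant iff it has at least one sequenced affected
#' member and every sequenced affected member is a carrier. Variants with
#' no segregating family are dropped — this removes both variants not
#' shared by all affected members of any family and variants present only
#' in unaffected individuals. Missing genotypes count as non-carrier.
#'
#' @param cohort A [cohort()].
#' @param variant_ids Variants to test (default all cohort variants).
#' @return A tibble with columns `variant_id`, `keep` (logical) and
#'   `segregating_families` (list of family IDs).
#' @export
family_segregation_filter <- function(cohort, variant_ids = NULL) {
  variant_ids <- variant_ids %||% cohort$variants$variant_id
  aff <- cohort$pedigree |>
    filter(.data$sequenced, .data$affected) |>
    select("family_id", "individual_id")
  carriers <- cohort$genotypes |>
    filter(is_carrier(.data$call)) |>
    select("variant_id", "individual_id")
  seg <- aff |>
    tidyr::expand_grid(variant_id = variant_ids) |>
    left_join(mutate(carriers, carrier = TRUE),
              by = c("variant_id", "individual_id")) |>
    mutate(carrier = coalesce(.data$carrier, FALSE)) |>
    summarise(all_carry = all(.data$carrier),
              .by = c("variant_id", "family_id")) |>
    filter(.data$all_carry)
  tibble(variant_id = variant_ids) |>
    left_join(
      seg |>
        summarise(segregating_families = list(sort(.data$family_id)),
                  .by = "variant_id"),
      by = "variant_id"
    ) |>
    mutate(
      segregating_families = map(.data$segregating_families,
                                 function(x) x %||% character()),
      keep = lengths(.data$segregating_families) > 0
    ) |>
    select("variant_id", "keep", "segregating_families")
}

#' Protein-alteration filter
#'
#' Keeps variants whose functional class alters the protein product
#' (missense, nonsense, frameshift, splice by default).
#'
#' @inheritParams linked_locus_filter
#' @return Logical keep vector.
#' @export
protein_alteration_filter <- function(variants, config = filter_config()) {
  !is.na(variants$func) & variants$func %in% config$protein_altering
}

# ---- staged runners ---------------------------------------------------------

new_audit <- function() {
  tibble(stage = character(), n_in = integer(), n_out = integer(),
         dropped = list())
}

audit_step <- function(audit, stage, ids_in, keep) {
  bind_rows(audit, tibble(
    stage = stage, n_in = length(ids_in), n_out = sum(keep),
    dropped = list(ids_in[!keep])
  ))
}

audit_fates <- function(audit, ids_in) {
  fate <- rep("passed", length(ids_in))
  names(fate) <- ids_in
  for (i in seq_len(nrow(audit))) {
    dropped <- audit$dropped[[i]]
    fate[dropped[fate[dropped] == "passed"]] <- audit$stage[i]
  }
  tibble(variant_id = ids_in, fate = unname(fate))
}

#' Run the initial (pre-Sanger) filter stage
#'
#' Applies, in order: linked locus (CGC-waived), targeted region (±pad,
#' CGC-waived), rare variant (initial threshold, ESP + 1000G CEU fields),
#' family segregation. Returns the survivors with a per-stage audit trail
#' and a per-variant fate (first dropping stage or `"passed"`).
#'
#' @param cohort A [cohort()].
#' @param config A [filter_config()] with targets set.
#' @return A `glioseg_stage` list: `variants` (surviving variant tibble,
#'   with a `segregating_families` list-column), `audit`, `fates`.
#' @export
run_initial_stage <- function(cohort, config) {
  v <- cohort$variants
  audit <- new_audit()
  ids0 <- v$variant_id

  keep <- linked_locus_filter(v, config, waive_cgc = TRUE)
  audit <- audit_step(audit, "linked_locus", v$variant_id, keep)
  v <- v[keep, , drop = FALSE]

  keep <- targeted_region_filter(v, config, mode = "padded",
                                 waive_cgc = TRUE)
  audit <- audit_step(audit, "targeted_region", v$variant_id, keep)
  v <- v[keep, , drop = FALSE]

  keep <- maf_filter(v, config$initial_maf_threshold_percent,
                     fields = c("esp_pct", "kg_ceu_pct"))
  audit <- audit_step(audit, "rare_variant", v$variant_id, keep)
  v <- v[keep, , drop = FALSE]

  seg <- family_segregation_filter(cohort, v$variant_id)
  audit <- audit_step(audit, "family_segregation", v$variant_id, seg$keep)
  v <- v |>
    left_join(select(seg, "variant_id", "segregating_families"),
              by = "variant_id") |>
    filter(seg$keep)

  structure(list(variants = v, audit = audit,
                 fates = audit_fates(audit, ids0)),
            class = "glioseg_stage")
}

#' Run the post-Sanger filter stage
#'
#' Keeps only fully Sanger-verified variants, then applies the final
#' filters: linked locus (no CGC waiver), very-rare variant (final
#' threshold, all frequency fields), targeted exome (exonic targets, no
#' pad), protein alteration. Emits one candidate record per
#' (variant, segregating family) with carrier ratios (see
#' [candidate_records()]).
#'
#' @param cohort A [cohort()].
#' @param verification Tibble with columns `variant_id`, `status` (from
#'   [verify_variants()]) covering every interrogated variant.
#' @param config A [filter_config()] with exonic targets set.
#' @return A `glioseg_stage` list: `variants`, `candidates` (candidate
#'   record tibble), `audit`, `fates`.
#' @export
run_post_sanger_stage <- function(cohort, verification, config) {
  if (anyNA(verification$status)) {
    abort("every interrogated variant needs a Sanger verification status")
  }
  v <- cohort$variants |>
    semi_join(verification, by = "variant_id")
  audit <- new_audit()
  ids0 <- v$variant_id

  keep <- v$variant_id %in%
    verification$variant_id[verification$status == "fully_verified"]
  audit <- audit_step(audit, "sanger_verified", v$variant_id, keep)
  v <- v[keep, , drop = FALSE]

  keep <- linked_locus_filter(v, config, waive_cgc = FALSE)
  audit <- audit_step(audit, "linked_locus_final", v$variant_id, keep)
  v <- v[keep, , drop = FALSE]

  keep <- maf_filter(v, config$final_maf_threshold_percent,
                     fields = c("esp_pct", "kg_pct", "kg_ceu_pct"))
  audit <- audit_step(audit, "very_rare_variant", v$variant_id, keep)
  v <- v[keep, , drop = FALSE]

  keep <- targeted_region_filter(v, config, mode = "exonic")
  audit <- audit_step(audit, "targeted_exome", v$variant_id, keep)
  v <- v[keep, , drop = FALSE]

  keep <- protein_alteration_filter(v, config)
  audit <- audit_step(audit, "protein_alteration", v$variant_id, keep)
  v <- v[keep, , drop = FALSE]

  records <- candidate_records(cohort, v$variant_id)
  structure(list(variants = v, candidates = records, audit = audit,
                 fates = audit_fates(audit, ids0)),
            class = "glioseg_stage")
}

#' @export
print.glioseg_stage <- function(x, ...) {
  cat("<glioseg_stage>\n")
  print(audit_percentages(x$audit), ...)
  invisible(x)
}

#' Per-stage retention percentages
#'
#' Adds `pct_retained` = 100 * n_out / n_in, rounded half-up to one
#' decimal, to an audit trail; stages with no input get `NA`.
#'
#' @param audit Audit tibble from a stage runner (columns `stage`, `n_in`,
#'   `n_out`).
#' @return The audit tibble with a `pct_retained` column.
#' @examples
#' audit_percentages(tibble::tibble(stage = "sanger", n_in = 539, n_out = 278))
#' @export
audit_percentages <- function(audit) {
  stopifnot(nrow(audit) > 0)
  audit |>
    mutate(pct_retained = ifelse(
      .data$n_in == 0, NA_real_,
      round_half_up(100 * .data$n_out / .data$n_in, 1)
    )) |>
    select(any_of(c("stage", "n_in", "n_out", "pct_retained")))
}

# round half away from zero at `digits` decimals (base round() is half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
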