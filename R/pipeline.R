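#' Run the full two-stage triage
#'
#' Chains the published schema end to end: initial filters, Sanger
#' concordance verification of the survivors, post-Sanger filters, carrier
#' ratios, sharing/novelty/privacy classification and C-score ranking.
#'
#' @param cohort A [cohort()].
#' @param sanger Sanger observation tibble (see [read_sanger()]).
#' @param config A [filter_config()] with targets set.
#' @return A `glioseg_result` list: `initial` and `post` stage objects,
#'   `verification`, `candidates` (ranked, classified records), `audit`
#'   (both stages' trails with retention percentages), `summary` (one-row
#'   tibble, see [glance.glioseg_result()]).
#' @export
run_pipeline <- function(cohort, sanger, config) {
  initial <- run_initial_stage(cohort, config)
  verification <- verify_variants(sanger, cohort,
                                  variant_ids = initial$variants$variant_id)
  post <- run_post_sanger_stage(cohort, verification, config)

  candidates <- post$candidates |>
    classify_sharing0() |>
    mutate(novel = is_novel(post$candidates),
           private = is_private(.data$variant_id, post$candidates)) |>
    rank_candidates()

  audit <- bind_rows(
    mutate(initial$audit, phase = "initial"),
    mutate(post$audit, phase = "post_sanger")
  ) |>
    audit_percentages0()

  res <- structure(
    list(initial = initial, verification = verification, post = post,
         candidates = candidates, audit = audit),
    class = "glioseg_result"
  )
  res$summary <- glance(res)
  res
}

# classify_sharing() errors on an empty final list only via its guard;
# these wrappers keep run_pipeline total on degenerate cohorts
classify_sharing0 <- function(records) {
  if (nrow(records) == 0) return(mutate(records, sharing = character()))
  classify_sharing(records)
}

audit_percentages0 <- function(audit) {
  if (nrow(audit) == 0) return(audit)
  bind_cols(select(audit, -any_of("pct_retained")),
            select(audit_percentages(audit), "pct_retained")) |>
    select("phase", "stage", "n_in", "n_out", "pct_retained", "dropped")
}

#' @export
print.glioseg_result <- function(x, ...) {
  cat("<glioseg_result>\n")
  print(select(x$audit, -"dropped"))
  cat(sprintf("%d candidate variant(s) on the final list\n",
              n_distinct(x$candidates$variant_id)))
  invisible(x)
}

#' Tidy the ranked candidate list of a triage result
#'
#' @param x A `glioseg_result`.
#' @param ... Unused.
#' @return The ranked candidate-record tibble (one row per variant/family
#'   record, with sharing, novelty, privacy, tier and rank columns).
#' @export
tidy.glioseg_result <- function(x, ...) {
  x$candidates
}

#' One-row summary of a triage result
#'
#' @param x A `glioseg_result`.
#' @param ... Unused.
#' @return A one-row tibble: candidate/shared/single-affected counts, novel
#'   count within the shared subset, number of multi-family genes, and the
#'   count of candidates with scaled C-score >= 10.
#' @export
glance.glioseg_result <- function(x, ...) {
  cand <- x$candidates
  tibble(
    n_variants_in = if (nrow(x$initial$audit) > 0) x$initial$audit$n_in[1]
                    else 0L,
    n_sanger_interrogated = nrow(x$verification),
    n_fully_verified =
      sum(x$verification$status == "fully_verified"),
    n_candidates = n_distinct(cand$variant_id),
    n_shared = sum(cand$sharing == "shared"),
    n_single_affected = sum(cand$sharing == "single_affected"),
    n_novel_shared = sum(cand$novel & cand$sharing == "shared"),
    n_multi_family_genes = length(genes_in_multiple_families(cand)),
    n_cscore_ge_10 = sum(!is.na(cand$cadd_scaled) & cand$cadd_scaled >= 10)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# ---- reports ----------------------------------------------------------------

candidate_report_cols <- function() {
  c("FamilyID", "Chr17Position", "RefAllele", "VarAllele", "GeneSymbol",
    "ESPFreqPct", "KGFreqPct", "dbSNP", "AffectedRatio", "UnaffectedRatio",
    "ScaledCScore", "SharingClass", "Novel", "Private")
}

#' Write triage reports to a directory
#'
#' Materialises the result as text reports: `candidates.tsv` (final-list
#' schema: family, position, alleles, gene, frequencies, dbSNP, carrier
#' ratios, scaled C-score, sharing/novel/private flags), `audit_trail.tsv`
#' (stage, in, out, pct), `audit_trail.json` (stage graph with counts) and
#' `summary.json` (final counts, multi-family genes, tier histogram).
#'
#' @param result A `glioseg_result`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
render_reports <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cand <- result$candidates
  cand_out <- tibble(
    FamilyID = cand$family_id,
    Chr17Position = as.integer(cand$pos),
    RefAllele = cand$ref,
    VarAllele = cand$alt,
    GeneSymbol = cand$gene,
    ESPFreqPct = cand$esp_pct,
    KGFreqPct = cand$kg_pct,
    dbSNP = cand$dbsnp,
    AffectedRatio = paste0(cand$affected_carriers, "/",
                           cand$affected_sequenced),
    UnaffectedRatio = paste0(cand$unaffected_carriers, "/",
                             cand$unaffected_sequenced),
    ScaledCScore = cand$cadd_scaled,
    SharingClass = cand$sharing,
    Novel = cand$novel,
    Private = cand$private
  )
  f_cand <- file.path(out_dir, "candidates.tsv")
  readr::write_tsv(cand_out, f_cand)

  audit <- select(result$audit, -"dropped")
  f_audit <- file.path(out_dir, "audit_trail.tsv")
  readr::write_tsv(audit, f_audit)

  f_audit_json <- file.path(out_dir, "audit_trail.json")
  jsonlite::write_json(
    list(stages = audit,
         edges = if (nrow(audit) > 1) {
           tibble(from = audit$stage[-nrow(audit)],
                  to = audit$stage[-1],
                  n = audit$n_out[-nrow(audit)])
         } else {
           tibble(from = character(), to = character(), n = integer())
         }),
    f_audit_json, dataframe = "rows", auto_unbox = TRUE, pretty = TRUE
  )

  tier_counts <- table(factor(
    as.character(deleteriousness_tier(cand$cadd_scaled)),
    levels = levels(deleteriousness_tier(numeric()))
  ))
  summary <- list(
    n_candidates = n_distinct(cand$variant_id),
    n_shared = sum(cand$sharing == "shared"),
    n_single_affected = sum(cand$sharing == "single_affected"),
    n_novel_shared = sum(cand$novel & cand$sharing == "shared"),
    multi_family_genes = genes_in_multiple_families(cand),
    tier_counts = as.list(tier_counts),
    stage_counts = audit
  )
  f_summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, f_summary, dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(c(f_cand, f_audit, f_audit_json, f_summary))
}

#' Re-read a written candidate report
#'
#' Inverse of the `candidates.tsv` writer in [render_reports()].
#'
#' @param path Path to `candidates.tsv`.
#' @return Tibble in the report schema.
#' @export
read_candidate_report <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    FamilyID = readr::col_character(),
                    RefAllele = readr::col_character(),
                    VarAllele = readr::col_character(),
                    GeneSymbol = readr::col_character(),
                    dbSNP = readr::col_character(),
                    AffectedRatio = readr::col_character(),
                    UnaffectedRatio = readr::col_character(),
                    Novel = readr::col_logical(),
                    Private = readr::col_logical()
                  ))
}
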