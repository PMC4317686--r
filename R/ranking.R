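# CADD scaled C-score tiering and deterministic candidate ranking.

#' Deleteriousness tier of a scaled C-score
#'
#' CADD scaled C-scores are phred-like: >= 10 places a substitution in the
#' predicted top 10% most deleterious possible substitutions in the human
#' genome, >= 20 in the top 1%, >= 30 in the top 0.1%. Lower bounds are
#' closed. A missing score yields `NA`.
#'
#' @param c_score Numeric vector of scaled C-scores (>= 0).
#' @return Ordered factor with levels `below_top_10pct < top_10pct <
#'   top_1pct < top_0_1pct`.
#' @examples
#' deleteriousness_tier(c(32, 28.2, 10, 5))
#' @export
deleteriousness_tier <- function(c_score) {
  if (any(!is.na(c_score) & c_score < 0)) {
    abort("scaled C-scores must be >= 0")
  }
  tier <- case_when(
    is.na(c_score) ~ NA_character_,
    c_score >= 30 ~ "top_0_1pct",
    c_score >= 20 ~ "top_1pct",
    c_score >= 10 ~ "top_10pct",
    .default = "below_top_10pct"
  )
  factor(tier,
         levels = c("below_top_10pct", "top_10pct", "top_1pct",
                    "top_0_1pct"),
         ordered = TRUE)
}

#' Rank candidate records by deleteriousness
#'
#' Descending scaled C-score; ties broken by ascending chromosome position;
#' records lacking a score rank last. The sort is stable. A `tier` column
#' (see [deleteriousness_tier()]) and a `rank` column are added.
#'
#' @param records Candidate-record tibble with `cadd_scaled` and `pos`.
#' @return The records, ranked.
#' @export
rank_candidates <- function(records) {
  out <- records |>
    arrange(desc(.data$cadd_scaled), .data$pos) |>
    mutate(tier = deleteriousness_tier(.data$cadd_scaled),
           rank = dplyr::row_number())
  # arrange(desc()) puts NA last already; make that explicit for clarity
  stopifnot(!is.unsorted(is.na(out$cadd_scaled)))
  out
}
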