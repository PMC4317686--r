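cfg_with_targets <- function(positions) {
  filter_config(targets = toy_targets(positions))
}

test_that("linked-locus filter keeps in-locus and CGC-waived variants", {
  v <- dplyr::bind_rows(
    toy_variant(49098662, gene = "SPAG9"),
    toy_variant(29550000, gene = "NF1"),     # outside locus, CGC
    toy_variant(29550000, ref = "C", alt = "G", gene = "GENEX"),
    toy_variant(29550000, ref = "C", alt = "T", gene = NA_character_)
  )
  cfg <- filter_config(targets = toy_targets(49098662))
  expect_equal(linked_locus_filter(v, cfg, waive_cgc = TRUE),
               c(TRUE, TRUE, FALSE, FALSE))
  # post-Sanger mode: no waiver rescues NF1
  expect_equal(linked_locus_filter(v, cfg, waive_cgc = FALSE),
               c(TRUE, FALSE, FALSE, FALSE))
})

test_that("targeted-region filter applies the 200 bp pad and the CGC waiver", {
  tg <- genomic_intervals("17", 1100, 1200) |> dplyr::mutate(exonic = FALSE)
  cfg <- filter_config(targets = tg)
  v <- dplyr::bind_rows(
    toy_variant(1000),                      # distance 100 -> keep
    toy_variant(850),                       # distance 250 -> drop
    toy_variant(900),                       # distance exactly 200 -> keep
    toy_variant(10, gene = "BRCA1")         # far, but CGC-waived
  )
  expect_equal(targeted_region_filter(v, cfg, mode = "padded"),
               c(TRUE, FALSE, TRUE, TRUE))
  # exonic mode: no pad, no waiver, and only exonic-flagged intervals count
  expect_equal(targeted_region_filter(v, cfg, mode = "exonic"),
               c(FALSE, FALSE, FALSE, FALSE))
  cfg_ex <- filter_config(targets = dplyr::mutate(tg, exonic = TRUE))
  expect_equal(targeted_region_filter(toy_variant(1150), cfg_ex, mode = "exonic"),
               TRUE)
})

test_that("frequency filter drops only present frequencies strictly above threshold", {
  expect_true(maf_filter(toy_variant(1, esp_pct = 0.069), 0.1))
  expect_true(maf_filter(toy_variant(1, kg_pct = 0.09), 0.1))
  expect_true(maf_filter(toy_variant(1), 0.1))           # all absent
  expect_false(maf_filter(toy_variant(1, esp_pct = 6), 5))
  expect_true(maf_filter(toy_variant(1, esp_pct = 5), 5))  # at threshold: kept
  expect_true(maf_filter(toy_variant(1, esp_pct = 0.1), 0.1))
  # field selection: a 1000G-overall frequency is ignored by the initial filter
  v <- toy_variant(1, kg_pct = 50)
  expect_true(maf_filter(v, 5, fields = c("esp_pct", "kg_ceu_pct")))
  expect_false(maf_filter(v, 5))
  expect_error(maf_filter(toy_variant(1, esp_pct = -1), 5), "negative")
})

test_that("family segregation requires all sequenced affected of some family to carry", {
  v <- toy_variant(35000000)
  # FA has sequenced affected FA3, FA4; FB has FB1
  seg <- function(carriers) {
    coh <- toy_cohort(v, toy_genotypes(v$variant_id, carriers))
    family_segregation_filter(coh)
  }
  both <- seg(c("FA3", "FA4"))
  expect_true(both$keep)
  expect_equal(both$segregating_families[[1]], "FA")

  expect_false(seg("FA3")$keep)                 # 1 of 2 affected
  expect_false(seg(c("FA5", "FB2"))$keep)       # unaffected-only
  single <- seg("FB1")                          # single-affected family
  expect_true(single$keep)
  expect_equal(single$segregating_families[[1]], "FB")
})

test_that("families with zero sequenced affected members never segregate", {
  ped <- toy_pedigree() |>
    dplyr::mutate(sequenced = ifelse(family_id == "FB" & affected,
                                     FALSE, sequenced))
  v <- toy_variant(35000000)
  g <- toy_genotypes(v$variant_id, "FB2",
                     all_ids = c("FA3", "FA4", "FA5", "FB2"))
  coh <- cohort(ped, v, g)
  expect_false(family_segregation_filter(coh)$keep)
})

test_that("initial stage chains filters with a conserved audit trail", {
  pos <- c(35000000, 35000100, 35000200, 35000300)
  v <- dplyr::bind_rows(
    toy_variant(pos[1]),                          # passes
    toy_variant(20000000),                        # off locus
    toy_variant(40000000),                        # off target (in locus)
    toy_variant(pos[2], esp_pct = 40),            # common
    toy_variant(pos[3])                           # non-segregating
  )
  g <- dplyr::bind_rows(
    toy_genotypes(v$variant_id[1], c("FA3", "FA4")),
    toy_genotypes(v$variant_id[2], c("FA3", "FA4")),
    toy_genotypes(v$variant_id[3], c("FA3", "FA4")),
    toy_genotypes(v$variant_id[4], c("FA3", "FA4")),
    toy_genotypes(v$variant_id[5], "FA3")
  )
  coh <- toy_cohort(v, g)
  cfg <- cfg_with_targets(pos)
  st <- run_initial_stage(coh, cfg)

  expect_equal(st$variants$variant_id, v$variant_id[1])
  # per-variant fates: each decoy attributed to its first failing stage
  fates <- tibble::deframe(st$fates)
  expect_equal(unname(fates[v$variant_id]),
               c("passed", "linked_locus", "targeted_region",
                 "rare_variant", "family_segregation"))
  # chain conservation: in_{k+1} == out_k and out == in - dropped
  expect_equal(st$audit$n_in[-1], st$audit$n_out[-nrow(st$audit)])
  expect_equal(st$audit$n_out, st$audit$n_in - lengths(st$audit$dropped))
  # fates partition the input
  expect_equal(sum(fates == "passed") + sum(fates != "passed"), nrow(v))
})

test_that("degenerate cohorts flow through the initial stage", {
  coh <- toy_cohort(toy_variant(35000000)[0, ], toy_genotypes("x", "FA3")[0, ])
  st <- run_initial_stage(coh, cfg_with_targets(35000000))
  expect_equal(nrow(st$variants), 0)
  expect_true(all(st$audit$n_in == 0))

  common <- dplyr::bind_rows(toy_variant(35000000, esp_pct = 20),
                             toy_variant(35000100, kg_ceu_pct = 90))
  coh <- toy_cohort(common, dplyr::bind_rows(
    toy_genotypes(common$variant_id[1], c("FA3", "FA4")),
    toy_genotypes(common$variant_id[2], c("FA3", "FA4"))
  ))
  st <- run_initial_stage(coh, cfg_with_targets(c(35000000, 35000100)))
  expect_equal(nrow(st$variants), 0)
  expect_equal(st$audit$n_out[st$audit$stage == "rare_variant"], 0)
})

test_that("post-Sanger survivor set matches the brute-force predicate oracle", {
  sim <- simulate_cohort(fast_sim_config(seed = 11))
  expect_lte(nrow(sim$cohort$variants), 50)
  cfg <- sim_filter_config(sim)
  init <- run_initial_stage(sim$cohort, cfg)
  ver <- verify_variants(sim$sanger, sim$cohort,
                         variant_ids = init$variants$variant_id)
  post <- run_post_sanger_stage(sim$cohort, ver, cfg)

  statuses <- setNames(as.list(ver$status), ver$variant_id)
  interrogated <- sim$cohort$variants |>
    dplyr::filter(variant_id %in% ver$variant_id)
  oracle <- post_stage_oracle(interrogated, statuses, sim$locus,
                              dplyr::filter(sim$targets, exonic))
  expect_setequal(post$variants$variant_id, oracle)
})

test_that("the post-Sanger survivor set is invariant under filter permutation", {
  sim <- simulate_cohort(fast_sim_config(seed = 12))
  cfg <- sim_filter_config(sim)
  init <- run_initial_stage(sim$cohort, cfg)
  ver <- verify_variants(sim$sanger, sim$cohort,
                         variant_ids = init$variants$variant_id)
  v <- sim$cohort$variants |>
    dplyr::filter(variant_id %in%
                    ver$variant_id[ver$status == "fully_verified"])
  preds <- list(
    locus = linked_locus_filter(v, cfg, waive_cgc = FALSE),
    rare = maf_filter(v, cfg$final_maf_threshold_percent),
    exome = targeted_region_filter(v, cfg, mode = "exonic"),
    protein = protein_alteration_filter(v, cfg)
  )
  reference <- run_post_sanger_stage(sim$cohort, ver, cfg)$variants$variant_id
  for (perm in list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3))) {
    keep <- Reduce(`&`, preds[perm])
    expect_setequal(v$variant_id[keep], reference)
  }
})

test_that("the CGC waiver never rescues a variant at the final linked-locus stage", {
  v <- toy_variant(29550000, gene = "NF1")  # outside locus, census gene
  coh <- toy_cohort(v, toy_genotypes(v$variant_id, c("FA3", "FA4")))
  cfg <- filter_config(targets = toy_targets(29550000))
  ver <- tibble::tibble(variant_id = v$variant_id, status = "fully_verified")
  post <- run_post_sanger_stage(coh, ver, cfg)
  expect_equal(nrow(post$variants), 0)
  fate <- st <- tibble::deframe(post$fates)
  expect_equal(unname(fate[v$variant_id]), "linked_locus_final")
})

test_that("retention percentages round half-up to one decimal", {
  audit <- tibble::tibble(stage = c("a", "b", "c", "d"),
                          n_in = c(539L, 278L, 7L, 0L),
                          n_out = c(278L, 186L, 7L, 0L))
  pct <- audit_percentages(audit)$pct_retained
  expect_equal(pct, c(51.6, 66.9, 100.0, NA_real_))
  # half-up at the boundary: 0.05 -> 0.1 (base round() would give 0.0)
  expect_equal(audit_percentages(
    tibble::tibble(stage = "x", n_in = 2000L, n_out = 1L))$pct_retained, 0.1)
})
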