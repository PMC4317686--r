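test_that("identical configurations produce byte-identical output files", {
  cfg <- fast_sim_config(seed = 7)
  d1 <- tempfile()
  d2 <- tempfile()
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # and a different seed changes the output
  d3 <- tempfile()
  write_cohort(simulate_cohort(fast_sim_config(seed = 8)), d3)
  expect_false(identical(readLines(file.path(d1, "cohort.vcf")),
                         readLines(file.path(d3, "cohort.vcf"))))
})

test_that("pedigrees are connected, parent links resolve, affected are blood relatives", {
  ped <- generate_pedigrees(sim_config(n_families = 10, seed = 21))
  expect_silent(glioseg:::validate_pedigree(ped))
  expect_true(all(ped$affected <= ped$blood))  # affected only among blood
  per_fam <- dplyr::count(dplyr::filter(ped, affected), family_id)
  expect_true(all(per_fam$n >= 2))
  expect_equal(nrow(per_fam), 10)
})

test_that("a fixed affected count per family is honoured and infeasible configs fail", {
  ped <- generate_pedigrees(sim_config(n_families = 6, seed = 2,
                                       n_affected_per_family = 2,
                                       pedigree_depth = 2))
  per_fam <- dplyr::count(dplyr::filter(ped, affected), family_id)
  expect_true(all(per_fam$n == 2))
  expect_error(
    generate_pedigrees(sim_config(n_families = 2, seed = 2,
                                  n_affected_per_family = 6,
                                  pedigree_depth = 2)),
    "infeasible")
})

test_that("the two-affected family fraction matches the cohort mixture", {
  ped <- generate_pedigrees(sim_config(n_families = 200, seed = 17))
  n_two <- ped |>
    dplyr::filter(affected) |>
    dplyr::count(family_id) |>
    dplyr::filter(n == 2) |>
    nrow()
  # 99% binomial acceptance band around 0.83 at n = 200
  expect_gte(n_two, qbinom(0.005, 200, 0.83))
  expect_lte(n_two, qbinom(0.995, 200, 0.83))
})

test_that("planted genotypes are Mendelian-consistent over the full map", {
  sim <- simulate_cohort(fast_sim_config(seed = 31))
  ped <- sim$cohort$pedigree
  gt <- sim$genotypes_full
  carriers <- gt |>
    dplyr::filter(is_carrier(call)) |>
    dplyr::left_join(ped, by = "individual_id")
  # brute force over every carrier with known parents: at least one parent
  # carries (the allele enters each family through a parentless founder)
  for (i in seq_len(nrow(carriers))) {
    row <- carriers[i, ]
    parents <- c(row$father_id, row$mother_id)
    parents <- parents[!is.na(parents)]
    if (length(parents) == 0) next  # founder introduction
    parent_calls <- gt$call[gt$variant_id == row$variant_id &
                              gt$individual_id %in% parents]
    expect_true(any(is_carrier(parent_calls)),
                info = paste(row$variant_id, row$individual_id))
  }
  # the restricted cohort genotype map covers sequenced individuals only
  seq_ids <- ped$individual_id[ped$sequenced]
  expect_true(all(sim$cohort$genotypes$individual_id %in% seq_ids))
})

test_that("the truth table assigns exactly one fate per generated variant", {
  cfg <- fast_sim_config(seed = 5)
  sim <- simulate_cohort(cfg)
  expect_equal(anyDuplicated(sim$truth$variant_id), 0)
  expect_setequal(sim$truth$variant_id, sim$cohort$variants$variant_id)
  expect_equal(sum(sim$truth$fate == "passed"), cfg$n_planted_candidates)
})

test_that("each decoy class is dropped at its intended stage", {
  sim <- simulate_cohort(sim_config(seed = 13, n_families = 10,
                                    decoys_per_class = 2,
                                    background_variant_count = 10))
  res <- run_pipeline(sim$cohort, sim$sanger, sim_filter_config(sim))
  fates <- dplyr::bind_rows(res$initial$fates, res$post$fates) |>
    dplyr::filter(fate != "passed") |>
    dplyr::distinct(variant_id, fate)
  observed <- sim$truth |>
    dplyr::left_join(fates, by = "variant_id", suffix = c("_truth", "_obs")) |>
    dplyr::mutate(fate_obs = dplyr::coalesce(fate_obs, "passed"))
  expect_equal(observed$fate_obs, observed$fate_truth)
})

test_that("flipping a decoy's single violating attribute makes it pass", {
  sim <- simulate_cohort(sim_config(seed = 19, n_families = 10,
                                    background_variant_count = 5))
  cfg <- sim_filter_config(sim)
  ped <- sim$cohort$pedigree

  for (class in decoy_classes()) {
    tr <- sim$truth[sim$truth$class == class, ][1, ]
    vid <- tr$variant_id
    variants <- sim$cohort$variants
    genotypes <- sim$cohort$genotypes
    sanger <- sim$sanger

    if (class %in% c("common_freq", "moderate_freq")) {
      variants$esp_pct[variants$variant_id == vid] <- NA_real_
    } else if (class %in% c("off_locus", "off_target")) {
      variants$pos[variants$variant_id == vid] <- tr$compliant_pos
    } else if (class == "synonymous") {
      variants$func[variants$variant_id == vid] <- "missense"
    } else if (class %in% c("non_segregating", "unaffected_only")) {
      aff <- ped$individual_id[ped$family_id == tr$family_id &
                                 ped$affected & ped$sequenced]
      genotypes$call[genotypes$variant_id == vid &
                       genotypes$individual_id %in% aff] <- "carrier-het"
      sanger <- dplyr::bind_rows(
        dplyr::filter(sanger, variant_id != vid),
        tibble::tibble(variant_id = vid, individual_id = aff,
                       fwd = "C", rev = "C"))
    } else {  # sanger_partial, sanger_failed: repair the evidence
      aff <- ped$individual_id[ped$family_id == tr$family_id &
                                 ped$affected & ped$sequenced]
      carriers <- genotypes$individual_id[
        genotypes$variant_id == vid & is_carrier(genotypes$call)]
      fix_ids <- intersect(aff, carriers)
      sanger <- dplyr::bind_rows(
        dplyr::filter(sanger, variant_id != vid),
        tibble::tibble(variant_id = vid, individual_id = fix_ids,
                       fwd = "C", rev = "C"))
    }

    coh <- cohort(ped, variants, genotypes)
    res <- run_pipeline(coh, sanger, cfg)
    expect_true(vid %in% res$candidates$variant_id,
                info = paste("class:", class))
  }
})

test_that("the pipeline recovers the planted truth exactly across seeds", {
  for (seed in 1:20) {
    sim <- simulate_cohort(fast_sim_config(seed = seed))
    res <- run_pipeline(sim$cohort, sim$sanger, sim_filter_config(sim))
    expect_identical(sort(unique(res$candidates$variant_id)),
                     sort(sim$truth$variant_id[sim$truth$fate == "passed"]),
                     info = paste("seed", seed))
  }
})

test_that("written simulations parse back into an identical cohort", {
  sim <- simulate_cohort(fast_sim_config(seed = 42))
  d <- tempfile()
  write_cohort(sim, d)
  rt <- read_simulation(d)
  sort_df <- function(x, ...) as.data.frame(dplyr::arrange(x, ...))
  expect_equal(sort_df(rt$cohort$pedigree, individual_id),
               sort_df(sim$cohort$pedigree, individual_id))
  expect_equal(sort_df(rt$cohort$variants, variant_id),
               sort_df(sim$cohort$variants, variant_id))
  expect_equal(sort_df(rt$cohort$genotypes, variant_id, individual_id),
               sort_df(sim$cohort$genotypes, variant_id, individual_id))
  expect_equal(as.data.frame(rt$targets), as.data.frame(sim$targets))
  expect_equal(as.data.frame(rt$locus), as.data.frame(sim$locus))
  expect_equal(sort_df(rt$sanger, variant_id, individual_id),
               sort_df(sim$sanger, variant_id, individual_id))
  expect_equal(sort_df(rt$truth, variant_id)[, c("variant_id", "class", "fate")],
               sort_df(sim$truth, variant_id)[, c("variant_id", "class", "fate")])

  # and the pipeline run on the re-read files recovers the same truth
  res <- run_pipeline(rt$cohort, rt$sanger,
                      filter_config(linkage_locus = rt$locus,
                                    targets = rt$targets))
  expect_setequal(unique(res$candidates$variant_id),
                  rt$truth$variant_id[rt$truth$fate == "passed"])
})
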