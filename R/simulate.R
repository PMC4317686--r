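# Seeded generator of synthetic multi-family cohorts with the statistical
# structure the triage assumes: connected pedigrees, Mendelian gene drop of
# planted very-rare segregating missense candidates, and decoy variants each
# engineered to violate exactly one filter, plus a truth table recording
# every variant's intended fate.

#' Decoy classes the simulator can plant
#'
#' Each class violates exactly one pipeline predicate and satisfies all the
#' others: `common_freq` (>5% frequency, initial rare-variant filter),
#' `moderate_freq` (0.1-5%, post-Sanger very-rare filter), `off_locus`
#' (outside the linkage locus), `off_target` (inside the locus but beyond
#' the target pad), `non_segregating` (not carried by all sequenced
#' affected of its family), `unaffected_only` (carried only by unaffected
#' members), `synonymous` (no protein alteration), `sanger_partial`
#' (bidirectional concordance in only a subset of affected carriers),
#' `sanger_failed` (no usable Sanger reads).
#'
#' @return Character vector of class names.
#' @export
decoy_classes <- function() {
  c("common_freq", "moderate_freq", "off_locus", "off_target",
    "non_segregating", "unaffected_only", "synonymous", "sanger_partial",
    "sanger_failed")
}

#' Simulation configuration
#'
#' Defaults emulate the study cohort: about twenty multiplex glioma
#' families, 83% with two and 17% with three or more affected members, a
#' high fraction of families with every affected member sequenced
#' (20 of 23), and background variants whose population frequencies mix a
#' point mass at "absent from databases" with a log-uniform spectrum over
#' 0.01-20%.
#'
#' @param n_families Number of families.
#' @param pedigree_depth Generations per pedigree (2-4).
#' @param n_affected_per_family Fixed affected count per family, or `NULL`
#'   (default) to draw from `affected_mixture`.
#' @param affected_mixture Probabilities of 2 vs 3 affected members.
#' @param p_sequenced Probability an unaffected member is sequenced.
#' @param p_family_sequenced_affected Fraction of families whose affected
#'   members are all sequenced; in the remaining families no affected
#'   member is sequenced (specimen unobtainable).
#' @param n_planted_candidates Number of planted passing candidates.
#' @param decoys_per_class Named integer vector (names from
#'   [decoy_classes()]) or a single count applied to every class.
#' @param background_variant_count Number of engineered background
#'   variants (never segregating; see Details in the package vignette).
#' @param p_background_absent Probability a background variant is absent
#'   from all databases.
#' @param background_freq_range Log-uniform support (percent) for
#'   background frequencies.
#' @param seed Integer seed fixing all randomness.
#' @return A `glioseg_sim_config` list.
#' @export
sim_config <- function(n_families = 20,
                       pedigree_depth = 3,
                       n_affected_per_family = NULL,
                       affected_mixture = c("2" = 0.83, "3" = 0.17),
                       p_sequenced = 0.6,
                       p_family_sequenced_affected = 20 / 23,
                       n_planted_candidates = 10,
                       decoys_per_class = 1,
                       background_variant_count = 30,
                       p_background_absent = 0.3,
                       background_freq_range = c(0.01, 20),
                       seed = 1L) {
  stopifnot(n_families >= 1, pedigree_depth %in% 2:4,
            p_sequenced >= 0, p_sequenced <= 1,
            p_family_sequenced_affected >= 0,
            p_family_sequenced_affected <= 1,
            n_planted_candidates >= 0, background_variant_count >= 0,
            abs(sum(affected_mixture) - 1) < 1e-8)
  if (length(decoys_per_class) == 1 && is.null(names(decoys_per_class))) {
    decoys_per_class <- setNames(rep(as.integer(decoys_per_class),
                                     length(decoy_classes())),
                                 decoy_classes())
  } else {
    bad <- setdiff(names(decoys_per_class), decoy_classes())
    if (length(bad) > 0) {
      abort(paste0("unknown decoy class: ", paste(bad, collapse = ", ")))
    }
    full <- setNames(rep(0L, length(decoy_classes())), decoy_classes())
    full[names(decoys_per_class)] <- as.integer(decoys_per_class)
    decoys_per_class <- full
  }
  if (!is.null(n_affected_per_family) && n_affected_per_family < 1) {
    abort("n_affected_per_family must be >= 1")
  }
  structure(
    list(n_families = n_families, pedigree_depth = pedigree_depth,
         n_affected_per_family = n_affected_per_family,
         affected_mixture = affected_mixture, p_sequenced = p_sequenced,
         p_family_sequenced_affected = p_family_sequenced_affected,
         n_planted_candidates = n_planted_candidates,
         decoys_per_class = decoys_per_class,
         background_variant_count = background_variant_count,
         p_background_absent = p_background_absent,
         background_freq_range = background_freq_range,
         seed = as.integer(seed)),
    class = "glioseg_sim_config"
  )
}

with_sim_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate synthetic pedigrees
#'
#' Each family is a connected pedigree descending from one founder couple
#' (with married-in spouses from `pedigree_depth` 3 up): affected statuses
#' are assigned to blood relatives only, and sequencing flags follow the
#' configuration (all affected sequenced in a
#' `p_family_sequenced_affected` fraction of families, none otherwise;
#' unaffected members sequenced independently with `p_sequenced`).
#'
#' @param cfg A [sim_config()].
#' @return A pedigree tibble (see [read_pedigree()]) with an extra logical
#'   `blood` column marking descendants of the founder couple.
#' @export
generate_pedigrees <- function(cfg) {
  with_sim_seed(cfg$seed, {
    fams <- map(seq_len(cfg$n_families), function(i) {
      make_sim_family(sprintf("FAM%02d", i), cfg)
    })
    list_rbind(fams)
  })
}

make_sim_family <- function(fid, cfg) {
  id <- function(k) sprintf("%s-I%02d", fid, k)
  nxt <- 0L
  new_id <- function() {
    nxt <<- nxt + 1L
    id(nxt)
  }
  rows <- list()
  add <- function(iid, father, mother, sex, blood) {
    rows[[length(rows) + 1L]] <<- tibble(
      family_id = fid, individual_id = iid, father_id = father,
      mother_id = mother, sex = sex, affected = FALSE, sequenced = FALSE,
      histology = NA_character_, age_at_diagnosis = NA_real_, blood = blood
    )
  }
  f1 <- new_id(); add(f1, NA, NA, "male", TRUE)
  f2 <- new_id(); add(f2, NA, NA, "female", TRUE)
  n_ch <- sample(2:3, 1)
  children <- character(n_ch)
  child_sex <- character(n_ch)
  for (k in seq_len(n_ch)) {
    children[k] <- new_id()
    child_sex[k] <- sample(c("male", "female"), 1)
    add(children[k], f1, f2, child_sex[k], TRUE)
  }
  grandchildren <- character()
  if (cfg$pedigree_depth >= 3) {
    for (k in seq_len(n_ch)) {
      if (runif(1) < 0.7) {
        sp <- new_id()
        sp_sex <- if (child_sex[k] == "male") "female" else "male"
        add(sp, NA, NA, sp_sex, FALSE)
        for (g in seq_len(sample(1:2, 1))) {
          gc <- new_id()
          father <- if (child_sex[k] == "male") children[k] else sp
          mother <- if (child_sex[k] == "male") sp else children[k]
          add(gc, father, mother, sample(c("male", "female"), 1), TRUE)
          grandchildren <- c(grandchildren, gc)
        }
      }
    }
  }
  if (cfg$pedigree_depth >= 4 && length(grandchildren) > 0) {
    gch <- grandchildren[1]
    fam_so_far <- list_rbind(rows)
    gch_sex <- fam_so_far$sex[fam_so_far$individual_id == gch]
    sp <- new_id()
    add(sp, NA, NA, if (gch_sex == "male") "female" else "male", FALSE)
    gg <- new_id()
    add(gg, if (gch_sex == "male") gch else sp,
        if (gch_sex == "male") sp else gch,
        sample(c("male", "female"), 1), TRUE)
  }
  fam <- list_rbind(rows)

  blood_ids <- fam$individual_id[fam$blood]
  n_aff <- cfg$n_affected_per_family %||%
    as.integer(sample(names(cfg$affected_mixture), 1,
                      prob = cfg$affected_mixture))
  if (n_aff > length(blood_ids)) {
    abort(sprintf("infeasible config: %d affected in a %d-blood-member family",
                  n_aff, length(blood_ids)))
  }
  aff_ids <- sample(blood_ids, n_aff)
  fam$affected <- fam$individual_id %in% aff_ids
  aff_sequenced <- runif(1) < cfg$p_family_sequenced_affected
  fam$sequenced <- ifelse(fam$affected, aff_sequenced,
                          runif(nrow(fam)) < cfg$p_sequenced)
  fam
}

# path from an individual up to the family's root founder, preferring the
# blood parent at each step; returns ids from the individual to the founder
chain_to_founder <- function(fam, iid) {
  path <- character()
  cur <- iid
  repeat {
    path <- c(path, cur)
    row <- fam[fam$individual_id == cur, ]
    father <- row$father_id
    mother <- row$mother_id
    father_blood <- !is.na(father) &&
      fam$blood[fam$individual_id == father]
    mother_blood <- !is.na(mother) &&
      fam$blood[fam$individual_id == mother]
    cur <- if (father_blood) father else if (mother_blood) mother else NA
    if (is.na(cur)) break
  }
  path
}

sim_locus <- function() linkage_locus_17q()

sim_targets <- function() {
  exonic_starts <- seq(34400000, by = 20000, length.out = 60)
  other_starts <- seq(54700000, by = 20000, length.out = 20)
  bind_rows(
    genomic_intervals("17", exonic_starts, exonic_starts + 199) |>
      mutate(exonic = TRUE),
    genomic_intervals("17", other_starts, other_starts + 199) |>
      mutate(exonic = FALSE)
  )
}

#' Simulate a complete synthetic cohort with truth table
#'
#' Generates pedigrees, drops planted candidate alleles through them
#' Mendelian-consistently (a root founder introduces each allele; every
#' other carrier inherits it along a parent chain), plants one decoy per
#' configured class violating exactly its intended predicate, engineers
#' background variants that never co-segregate, and produces matched
#' Sanger evidence (fully concordant for everything that should verify,
#' partial/failed patterns for the `sanger_*` classes).
#'
#' @param cfg A [sim_config()].
#' @return A `glioseg_sim` list: `cohort` (a [cohort()]; genotypes
#'   restricted to sequenced members), `genotypes_full` (carrier calls over
#'   all members, for Mendelian checks), `targets`, `locus`, `sanger`,
#'   `truth` (tibble: `variant_id`, `class`, `fate`, `family_id`,
#'   `compliant_pos`), and `config`.
#' @export
simulate_cohort <- function(cfg) {
  ped <- generate_pedigrees(cfg)
  with_sim_seed(cfg$seed + 1L, {
    targets <- sim_targets()
    locus <- sim_locus()
    fams <- split(ped, ped$family_id)

    seq_aff_count <- vapply(fams, function(f) sum(f$affected & f$sequenced),
                            integer(1))
    elig1 <- names(fams)[seq_aff_count >= 1]   # candidate planting
    elig2 <- names(fams)[seq_aff_count >= 2]   # classes needing >= 2 carriers
    if (length(elig1) == 0) {
      abort("infeasible config: no family has a sequenced affected member")
    }

    exonic <- filter(targets, .data$exonic)
    n_total <- cfg$n_planted_candidates + sum(cfg$decoys_per_class) +
      cfg$background_variant_count
    pos_pool <- sample(unlist(map2(exonic$start, exonic$end,
                                   function(s, e) seq(s + 5, e - 5, by = 7))))
    if (n_total > length(pos_pool)) abort("infeasible config: too many variants")

    alleles <- c("A", "C", "G", "T")
    idx <- 0L
    plan <- list()
    add_variant <- function(class, fate, family_id, pos, esp_pct, func,
                            novel = FALSE, compliant_pos = NA_real_) {
      idx <<- idx + 1L
      ref <- sample(alleles, 1)
      alt <- sample(setdiff(alleles, ref), 1)
      plan[[idx]] <<- list(
        class = class, fate = fate, family_id = family_id, pos = pos,
        ref = ref, alt = alt, gene = sprintf("GENE%04d", idx),
        func = func, esp_pct = esp_pct,
        dbsnp = if (novel) NA_character_ else sprintf("rs%07d", idx),
        cadd = round(runif(1, 5, 35), 1),
        compliant_pos = compliant_pos
      )
    }
    take_pos <- function() {
      p <- pos_pool[1]
      pos_pool <<- pos_pool[-1]
      p
    }

    for (k in seq_len(cfg$n_planted_candidates)) {
      novel <- runif(1) < 0.4
      add_variant("candidate", "passed", sample(elig1, 1), take_pos(),
                  esp_pct = if (novel) NA_real_ else
                    signif(runif(1, 0.001, 0.09), 2),
                  func = "missense", novel = novel)
    }
    for (class in decoy_classes()) {
      for (k in seq_len(cfg$decoys_per_class[[class]])) {
        fam <- switch(class,
          non_segregating = ,
          sanger_partial = {
            if (length(elig2) == 0) {
              abort(paste0("infeasible config: class ", class,
                           " needs a family with >= 2 sequenced affected"))
            }
            sample(elig2, 1)
          },
          sample(elig1, 1)
        )
        pos <- switch(class,
          off_locus = round(runif(1, 20e6, 34e6)),
          off_target = round(runif(1, 40e6, 45e6)),
          take_pos()
        )
        add_variant(
          class,
          fate = switch(class,
            common_freq = "rare_variant",
            moderate_freq = "very_rare_variant",
            off_locus = "linked_locus",
            off_target = "targeted_region",
            non_segregating = "family_segregation",
            unaffected_only = "family_segregation",
            synonymous = "protein_alteration",
            sanger_partial = "sanger_verified",
            sanger_failed = "sanger_verified"
          ),
          family_id = fam, pos = pos,
          esp_pct = switch(class,
            common_freq = signif(runif(1, 6, 30), 2),
            moderate_freq = signif(runif(1, 0.2, 4), 2),
            signif(runif(1, 0.001, 0.09), 2)
          ),
          func = if (class == "synonymous") "synonymous" else "missense",
          compliant_pos = if (class %in% c("off_locus", "off_target")) {
            p <- take_pos()
            p
          } else NA_real_
        )
      }
    }
    for (k in seq_len(cfg$background_variant_count)) {
      absent <- runif(1) < cfg$p_background_absent
      esp <- if (absent) NA_real_ else {
        r <- cfg$background_freq_range
        signif(10^runif(1, log10(r[1]), log10(r[2])), 2)
      }
      fate <- if (!is.na(esp) && esp > 5) "rare_variant"
              else "family_segregation"
      add_variant("background", fate, sample(names(fams), 1), take_pos(),
                  esp_pct = esp,
                  func = sample(c("missense", "synonymous", "intronic"), 1),
                  novel = absent)
    }

    built <- map(plan, function(p) {
      build_sim_variant(p, fams[[p$family_id]], ped)
    })
    variants <- list_rbind(map(built, "variant"))
    genotypes_full <- list_rbind(map(built, "genotypes"))
    truth <- list_rbind(map(built, "truth"))

    seq_ids <- ped$individual_id[ped$sequenced]
    genotypes <- filter(genotypes_full, .data$individual_id %in% seq_ids)
    coh <- cohort(select(ped, -"blood"), variants, genotypes)
    sanger <- sim_sanger(truth, coh)

    structure(
      list(cohort = coh, genotypes_full = genotypes_full, targets = targets,
           locus = locus, sanger = sanger, truth = truth, config = cfg),
      class = "glioseg_sim"
    )
  })
}

# carrier set for one planned variant; returns variant/genotype/truth rows
build_sim_variant <- function(p, fam, ped) {
  vid <- variant_key("17", p$pos, p$ref, p$alt)
  seq_aff <- fam$individual_id[fam$affected & fam$sequenced]
  carriers <- switch(
    p$class,
    non_segregating = {
      # exclude one sequenced affected who is not an ancestor of another
      # (a pedigree "leaf" among the affected), so the chain union of the
      # rest cannot cover everyone
      chains <- map(seq_aff, function(s) chain_to_founder(fam, s))
      names(chains) <- seq_aff
      is_anc <- vapply(seq_aff, function(s) {
        s %in% unlist(chains[setdiff(seq_aff, s)])
      }, logical(1))
      excluded <- seq_aff[!is_anc][1]
      unique(unlist(chains[setdiff(seq_aff, excluded)]))
    },
    unaffected_only = {
      # a single founder introduction with no transmission: a married-in
      # spouse, or an unaffected root founder (both parentless)
      spouses <- fam$individual_id[!fam$blood]
      seq_spouses <- intersect(spouses,
                               fam$individual_id[fam$sequenced])
      founders <- fam$individual_id[fam$blood & is.na(fam$father_id) &
                                      !fam$affected]
      if (length(seq_spouses) > 0) seq_spouses[1]
      else if (length(spouses) > 0) spouses[1]
      else if (length(founders) > 0) founders[1]
      else character()
    },
    background = {
      # drop from the founder, then truncate every chain at the first
      # sequenced affected member so no family can segregate it
      n_pick <- min(2L, nrow(fam))
      picks <- sample(fam$individual_id[fam$blood], n_pick)
      chains <- map(picks, function(s) {
        ch <- rev(chain_to_founder(fam, s))  # founder ... target
        stop_at <- which(ch %in% seq_aff)
        if (length(stop_at) > 0) ch <- ch[seq_len(stop_at[1] - 1L)]
        ch
      })
      unique(unlist(chains))
    },
    {
      # candidate-like: every sequenced affected member carries
      chains <- map(seq_aff, function(s) chain_to_founder(fam, s))
      unique(unlist(chains))
    }
  )
  genotypes <- tibble(
    variant_id = vid,
    individual_id = ped$individual_id,
    call = ifelse(ped$individual_id %in% carriers, "carrier-het",
                  "non-carrier")
  )
  list(
    variant = tibble(
      variant_id = vid, chrom = "17", pos = p$pos, ref = p$ref, alt = p$alt,
      gene = p$gene, func = p$func, dbsnp = p$dbsnp, esp_pct = p$esp_pct,
      kg_pct = NA_real_, kg_ceu_pct = NA_real_, cadd_scaled = p$cadd
    ),
    genotypes = genotypes,
    truth = tibble(
      variant_id = vid, class = p$class, fate = p$fate,
      family_id = p$family_id, compliant_pos = p$compliant_pos
    )
  )
}

# Sanger evidence consistent with the truth table: full bidirectional
# concordance for every variant that should verify, a missing reverse read
# for one carrier of sanger_partial decoys, no usable reads for
# sanger_failed decoys
sim_sanger <- function(truth, coh) {
  expected <- coh$genotypes |>
    filter(is_carrier(.data$call)) |>
    semi_join(filter(coh$pedigree, .data$affected, .data$sequenced),
              by = "individual_id") |>
    select("variant_id", "individual_id") |>
    left_join(select(truth, "variant_id", "class"), by = "variant_id") |>
    arrange(.data$variant_id, .data$individual_id)
  expected |>
    mutate(i = dplyr::row_number(), .by = "variant_id") |>
    mutate(
      fwd = ifelse(.data$class == "sanger_failed", "N", "C"),
      rev = case_when(
        .data$class == "sanger_failed" ~ "N",
        .data$class == "sanger_partial" & .data$i == 1 ~ "N",
        .default = "C"
      )
    ) |>
    select("variant_id", "individual_id", "fwd", "rev")
}

#' @export
print.glioseg_sim <- function(x, ...) {
  cat(sprintf("<glioseg_sim> seed %d: ", x$config$seed))
  print(x$cohort)
  cat(sprintf("truth: %d passing, %d decoy, %d background variant(s)\n",
              sum(x$truth$class == "candidate"),
              sum(!x$truth$class %in% c("candidate", "background")),
              sum(x$truth$class == "background")))
  invisible(x)
}

#' Filter configuration matching a simulated cohort
#'
#' @param sim A `glioseg_sim`.
#' @return A [filter_config()] using the simulation's locus and targets.
#' @export
sim_filter_config <- function(sim) {
  filter_config(linkage_locus = sim$locus, targets = sim$targets)
}

#' Write a simulated cohort to disk
#'
#' Writes `cohort.ped`, `cohort.vcf`, `annotations.tsv`, `sanger.tsv`,
#' `targets.bed`, `linkage.bed` and `truth.json` into `dir`. The files
#' parse back through the package readers (see [read_simulation()]) into
#' an identical cohort.
#'
#' @param sim A `glioseg_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "glioseg_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_files(sim$cohort, dir)
  write_sanger(sim$sanger, file.path(dir, "sanger.tsv"))
  write_intervals(sim$targets, file.path(dir, "targets.bed"))
  write_intervals(sim$locus, file.path(dir, "linkage.bed"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  invisible(dir)
}

#' Read a simulated cohort back from disk
#'
#' @param dir Directory written by [write_cohort()].
#' @return A list with `cohort`, `targets`, `locus`, `sanger`, `truth`.
#' @export
read_simulation <- function(dir) {
  coh <- read_cohort(dir)
  truth <- as_tibble(jsonlite::read_json(file.path(dir, "truth.json"),
                                         simplifyVector = TRUE))
  if (!"compliant_pos" %in% names(truth)) truth$compliant_pos <- NA_real_
  list(
    cohort = coh,
    targets = read_targets(file.path(dir, "targets.bed")),
    locus = read_intervals(file.path(dir, "linkage.bed")),
    sanger = read_sanger(file.path(dir, "sanger.tsv")),
    truth = truth
  )
}
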