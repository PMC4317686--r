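#' Read a pedigree/phenotype file
#'
#' Reads a tab-delimited PED-dialect file with the six standard columns
#' (family, individual, father, mother, sex, phenotype) plus three extension
#' columns: sequenced flag (0/1), histology label, and age at diagnosis.
#' `0` in a parent column means unknown. Phenotype is coded 2 = affected,
#' 1 = unaffected, 0/-9 = unknown; unknown is treated as unaffected for all
#' downstream filtering (the filters reference only affected/unaffected
#' strata).
#'
#' @param path Path to the PED file.
#' @return A tibble with one row per individual: `family_id`,
#'   `individual_id`, `father_id`, `mother_id` (NA when unknown), `sex`
#'   (`"male"`, `"female"`, `"unknown"`), `affected`, `sequenced` (logical),
#'   `histology`, `age_at_diagnosis`.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) abort(paste0("pedigree file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_pedigree())
  rows <- map(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6) {
      abort(sprintf("malformed pedigree line %d: %d column(s), need >= 6",
                    i, length(f)))
    }
    pheno <- suppressWarnings(as.numeric(f[6]))
    if (is.na(pheno) || !pheno %in% c(-9, 0, 1, 2)) {
      abort(sprintf("malformed pedigree line %d: bad phenotype code %s",
                    i, encodeString(f[6], quote = "'")))
    }
    tibble(
      family_id = f[1],
      individual_id = f[2],
      father_id = if (f[3] == "0") NA_character_ else f[3],
      mother_id = if (f[4] == "0") NA_character_ else f[4],
      sex = c("1" = "male", "2" = "female")[f[5]] %|na|% "unknown",
      affected = pheno == 2,
      sequenced = length(f) >= 7 && f[7] == "1",
      histology = if (length(f) >= 8 && nzchar(f[8])) f[8] else NA_character_,
      age_at_diagnosis = if (length(f) >= 9)
        suppressWarnings(as.numeric(f[9])) else NA_real_
    )
  })
  ped <- list_rbind(rows)
  validate_pedigree(ped)
  ped
}

`%|na|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else unname(x)

empty_pedigree <- function() {
  tibble(
    family_id = character(), individual_id = character(),
    father_id = character(), mother_id = character(),
    sex = character(), affected = logical(), sequenced = logical(),
    histology = character(), age_at_diagnosis = numeric()
  )
}

validate_pedigree <- function(ped) {
  dup <- ped |>
    count(.data$family_id, .data$individual_id) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicated individual within family: ",
                 paste(dup$individual_id, collapse = ", ")))
  }
  for (fam in split(ped, ped$family_id)) {
    parents <- stats::na.omit(c(fam$father_id, fam$mother_id))
    missing <- setdiff(parents, fam$individual_id)
    if (length(missing) > 0) {
      abort(paste0("parent ID not found in family ", fam$family_id[1], ": ",
                   paste(unique(missing), collapse = ", ")))
    }
  }
  invisible(ped)
}

#' Write a pedigree tibble to a PED file
#'
#' Inverse of [read_pedigree()].
#'
#' @param pedigree Pedigree tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  lines <- pedigree |>
    mutate(
      father = coalesce(.data$father_id, "0"),
      mother = coalesce(.data$mother_id, "0"),
      sexcode = case_match(.data$sex, "male" ~ "1", "female" ~ "2",
                           .default = "0"),
      pheno = ifelse(.data$affected, "2", "1"),
      seq = ifelse(.data$sequenced, "1", "0"),
      hist = coalesce(.data$histology, ""),
      age = ifelse(is.na(.data$age_at_diagnosis), "",
                   format(.data$age_at_diagnosis, trim = TRUE))
    ) |>
    mutate(line = paste(.data$family_id, .data$individual_id, .data$father,
                        .data$mother, .data$sexcode, .data$pheno, .data$seq,
                        .data$hist, .data$age, sep = "\t")) |>
    pull(.data$line)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Packaged Gliogene affected-member pedigree
#'
#' The 20-family pedigree of histologically confirmed glioma cases
#' (relationship, histology, age at diagnosis, sex, sequenced flag) shipped
#' with the package. Only the parent links stated directly by the published
#' relationships are encoded; more distant affected relatives appear as
#' founders within their family.
#'
#' @return A pedigree tibble (see [read_pedigree()]).
#' @export
gliogene_pedigree <- function() {
  read_pedigree(system.file("extdata", "gliogene_affected.ped",
                            package = "glioseg", mustWork = TRUE))
}
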