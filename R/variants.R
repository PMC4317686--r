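# Annotated variants and per-sample genotype calls.
#
# A variant table has one row per (position, alt allele):
#   variant_id chrom pos ref alt gene func dbsnp esp_pct kg_pct kg_ceu_pct
#   cadd_scaled
# Frequencies are percentages in [0, 100]. A genotype table has one row per
# (variant, sequenced individual) with call in
# {carrier-het, carrier-hom, non-carrier, missing}.

#' Functional classes counted as protein-altering
#' @export
protein_altering_classes <- function() {
  c("missense", "nonsense", "frameshift", "splice")
}

functional_classes <- function() {
  c(protein_altering_classes(),
    "synonymous", "UTR", "intronic", "intergenic", "other-noncoding")
}

genotype_calls <- function() {
  c("carrier-het", "carrier-hom", "non-carrier", "missing")
}

#' Variant identity key
#'
#' @param chrom,pos,ref,alt Variant coordinates and alleles.
#' @return `"chrom:pos:ref:alt"` character keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(norm_chrom(as.character(chrom)), as.integer(pos), ref, alt, sep = ":")
}

#' Is a genotype call a carrier call?
#'
#' Heterozygous and homozygous alternate calls both count as carriers;
#' the triage never distinguishes zygosity.
#'
#' @param call Character vector of genotype calls.
#' @return Logical vector.
#' @export
is_carrier <- function(call) {
  call %in% c("carrier-het", "carrier-hom")
}

empty_variants <- function() {
  tibble(
    variant_id = character(), chrom = character(), pos = numeric(),
    ref = character(), alt = character(), gene = character(),
    func = character(), dbsnp = character(), esp_pct = numeric(),
    kg_pct = numeric(), kg_ceu_pct = numeric(), cadd_scaled = numeric()
  )
}

empty_genotypes <- function() {
  tibble(variant_id = character(), individual_id = character(),
         call = character())
}

#' Read variants and genotypes from a VCF plus an annotation table
#'
#' Multi-allelic VCF records are decomposed into one variant per ALT allele
#' (the filters are per-allele: frequencies, protein effect). Per-sample GT
#' fields become genotype calls; a genotype carrying the allele on one
#' haplotype is `carrier-het`, on both `carrier-hom`, `./.` is `missing`.
#' The annotation table is joined on (chrom, pos, ref, alt); variants with
#' no annotation row keep their optional fields unset.
#'
#' @param vcf_path Path to a VCF 4.x file with per-sample GT.
#' @param annotation_path Optional path to a tab-separated annotation table
#'   with header `chrom pos ref alt gene func dbsnp esp_pct kg_pct
#'   kg_ceu_pct cadd_scaled`.
#' @param pedigree Optional pedigree tibble; when given, every VCF sample
#'   must be a sequenced individual of the pedigree.
#' @return A list with elements `variants` and `genotypes` (tibbles).
#' @export
read_variants <- function(vcf_path, annotation_path = NULL, pedigree = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCFs drop to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(list(variants = empty_variants(), genotypes = empty_genotypes()))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt) %||% character()
  if (!is.null(pedigree) && length(samples) > 0) {
    seq_ids <- pedigree$individual_id[pedigree$sequenced]
    unknown <- setdiff(samples, pedigree$individual_id)
    if (length(unknown) > 0) {
      abort(paste0("VCF sample(s) absent from pedigree: ",
                   paste(unknown, collapse = ", ")))
    }
    unseq <- setdiff(samples, seq_ids)
    if (length(unseq) > 0) {
      abort(paste0("VCF sample(s) not flagged as sequenced: ",
                   paste(unseq, collapse = ", ")))
    }
  }

  recs <- map(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    map(seq_along(alts), function(k) {
      vid <- variant_key(fix$CHROM[i], as.numeric(fix$POS[i]),
                         fix$REF[i], alts[k])
      calls <- if (length(samples) > 0) {
        vapply(gt[i, , drop = TRUE], classify_gt, character(1),
               alt_index = k, USE.NAMES = FALSE)
      } else {
        character()
      }
      list(
        variant = tibble(
          variant_id = vid, chrom = norm_chrom(fix$CHROM[i]),
          pos = as.numeric(fix$POS[i]), ref = fix$REF[i], alt = alts[k]
        ),
        genotypes = tibble(variant_id = vid, individual_id = samples,
                           call = calls)
      )
    })
  })
  recs <- purrr::flatten(recs)
  variants <- list_rbind(map(recs, "variant"))
  genotypes <- list_rbind(map(recs, "genotypes"))
  variants <- join_annotations(variants, annotation_path)
  list(variants = variants, genotypes = genotypes)
}

# one GT string -> call, for the k-th ALT allele of its record
classify_gt <- function(gt, alt_index) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return("missing")
  n_alt <- sum(alleles == as.character(alt_index))
  if (n_alt >= 2) "carrier-hom" else if (n_alt == 1) "carrier-het"
  else "non-carrier"
}

join_annotations <- function(variants, annotation_path) {
  base <- variants |>
    mutate(gene = NA_character_, func = NA_character_, dbsnp = NA_character_,
           esp_pct = NA_real_, kg_pct = NA_real_, kg_ceu_pct = NA_real_,
           cadd_scaled = NA_real_)
  if (is.null(annotation_path)) return(base)
  ann <- readr::read_tsv(
    annotation_path, show_col_types = FALSE,
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_double(),
      ref = readr::col_character(), alt = readr::col_character(),
      gene = readr::col_character(), func = readr::col_character(),
      dbsnp = readr::col_character(), esp_pct = readr::col_double(),
      kg_pct = readr::col_double(), kg_ceu_pct = readr::col_double(),
      cadd_scaled = readr::col_double()
    )
  ) |>
    mutate(variant_id = variant_key(.data$chrom, .data$pos, .data$ref,
                                    .data$alt)) |>
    select("variant_id", "gene", "func", "dbsnp", "esp_pct", "kg_pct",
           "kg_ceu_pct", "cadd_scaled")
  if (anyDuplicated(ann$variant_id)) {
    abort("annotation key collision: duplicated (chrom, pos, ref, alt)")
  }
  variants |>
    left_join(ann, by = "variant_id")
}

validate_variants <- function(variants) {
  if (any(variants$pos < 1)) abort("variant positions must be >= 1")
  if (any(variants$ref == variants$alt)) {
    abort("variant ref and alt alleles must differ")
  }
  for (col in c("esp_pct", "kg_pct", "kg_ceu_pct")) {
    v <- variants[[col]]
    if (any(!is.na(v) & (v < 0 | v > 100))) {
      abort(paste0("population frequencies must be percentages in [0, 100]: ",
                   col))
    }
  }
  cs <- variants$cadd_scaled
  if (any(!is.na(cs) & cs < 0)) abort("scaled C-scores must be >= 0")
  bad <- !is.na(variants$func) & !variants$func %in% functional_classes()
  if (any(bad)) {
    abort(paste0("unknown functional class: ",
                 paste(unique(variants$func[bad]), collapse = ", ")))
  }
  invisible(variants)
}

#' Write variants and genotypes to a VCF file
#'
#' Inverse of [read_variants()]: each variant becomes a bi-allelic VCF 4.2
#' record with per-sample GT (`0/1`, `1/1`, `0/0`, `./.`).
#'
#' @param variants Variant tibble.
#' @param genotypes Genotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes, path) {
  samples <- sort(unique(genotypes$individual_id))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gtmap <- c("carrier-het" = "0/1", "carrier-hom" = "1/1",
             "non-carrier" = "0/0", "missing" = "./.")
  wide <- genotypes |>
    mutate(gt = unname(gtmap[.data$call])) |>
    select("variant_id", "individual_id", "gt") |>
    tidyr::pivot_wider(names_from = "individual_id", values_from = "gt",
                       values_fill = "0/0")
  v <- variants |>
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    left_join(wide, by = "variant_id")
  body <- vapply(seq_len(nrow(v)), function(i) {
    gts <- if (length(samples) > 0) {
      unlist(v[i, samples], use.names = FALSE)
    } else {
      character()
    }
    gts[is.na(gts)] <- "0/0"
    paste(c(paste0("chr", v$chrom[i]), format(v$pos[i], scientific = FALSE,
                                              trim = TRUE),
            ".", v$ref[i], v$alt[i], ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, character(1))
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Write a variant annotation table
#'
#' Inverse of the annotation join in [read_variants()].
#'
#' @param variants Variant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(variants, path) {
  variants |>
    select("chrom", "pos", "ref", "alt", "gene", "func", "dbsnp",
           "esp_pct", "kg_pct", "kg_ceu_pct", "cadd_scaled") |>
    readr::write_tsv(path)
  invisible(path)
}
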