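#' Genomic intervals as a tibble
#'
#' Intervals are kept as plain tibbles with columns `chrom`, `start`, `end`,
#' 1-based with closed (inclusive) endpoints — the convention in which VCF
#' positions and the published linkage-locus boundaries are written.
#' Chromosome labels are normalised by stripping a leading `"chr"`, so
#' `"chr17"` and `"17"` refer to the same sequence.
#'
#' @param chrom Character vector of chromosome labels.
#' @param start,end Integer vectors of 1-based inclusive positions.
#' @return A tibble with columns `chrom`, `start`, `end`, sorted by
#'   chromosome then start.
#' @examples
#' genomic_intervals("17", 34355567, 52135011)
#' @export
genomic_intervals <- function(chrom, start, end) {
  x <- tibble(
    chrom = norm_chrom(as.character(chrom)),
    start = as.numeric(start),
    end   = as.numeric(end)
  )
  validate_intervals(x)
  arrange(x, .data$chrom, .data$start)
}

norm_chrom <- function(x) sub("^chr", "", x)

validate_intervals <- function(x) {
  if (any(is.na(x$chrom) | x$chrom == "")) {
    abort("interval chromosome labels must be non-empty")
  }
  if (any(x$start < 1)) abort("interval start positions must be >= 1")
  if (any(x$end < x$start)) abort("interval end must be >= start")
  invisible(x)
}

#' The chromosome 17q familial-glioma linkage locus
#'
#' The two adjacent 1.7-LOD-drop intervals on chromosome 17q
#' (GRCh37: 34,355,567-52,135,011 and 54,612,056-61,596,548) used as the
#' default positional gate for the linked-locus filter.
#'
#' @return A tibble of two intervals (see [genomic_intervals()]).
#' @export
linkage_locus_17q <- function() {
  genomic_intervals(
    chrom = c("17", "17"),
    start = c(34355567, 54612056),
    end   = c(52135011, 61596548)
  )
}

#' Read intervals from a BED file
#'
#' BED records are 0-based half-open; they are converted on read to the
#' package's 1-based inclusive convention (`start + 1`, `end`). Overlapping
#' or bookended records on the same chromosome are merged into one interval.
#'
#' @param path Path to a BED file (3+ columns).
#' @param merge Merge overlapping/adjacent records (default `TRUE`).
#' @return A tibble of intervals (see [genomic_intervals()]).
#' @export
read_intervals <- function(path, merge = TRUE) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0) {
    return(genomic_intervals(character(), numeric(), numeric()))
  }
  if (merge) gr <- GenomicRanges::reduce(gr)
  # rtracklayer already converts BED to 1-based closed coordinates
  genomic_intervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end   = GenomicRanges::end(gr)
  )
}

#' Read capture-target intervals with an exonic flag
#'
#' The capture design distinguishes exonic targets (used by the post-Sanger
#' "Targeted Exome" filter) from the full padded target set (used by the
#' initial "Targeted Region" filter). The flag is carried in the BED name
#' column: intervals named `exonic` are exonic targets; any other (or
#' missing) name marks a non-exonic target.
#'
#' @param path Path to a BED file whose 4th column flags exonic intervals.
#' @return A tibble with columns `chrom`, `start`, `end`, `exonic` (logical).
#'   Records are merged within each exonic stratum.
#' @export
read_targets <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  exonic = logical()))
  }
  nm <- if (!is.null(gr$name)) gr$name else rep(NA_character_, length(gr))
  exonic <- !is.na(nm) & nm == "exonic"
  parts <- lapply(c(FALSE, TRUE), function(flag) {
    sub <- gr[exonic == flag]
    if (length(sub) == 0) return(NULL)
    sub <- GenomicRanges::reduce(sub)
    tibble(
      chrom = norm_chrom(as.character(GenomicRanges::seqnames(sub))),
      start = as.numeric(GenomicRanges::start(sub)),
      end   = as.numeric(GenomicRanges::end(sub)),
      exonic = flag
    )
  })
  out <- bind_rows(parts)
  validate_intervals(out)
  arrange(out, .data$chrom, .data$start)
}

#' Write intervals to a BED file
#'
#' Inverse of [read_intervals()]/[read_targets()]: converts the package's
#' 1-based closed intervals back to 0-based half-open BED records. If the
#' tibble has an `exonic` column it is written to the BED name column as
#' `exonic`/`target`.
#'
#' @param intervals An interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  name <- if ("exonic" %in% names(intervals)) {
    ifelse(intervals$exonic, "exonic", "target")
  } else {
    rep("target", nrow(intervals))
  }
  lines <- sprintf("chr%s\t%d\t%d\t%s", intervals$chrom,
                   as.integer(intervals$start - 1), as.integer(intervals$end),
                   name)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Test positions for membership in a linkage locus
#'
#' @param pos Numeric vector of 1-based positions.
#' @param locus Interval tibble (default [linkage_locus_17q()]).
#' @param chrom Chromosome label(s) of the positions (default `"17"`).
#' @return Logical vector: `TRUE` where the position falls inside any locus
#'   interval (closed endpoints).
#' @examples
#' in_linkage_locus(c(49098662, 34355566, 53e6))
#' @export
in_linkage_locus <- function(pos, locus = linkage_locus_17q(), chrom = "17") {
  stopifnot(all(pos >= 1))
  chrom <- norm_chrom(rep_len(as.character(chrom), length(pos)))
  map_lgl(seq_along(pos), function(i) {
    any(locus$chrom == chrom[i] & locus$start <= pos[i] & pos[i] <= locus$end)
  })
}

#' Distance from positions to the nearest interval
#'
#' Gap in bases between each position and the closest interval on the same
#' chromosome; 0 for positions inside an interval, `Inf` when no interval
#' shares the chromosome.
#'
#' @inheritParams in_linkage_locus
#' @param intervals Interval tibble.
#' @return Numeric vector of distances.
#' @export
interval_distance <- function(pos, intervals, chrom = "17") {
  chrom <- norm_chrom(rep_len(as.character(chrom), length(pos)))
  map_dbl(seq_along(pos), function(i) {
    iv <- intervals[intervals$chrom == chrom[i], , drop = FALSE]
    if (nrow(iv) == 0) return(Inf)
    min(pmax(0, iv$start - pos[i], pos[i] - iv$end))
  })
}
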