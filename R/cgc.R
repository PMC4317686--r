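#' Load a Cancer Gene Census gene list
#'
#' One gene symbol per line; duplicates are dropped. With no `path` the
#' packaged default is returned: the 23 chromosome 17 genes that were in
#' the Cancer Gene Census at the time of the original analysis. Variants in
#' these genes are exempt from the initial positional filters.
#'
#' @param path Optional path to a plain-text gene list.
#' @return Character vector of unique gene symbols.
#' @examples
#' "NF1" %in% load_cgc_genes()
#' @export
load_cgc_genes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cgc_chr17_genes.txt",
                        package = "glioseg", mustWork = TRUE)
  }
  genes <- readr::read_lines(path)
  genes <- unique(trimws(genes[nzchar(trimws(genes))]))
  if (length(genes) == 0) warn("CGC gene list is empty")
  genes
}
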