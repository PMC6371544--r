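#' Construct and validate a SNP map
#'
#' A SNP map describes the markers shared by all genotype matrices and
#' haplotype panels in an analysis: one row per SNP with its identifier,
#' chromosome label, 1-based physical position and the two observed alleles.
#' By convention `allele1` is the alphabetically lower of the two bases, so
#' that "frequency of allele 1" is defined without reference to a genotyping
#' platform's strand or REF/ALT orientation.
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chrom chromosome label per SNP (autosome numbers plus "X"; the X
#'   chromosome may equivalently be coded with the next integer after the last
#'   autosome, e.g. "30" in a 29-autosome genome).
#' @param pos integer physical position in bp (1-based), strictly increasing
#'   within each chromosome.
#' @param allele1,allele2 single-character alleles; `allele1` must sort
#'   alphabetically before `allele2`.
#' @return A `data.frame` of class `snp_map` with columns
#'   `snp_id`, `chrom`, `pos`, `allele1`, `allele2`.
#' @examples
#' snp_map(paste0("snp", 1:3), chrom = "1", pos = c(100L, 200L, 300L))
#' @export
snp_map <- function(snp_id, chrom, pos, allele1 = "A", allele2 = "C") {
  n <- length(snp_id)
  map <- data.frame(
    snp_id = as.character(snp_id),
    chrom = rep_len(as.character(chrom), n),
    pos = as.integer(pos),
    allele1 = rep_len(as.character(allele1), n),
    allele2 = rep_len(as.character(allele2), n),
    stringsAsFactors = FALSE
  )
  validate_snp_map(map)
  class(map) <- c("snp_map", "data.frame")
  map
}

validate_snp_map <- function(map) {
  stopifnot(all(c("snp_id", "chrom", "pos", "allele1", "allele2") %in% names(map)))
  if (anyDuplicated(map$snp_id)) {
    stop("duplicate snp_id in map: ", map$snp_id[anyDuplicated(map$snp_id)])
  }
  bad <- map$allele1 >= map$allele2
  if (any(bad)) {
    stop(
      "allele1 must be the alphabetically lower allele; offending SNP: ",
      map$snp_id[which(bad)[1]]
    )
  }
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  invisible(map)
}

#' @export
print.snp_map <- function(x, ...) {
  cat(
    "SNP map:", nrow(x), "SNPs on", length(unique(x$chrom)),
    "chromosome(s)\n"
  )
  NextMethod()
}

# row indices of `map` on one chromosome, in map order
chrom_index <- function(map, chrom) which(map$chrom == as.character(chrom))

#' Dosage matrix from a phased haplotype panel
#'
#' Haplotype panels code alleles as 0 = allele1, 1 = allele2; genotype
#' matrices store the dosage of allele1 in \{0, 1, 2\}. Consecutive row pairs
#' of the panel (2i-1, 2i) form individual i, so the allele1 dosage is
#' `2 - (h1 + h2)`.
#'
#' @param panel numeric 0/1 matrix, haplotypes in rows (even count), SNPs in
#'   columns.
#' @param sample_ids optional ids for the resulting individuals.
#' @return integer matrix of allele1 dosages, individuals in rows.
#' @export
panel_to_dosage <- function(panel, sample_ids = NULL) {
  stopifnot(is.matrix(panel), nrow(panel) %% 2 == 0)
  odd <- seq(1L, nrow(panel), by = 2L)
  dos <- 2L - (panel[odd, , drop = FALSE] + panel[odd + 1L, , drop = FALSE])
  storage.mode(dos) <- "integer"
  if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_along(odd))
  rownames(dos) <- sample_ids
  colnames(dos) <- colnames(panel)
  dos
}
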