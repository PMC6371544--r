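#' Per-group allele frequencies and expected heterozygosity
#'
#' For each SNP and group, computes the frequency of allele1 from the
#' non-missing dosages (complete-case denominator), the number of alleles
#' used, and the expected heterozygosity `2 p (1 - p)`. Hemizygous samples
#' (e.g. males on the X chromosome, coded on a 0/1 dosage scale) can be
#' declared via `ploidy` so each contributes one allele.
#'
#' @param geno samples x SNPs dosage matrix of allele1 copies (`NA` missing).
#' @param groups character/factor of group labels, one per sample (named or
#'   in row order of `geno`).
#' @param map optional `snp_map` carried along into the result.
#' @param ploidy integer 1 or 2 per sample (default all 2).
#' @return object of class `freq_table`: list with `groups`, and SNPs x
#'   groups matrices `p`, `n_obs`, `het`; `p` is `NA` (flagged) where a group
#'   has no non-missing call.
#' @examples
#' g <- rbind(a = c(2, 0), b = c(2, 1), c = c(1, 2), d = c(1, 2))
#' ft <- group_frequencies(g, groups = c("I", "I", "I", "I"))
#' ft$p  # 0.75, 0.625
#' @export
group_frequencies <- function(geno, groups, map = NULL, ploidy = NULL) {
  stopifnot(is.matrix(geno))
  if (!is.null(names(groups)) && !is.null(rownames(geno))) {
    groups <- groups[rownames(geno)]
  }
  stopifnot(length(groups) == nrow(geno))
  groups <- as.character(groups)
  if (anyNA(groups)) stop("every analyzed sample must have a group label")
  if (is.null(ploidy)) ploidy <- rep(2L, nrow(geno))
  stopifnot(length(ploidy) == nrow(geno), all(ploidy %in% c(1L, 2L)))

  labs <- unique(groups)
  L <- ncol(geno)
  p <- n_obs <- matrix(NA_real_, nrow = L, ncol = length(labs),
                       dimnames = list(colnames(geno), labs))
  obs <- !is.na(geno)
  for (k in seq_along(labs)) {
    rows <- which(groups == labs[k])
    if (!length(rows)) stop("group ", labs[k], " is empty")
    sub <- geno[rows, , drop = FALSE]
    subobs <- obs[rows, , drop = FALSE]
    cnt1 <- colSums(sub * subobs, na.rm = TRUE)          # allele1 copies
    denom <- colSums(subobs * ploidy[rows])              # alleles observed
    n_obs[, k] <- denom
    p[, k] <- ifelse(denom > 0, cnt1 / denom, NA_real_)
  }
  out <- list(groups = labs, p = p, n_obs = n_obs, het = 2 * p * (1 - p),
              map = map)
  class(out) <- "freq_table"
  out
}

#' Build a frequency table from known allele frequencies
#'
#' Constructs the same object as [group_frequencies()] directly from a
#' matrix of allele1 frequencies — useful when per-group frequencies are
#' available (e.g. published summary tables) but genotypes are not.
#'
#' @param p SNPs x groups matrix of allele1 frequencies (column names are
#'   the group labels).
#' @param map optional `snp_map`.
#' @param n_obs optional SNPs x groups matrix of allele counts.
#' @return object of class `freq_table`.
#' @export
freq_table <- function(p, map = NULL, n_obs = NULL) {
  p <- as.matrix(p)
  if (is.null(colnames(p))) stop("p must have group labels as column names")
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  if (!is.null(map)) stopifnot(nrow(p) == nrow(map))
  out <- list(groups = colnames(p), p = p, n_obs = n_obs,
              het = 2 * p * (1 - p), map = map)
  class(out) <- "freq_table"
  out
}

#' @export
print.freq_table <- function(x, ...) {
  cat("Frequency table:", nrow(x$p), "SNPs x groups {",
      paste(x$groups, collapse = ", "), "}\n")
  invisible(x)
}

new_site_track <- function(values, stat, comparison, map = NULL) {
  out <- list(values = as.numeric(values), stat = stat,
              comparison = comparison, map = map)
  class(out) <- "site_track"
  out
}

#' @export
print.site_track <- function(x, ...) {
  cat("Per-SNP", x$stat, "track:", length(x$values), "SNPs, comparison",
      paste(x$comparison, collapse = " vs "), "\n")
  invisible(x)
}

check_groups <- function(freqs, ...) {
  for (g in c(...)) {
    if (!g %in% freqs$groups) stop("group ", g, " not in frequency table")
  }
}

#' Allele frequency difference (AFD) track
#'
#' `AFD_i = |p_A - p_B|` per SNP: the absolute difference in allele1
#' frequency between two groups. Symmetric in group order. SNPs with an
#' undefined frequency in either group are flagged `NA`.
#'
#' @param freqs a [group_frequencies()] result.
#' @param group_a,group_b group labels.
#' @return `site_track` with `stat = "AFD"`, values in \[0, 1\].
#' @export
afd <- function(freqs, group_a, group_b) {
  check_groups(freqs, group_a, group_b)
  new_site_track(abs(freqs$p[, group_a] - freqs$p[, group_b]),
                 "AFD", c(group_a, group_b), freqs$map)
}

#' Heterozygosity difference (HD) track
#'
#' `HD_i = het_A - het_B` per SNP (expected heterozygosity of the
#' first-listed group minus the second's). Signed and antisymmetric:
#' swapping the groups negates the track.
#'
#' @inheritParams afd
#' @return `site_track` with `stat = "HD"`, values in \[-0.5, 0.5\].
#' @export
hd <- function(freqs, group_a, group_b) {
  check_groups(freqs, group_a, group_b)
  new_site_track(freqs$het[, group_a] - freqs$het[, group_b],
                 "HD", c(group_a, group_b), freqs$map)
}

#' SNP mask by minimum allele frequency difference
#'
#' Inclusive threshold: keeps SNPs with `AFD >= min_afd`.
#'
#' @inheritParams afd
#' @param min_afd threshold in \[0, 1\].
#' @return logical vector; `NA`-valued AFD yields `FALSE`.
#' @export
afd_filter <- function(freqs, group_a, group_b, min_afd) {
  stopifnot(min_afd >= 0, min_afd <= 1)
  v <- afd(freqs, group_a, group_b)$values
  !is.na(v) & v >= min_afd
}

#' Calibrate a random-AFD threshold from a within-cohort split
#'
#' The AFD between two disjoint subsets of one cohort measures allele
#' frequency differences that arise without any systematic selection
#' contrast ("random AFD", e.g. between contemporaries kept at different
#' facilities but bred to the same goals). The maximum of that empirical
#' distribution, rounded to the nearest 0.01, is a conservative threshold
#' above which between-cohort AFD is unlikely to be random.
#'
#' @param geno dosage matrix containing all samples of the cohort.
#' @param subset_a,subset_b disjoint, non-empty character vectors of sample
#'   ids (rownames of `geno`) defining the split.
#' @return list with `afd` (the full random-AFD distribution), `max`, and
#'   `threshold` (max rounded to 2 decimals).
#' @export
calibrate_random_afd <- function(geno, subset_a, subset_b) {
  stopifnot(length(subset_a) > 0, length(subset_b) > 0)
  if (length(intersect(subset_a, subset_b))) {
    stop("split subsets must be disjoint")
  }
  missing_ids <- setdiff(c(subset_a, subset_b), rownames(geno))
  if (length(missing_ids)) stop("unknown sample id(s): ",
                                paste(utils::head(missing_ids, 3), collapse = ", "))
  sub <- geno[c(subset_a, subset_b), , drop = FALSE]
  grp <- c(rep("a", length(subset_a)), rep("b", length(subset_b)))
  ft <- group_frequencies(sub, grp)
  v <- afd(ft, "a", "b")$values
  mx <- max(v, na.rm = TRUE)
  list(afd = v, max = mx, threshold = round(mx, 2))
}

#' Direction-consistent allele frequency change across three cohorts
#'
#' Keeps SNPs whose allele frequency moved in the same direction in both
#' selection phases (`sign(p_II - p_I) == sign(p_III - p_II)`, ties treated
#' as inconsistent) and whose overall change `|p_III - p_I|` reaches
#' `min_afd`. Such SNPs are unlikely to reflect drift alone.
#'
#' @param freqs a [group_frequencies()] result.
#' @param g1,g2,g3 labels of the serial cohorts in time order.
#' @param min_afd overall AFD threshold (inclusive; default the calibrated
#'   0.10).
#' @return list with `mask` (logical per SNP), `count`, and `fraction` of all
#'   SNPs.
#' @export
direction_consistent <- function(freqs, g1, g2, g3, min_afd = 0.10) {
  check_groups(freqs, g1, g2, g3)
  d1 <- freqs$p[, g2] - freqs$p[, g1]
  d2 <- freqs$p[, g3] - freqs$p[, g2]
  tot <- abs(freqs$p[, g3] - freqs$p[, g1])
  mask <- !is.na(d1) & !is.na(d2) &
    sign(d1) == sign(d2) & sign(d1) != 0 & tot >= min_afd
  list(mask = mask, count = sum(mask), fraction = mean(mask))
}

#' Fraction of the genome above AFD thresholds
#'
#' @inheritParams afd
#' @param thresholds numeric vector of AFD thresholds (inclusive).
#' @return data.frame with `threshold`, `count`, `fraction` (of SNPs with a
#'   defined AFD).
#' @export
genome_fraction <- function(freqs, group_a, group_b, thresholds = 0.10) {
  v <- afd(freqs, group_a, group_b)$values
  v <- v[!is.na(v)]
  data.frame(
    threshold = thresholds,
    count = vapply(thresholds, function(t) sum(v >= t), 1L),
    fraction = vapply(thresholds, function(t) mean(v >= t), 1)
  )
}
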