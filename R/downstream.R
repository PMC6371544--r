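#' Identity-by-state distance matrix
#'
#' Allele-sharing distance between individuals from dosage data:
#' `IBS(a, b) = mean over co-observed SNPs of (2 - |d_a - d_b|) / 2`, and the
#' distance is `1 - IBS`. Pairs with zero co-observed SNPs are flagged `NA`.
#'
#' @param geno samples x SNPs dosage matrix (allele1 copies, `NA` missing).
#' @return symmetric matrix of class `ibs_dist` with zero diagonal, values in
#'   \[0, 1\].
#' @export
ibs_distances <- function(geno) {
  stopifnot(is.matrix(geno), nrow(geno) >= 2L)
  obs <- !is.na(geno)
  all_missing <- rowSums(obs) == 0L
  if (any(all_missing)) {
    stop("sample(s) with all genotypes missing: ",
         paste(rownames(geno)[all_missing], collapse = ", "))
  }
  # sum |d_a - d_b| over co-observed SNPs via dosage-class indicators:
  # |diff| = 1 for {0,1} and {1,2} pairs, 2 for {0,2} pairs
  I0 <- (geno == 0L) & obs; I1 <- (geno == 1L) & obs; I2 <- (geno == 2L) & obs
  I0[is.na(I0)] <- FALSE; I1[is.na(I1)] <- FALSE; I2[is.na(I2)] <- FALSE
  mode(I0) <- mode(I1) <- mode(I2) <- "numeric"
  s01 <- tcrossprod(I0, I1); s12 <- tcrossprod(I1, I2); s02 <- tcrossprod(I0, I2)
  absdiff <- s01 + t(s01) + s12 + t(s12) + 2 * (s02 + t(s02))
  n_co <- tcrossprod(matrix(as.numeric(obs), nrow(geno)))
  D <- ifelse(n_co > 0, absdiff / (2 * n_co), NA_real_)
  diag(D) <- 0
  dimnames(D) <- list(rownames(geno), rownames(geno))
  class(D) <- c("ibs_dist", class(D))
  D
}

#' Classical (metric) multidimensional scaling of a distance matrix
#'
#' Torgerson MDS via double-centered Gram eigendecomposition
#' ([stats::cmdscale()]), with coordinates for the top-`k`
#' positive-eigenvalue axes and a deterministic sign convention: each axis is
#' oriented so its largest-magnitude coordinate is positive. When fewer than
#' `k` positive eigenvalues exist the result is truncated with a warning.
#'
#' @param d distance matrix (e.g. from [ibs_distances()]).
#' @param k number of dimensions (default 4).
#' @return object of class `mds_result`: list with `points` (samples x
#'   dims), `eig` (all eigenvalues, decreasing).
#' @export
classical_mds <- function(d, k = 4L) {
  stopifnot(k >= 1L)
  d <- unclass(d)
  res <- stats::cmdscale(stats::as.dist(d), k = min(k, nrow(d) - 1L), eig = TRUE)
  n_pos <- sum(res$eig > sqrt(.Machine$double.eps) * max(abs(res$eig)))
  if (n_pos < k) {
    warning("only ", n_pos, " positive eigenvalue(s); returning ", n_pos,
            " dimension(s)")
  }
  pts <- res$points[, seq_len(min(k, n_pos)), drop = FALSE]
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("dim", seq_len(ncol(pts)))
  out <- list(points = pts, eig = res$eig)
  class(out) <- "mds_result"
  out
}

#' @export
print.mds_result <- function(x, ...) {
  cat("Classical MDS:", nrow(x$points), "samples,", ncol(x$points),
      "dimension(s); leading eigenvalues:",
      paste(signif(utils::head(x$eig, 4), 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.mds_result <- function(x, dims = c(1, 2), groups = NULL, ...) {
  p <- x$points[, dims, drop = FALSE]
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  graphics::plot(p, col = col, xlab = colnames(p)[1], ylab = colnames(p)[2], ...)
  if (!is.null(groups)) {
    graphics::legend("topleft", legend = levels(factor(groups)),
                     col = seq_along(levels(factor(groups))), pch = 1)
  }
  invisible(x)
}

#' Correlation between per-SNP effects of two traits
#'
#' Pearson correlation between two columns of an effect table over a SNP
#' subset, after removing SNPs inside exclusion intervals (e.g. a region
#' whose single extreme-effect gene would dominate the estimate). The
#' p-value is the usual t transform of r, reported descriptively.
#'
#' @param effects effect table (`snp_id` + trait columns).
#' @param trait_a,trait_b trait column names.
#' @param map optional `snp_map`; required when `exclusions` are given.
#' @param subset optional logical mask or character vector of snp_ids
#'   restricting the SNP set (e.g. SNPs inside selection signatures).
#' @param exclusions optional data.frame of intervals (`chrom`, `start`,
#'   `end`; 1-based inclusive bp bounds) whose SNPs are removed.
#' @param label free-text label for the SNP subset.
#' @return object of class `correlation_report`: list with `label`, `n`,
#'   `r`, `p_value`, `exclusions`.
#' @export
effect_correlation <- function(effects, trait_a, trait_b, map = NULL,
                               subset = NULL, exclusions = NULL,
                               label = "all SNPs") {
  stopifnot(all(c(trait_a, trait_b) %in% names(effects)))
  keep <- rep(TRUE, nrow(effects))
  if (!is.null(subset)) {
    keep <- if (is.logical(subset)) subset else effects$snp_id %in% subset
  }
  if (!is.null(exclusions) && nrow(exclusions)) {
    if (is.null(map)) stop("exclusion intervals require a map")
    pos <- map$pos[match(effects$snp_id, map$snp_id)]
    chrom <- map$chrom[match(effects$snp_id, map$snp_id)]
    for (k in seq_len(nrow(exclusions))) {
      inside <- !is.na(pos) & chrom == as.character(exclusions$chrom[k]) &
        pos >= exclusions$start[k] & pos <= exclusions$end[k]
      keep <- keep & !inside
    }
  }
  a <- effects[[trait_a]][keep]
  b <- effects[[trait_b]][keep]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L) stop("fewer than 3 SNPs after subsetting/exclusion")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(a, b, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  out <- list(label = label, n = length(a), r = r, p_value = p,
              exclusions = exclusions)
  class(out) <- "correlation_report"
  out
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Effect correlation [", x$label, "]: r = ",
      ifelse(is.na(x$r), "NA (constant effects)", signif(x$r, 3)),
      " over n = ", x$n, " SNPs",
      if (!is.null(x$exclusions) && nrow(x$exclusions))
        paste0(" (", nrow(x$exclusions), " exclusion interval(s))") else "",
      "\n", sep = "")
  invisible(x)
}

#' Annotate signatures with contained and proximal genes
#'
#' For each signature interval, reports genes fully or partly overlapping it
#' ("contained", distance 0) and genes whose nearest edge lies within
#' `proximity_bp` of a signature boundary ("proximal", with the gap
#' distance). Signature coordinates are 1-based inclusive bp; gene intervals
#' use the 0-based half-open convention of [read_bed_intervals()].
#'
#' @param signatures data.frame with `chrom`, `start_bp`, `end_bp` (e.g.
#'   [call_signatures()] or [merge_across_windows()] output).
#' @param genes interval data.frame from [read_bed_intervals()].
#' @param proximity_bp maximal gap for a "proximal" call (default 1.5 Mb).
#' @return list with `hits` (data.frame: signature row, gene name, relation,
#'   distance_bp) and `n_signatures_hit` (signatures with >= 1 hit).
#' @export
annotate_signatures <- function(signatures, genes, proximity_bp = 1.5e6) {
  hits <- list()
  if (nrow(signatures) && nrow(genes)) {
    g_start1 <- genes$start + 1  # to 1-based inclusive
    g_end1 <- genes$end
    for (i in seq_len(nrow(signatures))) {
      same <- which(genes$chrom == signatures$chrom[i])
      for (k in same) {
        gap <- max(g_start1[k] - signatures$end_bp[i],
                   signatures$start_bp[i] - g_end1[k], 0)
        if (gap == 0) {
          rel <- "contained"
        } else if (gap <= proximity_bp) {
          rel <- "proximal"
        } else next
        hits[[length(hits) + 1L]] <- data.frame(
          signature = i, chrom = signatures$chrom[i],
          start_bp = signatures$start_bp[i], end_bp = signatures$end_bp[i],
          gene = genes$name[k], relation = rel, distance_bp = gap,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else data.frame(
    signature = integer(), chrom = character(), start_bp = numeric(),
    end_bp = numeric(), gene = character(), relation = character(),
    distance_bp = numeric(), stringsAsFactors = FALSE
  )
  list(hits = hits, n_signatures_hit = length(unique(hits$signature)))
}
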