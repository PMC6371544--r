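#' Build sliding windows over a SNP map
#'
#' Every SNP is a window center. In `"count"` mode the window holds `size`
#' SNPs ( (size-1)/2 on each side); in `"distance"` mode it holds all SNPs
#' within `size/2` bp of the center. Windows never cross a chromosome
#' boundary: interior windows are symmetric and edge windows are truncated
#' asymmetrically, so window centers near chromosome ends average unequal
#' numbers of single-SNP statistics on their two sides.
#'
#' @param map a `snp_map`.
#' @param mode `"distance"` (bp span) or `"count"` (odd SNP count).
#' @param size window size: bp span in distance mode, odd SNP count in count
#'   mode.
#' @return object of class `window_spec`: list with `mode`, `size`, and
#'   integer vectors `l`, `u` of first/last marker indices (global row
#'   indices of `map`) per window center.
#' @export
build_windows <- function(map, mode = c("distance", "count"), size) {
  mode <- match.arg(mode)
  if (mode == "count") {
    size <- as.integer(size)
    if (size < 1L || size %% 2L == 0L) stop("count-mode size must be odd and >= 1")
  } else {
    if (size <= 0) stop("distance-mode size must be > 0")
  }
  L <- nrow(map)
  l <- u <- integer(L)
  for (ch in unique(map$chrom)) {
    idx <- chrom_index(map, ch)
    if (!length(idx)) stop("empty chromosome ", ch)
    n <- length(idx)
    j <- seq_len(n)
    if (mode == "count") {
      h <- (size - 1L) %/% 2L
      l[idx] <- idx[pmax(1L, j - h)]
      u[idx] <- idx[pmin(n, j + h)]
    } else {
      pos <- map$pos[idx]
      half <- size / 2
      # first marker with pos >= center - half; last with pos <= center + half
      l[idx] <- idx[findInterval(pos - half - 0.5, pos) + 1L]
      u[idx] <- idx[findInterval(pos + half, pos)]
    }
  }
  out <- list(mode = mode, size = size, l = l, u = u)
  class(out) <- "window_spec"
  out
}

#' Long-range (windowed mean) statistic track
#'
#' `X_j = sum(S_i, i = l_j..u_j) / (u_j - l_j + 1)`: the mean of the per-SNP
#' statistic over SNP j's window. Implemented with rolling cumulative sums;
#' flagged-missing `S_i` are excluded and the denominator reduced. A window
#' with no usable statistic is flagged `NA`.
#'
#' @param track a `site_track` from [afd()] or [hd()].
#' @param windows a [build_windows()] spec over the same map.
#' @return object of class `x_track`: list with `X` (numeric per SNP),
#'   `stat`, `comparison`, `windows`, `map`.
#' @export
longrange_mean <- function(track, windows) {
  stopifnot(inherits(track, "site_track"), inherits(windows, "window_spec"))
  S <- track$values
  if (length(S) != length(windows$l)) stop("track and windows cover different maps")
  ok <- !is.na(S)
  cs <- cumsum(ifelse(ok, S, 0))
  cn <- cumsum(ok)
  l <- windows$l; u <- windows$u
  tot <- cs[u]; cnt <- cn[u]
  nz <- l > 1L
  tot[nz] <- tot[nz] - cs[l[nz] - 1L]
  cnt[nz] <- cnt[nz] - cn[l[nz] - 1L]
  X <- ifelse(cnt > 0L, tot / cnt, NA_real_)
  out <- list(X = X, stat = track$stat, comparison = track$comparison,
              windows = windows, map = track$map)
  class(out) <- "x_track"
  out
}

#' Standardize a long-range track per chromosome
#'
#' `Z_j = (X_j - mean(X)) / sd(X)` with the mean and sample standard
#' deviation (n - 1) computed within each chromosome, so chromosomes with
#' different baseline differentiation are scanned on a common scale. A
#' chromosome whose usable `X` values are constant (zero sd) is flagged:
#' its `Z` is `NA`.
#'
#' @param x an [longrange_mean()] result (`x_track`). Its `map` must be set.
#' @return object of class `z_track`: list with `Z`, `X`, `map`,
#'   `chrom_stats` (data.frame chrom/mean/sd/n), `stat`, `comparison`,
#'   `windows`.
#' @export
standardize <- function(x) {
  stopifnot(inherits(x, "x_track"))
  map <- x$map
  if (is.null(map)) stop("x_track carries no map; build the site track with one")
  Z <- rep(NA_real_, length(x$X))
  chroms <- unique(map$chrom)
  st <- data.frame(chrom = chroms, mean = NA_real_, sd = NA_real_, n = NA_integer_,
                   stringsAsFactors = FALSE)
  for (k in seq_along(chroms)) {
    idx <- chrom_index(map, chroms[k])
    xv <- x$X[idx]
    usable <- sum(!is.na(xv))
    if (usable < 2L) stop("chromosome ", chroms[k], " has fewer than 2 usable X values")
    m <- mean(xv, na.rm = TRUE)
    s <- stats::sd(xv, na.rm = TRUE)
    st$mean[k] <- m; st$sd[k] <- s; st$n[k] <- usable
    # an all-constant chromosome (sd zero up to rolling-sum round-off) is
    # flagged rather than standardized
    if (s > 1e-10 * max(1, abs(m))) Z[idx] <- (xv - m) / s
  }
  out <- list(Z = Z, X = x$X, map = map, chrom_stats = st,
              stat = x$stat, comparison = x$comparison, windows = x$windows)
  class(out) <- "z_track"
  out
}

#' @export
print.z_track <- function(x, ...) {
  w <- x$windows
  cat("Z_", x$stat, " track: ", length(x$Z), " SNPs, ",
      nrow(x$chrom_stats), " chromosome(s), window ", w$size,
      if (w$mode == "distance") " bp" else " SNPs",
      ", comparison ", paste(x$comparison, collapse = " vs "), "\n", sep = "")
  invisible(x)
}

#' @export
plot.z_track <- function(x, ...) {
  graphics::plot(x$map$pos, x$Z, type = "l", xlab = "position (bp)",
                 ylab = paste0("Z_", x$stat), ...)
  graphics::abline(h = c(-3, 3), lty = 2)
  invisible(x)
}

#' Call selection signatures from a Z track
#'
#' Peak-and-extend rule: every maximal run of consecutive SNPs with
#' `|Z| >= extend_thresh` that contains at least one SNP with
#' `|Z| >= call_thresh` becomes one signature, bounded by the outermost
#' qualifying SNP positions. `Z_AFD` is one-sided (only positive excess
#' differentiation qualifies); `Z_HD` is two-sided and a run must be
#' sign-consistent, with the peak's sign reported. The peak is the
#' maximum-|Z| SNP (leftmost on ties).
#'
#' @param z a [standardize()] result (`z_track`).
#' @param call_thresh peak threshold (default 3).
#' @param extend_thresh extension threshold (default 2); must not exceed
#'   `call_thresh`.
#' @param two_sided default `TRUE` for HD tracks, `FALSE` for AFD.
#' @return `data.frame` of class `selection_signatures`: one row per
#'   signature with `chrom`, `start_bp`, `end_bp`, `peak_bp`, `peak_z`,
#'   `sign`, `n_snps`, `stat`, `window_mode`, `window_size`, `comparison`.
#' @export
call_signatures <- function(z, call_thresh = 3, extend_thresh = 2,
                            two_sided = identical(z$stat, "HD")) {
  stopifnot(inherits(z, "z_track"))
  if (call_thresh < extend_thresh) stop("call_thresh must be >= extend_thresh")
  map <- z$map
  rows <- list()
  for (ch in unique(map$chrom)) {
    idx <- chrom_index(map, ch)
    zz <- z$Z[idx]
    score <- if (two_sided) abs(zz) else zz
    qual <- !is.na(score) & score >= extend_thresh
    if (two_sided) {
      # split candidate runs at sign changes
      sgn <- sign(zz)
      sgn[is.na(sgn)] <- 0
      run_id <- cumsum(c(TRUE, diff(qual) != 0 | (qual[-1] & diff(sgn) != 0)))
    } else {
      run_id <- cumsum(c(TRUE, diff(qual) != 0))
    }
    for (r in split(seq_along(zz)[qual], run_id[qual])) {
      sc <- score[r]
      if (max(sc) < call_thresh) next
      peak_local <- r[which.max(sc)]   # which.max takes the leftmost tie
      gi <- idx[r]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch,
        start_bp = map$pos[gi[1L]],
        end_bp = map$pos[gi[length(gi)]],
        peak_bp = map$pos[idx[peak_local]],
        peak_z = zz[peak_local],
        sign = sign(zz[peak_local]),
        n_snps = length(gi),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    chrom = character(), start_bp = numeric(), end_bp = numeric(),
    peak_bp = numeric(), peak_z = numeric(), sign = numeric(),
    n_snps = integer(), stringsAsFactors = FALSE
  )
  out$stat <- rep(z$stat, nrow(out))
  out$window_mode <- rep(z$windows$mode, nrow(out))
  out$window_size <- rep(z$windows$size, nrow(out))
  out$comparison <- rep(paste(z$comparison, collapse = "-"), nrow(out))
  class(out) <- c("selection_signatures", "data.frame")
  out
}

#' Merge signatures called at several window sizes
#'
#' Takes signature tables from the same comparison and statistic family
#' (e.g. window sizes 0.5, 1, 2, 3 Mb) and unions overlapping or bookended
#' intervals per chromosome. Each merged region records the contributing
#' window sizes and statistics and the best (largest-|Z|) peak. The merge
#' rule is a declared consolidation choice, recorded in the output's
#' `merge_rule` attribute.
#'
#' @param sig_list list of `selection_signatures` tables.
#' @return `data.frame` with `chrom`, `start_bp`, `end_bp`, `n_contributing`,
#'   `window_sizes`, `stats`, `best_peak_z`, `best_peak_bp`.
#' @export
merge_across_windows <- function(sig_list) {
  all_sig <- do.call(rbind, lapply(sig_list, as.data.frame))
  if (is.null(all_sig) || nrow(all_sig) == 0L) {
    out <- data.frame(chrom = character(), start_bp = numeric(), end_bp = numeric(),
                      n_contributing = integer(), window_sizes = character(),
                      stats = character(), best_peak_z = numeric(),
                      best_peak_bp = numeric(), stringsAsFactors = FALSE)
    attr(out, "merge_rule") <- "union of overlapping/adjacent intervals"
    return(out)
  }
  if (length(unique(all_sig$comparison)) > 1L) {
    stop("signature lists come from different comparisons")
  }
  rows <- list()
  for (ch in unique(all_sig$chrom)) {
    sub <- all_sig[all_sig$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(start = sub$start_bp, end = sub$end_bp)
    red <- IRanges::reduce(ir)
    ov <- as.data.frame(IRanges::findOverlaps(ir, red))
    for (k in seq_len(length(red))) {
      contrib <- sub[ov$queryHits[ov$subjectHits == k], , drop = FALSE]
      best <- which.max(abs(contrib$peak_z))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch,
        start_bp = IRanges::start(red)[k],
        end_bp = IRanges::end(red)[k],
        n_contributing = nrow(contrib),
        window_sizes = paste(sort(unique(contrib$window_size)), collapse = ","),
        stats = paste(sort(unique(contrib$stat)), collapse = ","),
        best_peak_z = contrib$peak_z[best],
        best_peak_bp = contrib$peak_bp[best],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "merge_rule") <- "union of overlapping/adjacent intervals"
  out
}

#' One-call genome scan: site statistic to merged signatures
#'
#' Convenience pipeline: builds the AFD or HD track for a cohort comparison,
#' scans it at each requested window size, standardizes per chromosome,
#' calls signatures with the peak-and-extend rule, and merges across window
#' sizes.
#'
#' @param freqs a [group_frequencies()] result whose `map` is set.
#' @param group_a,group_b cohorts to compare.
#' @param stat `"AFD"` or `"HD"`.
#' @param window_sizes bp spans of the fixed-distance sliding windows
#'   (default 0.5, 1, 2, 3 Mb).
#' @param call_thresh,extend_thresh thresholds passed to
#'   [call_signatures()].
#' @return list with `signatures` (per window size) and `merged`.
#' @export
scan_selection <- function(freqs, group_a, group_b, stat = c("AFD", "HD"),
                           window_sizes = c(0.5e6, 1e6, 2e6, 3e6),
                           call_thresh = 3, extend_thresh = 2) {
  stat <- match.arg(stat)
  if (is.null(freqs$map)) stop("frequency table carries no map")
  track <- if (stat == "AFD") afd(freqs, group_a, group_b) else
    hd(freqs, group_a, group_b)
  sigs <- lapply(window_sizes, function(w) {
    ws <- build_windows(freqs$map, "distance", w)
    call_signatures(standardize(longrange_mean(track, ws)),
                    call_thresh, extend_thresh)
  })
  names(sigs) <- paste0(window_sizes / 1e6, "Mb")
  list(signatures = sigs, merged = merge_across_windows(sigs))
}
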