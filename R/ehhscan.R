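#' Specify a core haplotype
#'
#' A core is a short contiguous run of SNPs together with one allele string
#' over them; extended haplotype homozygosity (EHH) is measured outward from
#' its edges among the haplotypes that carry it.
#'
#' @param chrom chromosome label.
#' @param from,to first and last SNP index of the core (global row indices of
#'   the map, contiguous, on `chrom`).
#' @param hap integer 0/1 vector of core alleles (0 = allele1), length
#'   `to - from + 1`.
#' @return object of class `core_spec`.
#' @export
core_spec <- function(chrom, from, to, hap) {
  from <- as.integer(from); to <- as.integer(to)
  hap <- as.integer(hap)
  stopifnot(to >= from, length(hap) == to - from + 1L, all(hap %in% 0:1))
  structure(list(chrom = as.character(chrom), from = from, to = to, hap = hap),
            class = "core_spec")
}

core_carriers <- function(panel, core) {
  seg <- panel[, core$from:core$to, drop = FALSE]
  which(colSums(t(seg) != core$hap) == 0L)
}

# EHH among carrier rows `rows` over columns `cols` of panel:
# group carriers by identity over cols, EHH = sum C(e_g,2) / C(c,2)
ehh_of_groups <- function(panel, rows, cols) {
  c_n <- length(rows)
  if (!length(cols)) return(1)
  key <- apply(panel[rows, cols, drop = FALSE], 1L, paste, collapse = "")
  sizes <- table(key)
  sum(choose(sizes, 2)) / choose(c_n, 2)
}

#' EHH at a single flanking SNP
#'
#' Among the carriers of the core haplotype, the probability that two
#' randomly drawn carriers are identical at every SNP from the near core
#' edge out to the target SNP (inclusive): with carriers grouped by identity
#' over that stretch into groups of sizes `e_g`,
#' `EHH = sum C(e_g, 2) / C(c, 2)`.
#'
#' @param panel haplotypes x SNPs 0/1 matrix.
#' @param core a [core_spec()].
#' @param target global SNP index of the flanking target.
#' @return EHH in \[0, 1\]; `NA` (flagged) when fewer than 2 carriers.
#' @export
ehh_at <- function(panel, core, target) {
  rows <- core_carriers(panel, core)
  if (length(rows) < 2L) return(NA_real_)
  cols <- if (target > core$to) (core$to + 1L):target
          else if (target < core$from) target:(core$from - 1L)
          else integer(0)  # inside the core: EHH = 1 by definition
  ehh_of_groups(panel, rows, cols)
}

# incremental EHH walk in one direction; returns list(ehh = numeric vector
# over `cols` in walk order, n_ok = SNPs with EHH >= threshold before the
# first drop). Early stop only when `stop_below` is TRUE.
ehh_walk <- function(panel, rows, cols, threshold, stop_below = FALSE) {
  grp <- rep(1L, length(rows))
  c2 <- choose(length(rows), 2)
  ehh <- numeric(0)
  n_ok <- 0L
  consec <- TRUE
  for (j in cols) {
    key <- grp * 2L + panel[rows, j]
    grp <- match(key, unique(key))
    e <- sum(choose(tabulate(grp), 2)) / c2
    ehh <- c(ehh, e)
    if (consec && e >= threshold) n_ok <- n_ok + 1L else consec <- FALSE
    if (stop_below && !consec) break
  }
  list(ehh = ehh, n_ok = n_ok)
}

#' EHH profile and decay distances around a core
#'
#' Computes EHH at every flanking SNP in both directions and the decay
#' distance per direction: the bp distance from the core edge to the last
#' consecutive SNP with `EHH >= threshold` (the first SNP below the
#' threshold terminates the extension; no interpolation). The total distance
#' adds both directions and the core span.
#'
#' @param panel haplotypes x SNPs 0/1 matrix covering the core's chromosome.
#' @param core a [core_spec()].
#' @param map `snp_map` for the panel columns.
#' @param threshold minimal EHH defining the decay distance (default 0.6).
#' @return object of class `ehh_profile`: list with `core`, `carriers`,
#'   `freq` (carriers / panel size), `snp` / `pos` / `ehh` (flanking SNPs,
#'   walk order away from the core; the core itself has EHH 1), `decay_left`,
#'   `decay_right`, `decay_total` (bp), `threshold`.
#' @export
ehh_profile <- function(panel, core, map, threshold = 0.6) {
  idx <- chrom_index(map, core$chrom)
  stopifnot(core$from %in% idx, core$to %in% idx)
  rows <- core_carriers(panel, core)
  if (length(rows) < 2L) {
    stop("core haplotype has fewer than 2 carriers; EHH undefined")
  }
  left_cols <- rev(idx[idx < core$from])
  right_cols <- idx[idx > core$to]
  lw <- ehh_walk(panel, rows, left_cols, threshold)
  rw <- ehh_walk(panel, rows, right_cols, threshold)
  decay_left <- if (lw$n_ok > 0L) map$pos[core$from] - map$pos[left_cols[lw$n_ok]] else 0
  decay_right <- if (rw$n_ok > 0L) map$pos[right_cols[rw$n_ok]] - map$pos[core$to] else 0
  core_span <- map$pos[core$to] - map$pos[core$from]
  out <- list(
    core = core,
    carriers = length(rows),
    freq = length(rows) / nrow(panel),
    snp = c(rev(left_cols), right_cols),
    pos = map$pos[c(rev(left_cols), right_cols)],
    ehh = c(rev(lw$ehh), rw$ehh),
    decay_left = decay_left,
    decay_right = decay_right,
    decay_total = decay_left + decay_right + core_span,
    threshold = threshold
  )
  class(out) <- "ehh_profile"
  out
}

#' @export
print.ehh_profile <- function(x, ...) {
  cat("EHH profile: core chr", x$core$chrom, " SNPs ", x$core$from, "-",
      x$core$to, " [", paste(x$core$hap, collapse = ""), "], ",
      x$carriers, " carriers (freq ", signif(x$freq, 3), "), decay ",
      round(x$decay_left), " + ", round(x$decay_right), " bp (total ",
      round(x$decay_total), " bp at EHH >= ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' @export
plot.ehh_profile <- function(x, ...) {
  ord <- order(x$pos)
  graphics::plot(x$pos[ord], x$ehh[ord], type = "b", ylim = c(0, 1),
                 xlab = "position (bp)", ylab = "EHH", ...)
  graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}

#' Enumerate core haplotypes genome-wide and profile their EHH
#'
#' Slides a fixed-SNP-count core across each chromosome (every offset); at
#' each position, every distinct core haplotype with frequency at least
#' `min_core_freq` is profiled. The EHH walk stops at the first SNP below
#' `threshold`, which is what the decay distance measures.
#'
#' @param panel haplotypes x SNPs 0/1 matrix.
#' @param map matching `snp_map`.
#' @param core_size core length in SNPs (default 5).
#' @param threshold minimal EHH (default 0.6).
#' @param min_core_freq frequency floor for a core haplotype (default 0.05).
#' @return `data.frame`, one row per (core position, haplotype): `chrom`,
#'   `from`, `to`, `start_bp`, `end_bp`, `hap`, `carriers`, `freq`,
#'   `decay_left`, `decay_right`, `decay_total`.
#' @export
scan_cores <- function(panel, map, core_size = 5L, threshold = 0.6,
                       min_core_freq = 0.05) {
  stopifnot(core_size >= 1L, ncol(panel) == nrow(map))
  rows_out <- list()
  n_hap <- nrow(panel)
  for (ch in unique(map$chrom)) {
    idx <- chrom_index(map, ch)
    if (length(idx) < core_size) next
    for (a in idx[seq_len(length(idx) - core_size + 1L)]) {
      b <- a + core_size - 1L
      seg <- panel[, a:b, drop = FALSE]
      key <- apply(seg, 1L, paste, collapse = "")
      tab <- table(key)
      keep <- names(tab)[tab / n_hap >= min_core_freq & tab >= 2L]
      for (hk in keep) {
        rows <- which(key == hk)
        left_cols <- rev(idx[idx < a])
        right_cols <- idx[idx > b]
        lw <- ehh_walk(panel, rows, left_cols, threshold, stop_below = TRUE)
        rw <- ehh_walk(panel, rows, right_cols, threshold, stop_below = TRUE)
        dl <- if (lw$n_ok > 0L) map$pos[a] - map$pos[left_cols[lw$n_ok]] else 0
        dr <- if (rw$n_ok > 0L) map$pos[right_cols[rw$n_ok]] - map$pos[b] else 0
        rows_out[[length(rows_out) + 1L]] <- data.frame(
          chrom = ch, from = a, to = b,
          start_bp = map$pos[a], end_bp = map$pos[b],
          hap = hk, carriers = length(rows), freq = length(rows) / n_hap,
          decay_left = dl, decay_right = dr,
          decay_total = dl + dr + (map$pos[b] - map$pos[a]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows_out)) {
    return(data.frame(chrom = character(), from = integer(), to = integer(),
                      start_bp = numeric(), end_bp = numeric(), hap = character(),
                      carriers = integer(), freq = numeric(), decay_left = numeric(),
                      decay_right = numeric(), decay_total = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows_out)
}

#' Count maximal regions with long EHH decay
#'
#' Qualifying cores (best haplotype `decay_total >= cut`) are expanded to
#' their full EHH span `[start_bp - decay_left, end_bp + decay_right]` and
#' overlapping spans are merged per chromosome, so a region covered by many
#' overlapping long-EHH cores counts once.
#'
#' @param cores a [scan_cores()] table.
#' @param cut minimal total decay distance in bp (e.g. 1e6).
#' @return number of merged regions.
#' @export
count_long_ehh_regions <- function(cores, cut) {
  q <- cores[cores$decay_total >= cut, , drop = FALSE]
  if (!nrow(q)) return(0L)
  n <- 0L
  for (ch in unique(q$chrom)) {
    sub <- q[q$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(start = sub$start_bp - sub$decay_left,
                           end = sub$end_bp + sub$decay_right)
    n <- n + length(IRanges::reduce(ir))
  }
  n
}

#' Core-haplotype frequencies across cohorts
#'
#' Tabulates the frequency of every distinct haplotype over a core SNP range
#' in each cohort's panel, sorted by descending frequency in the last
#' cohort. Under positive selection the favoured core haplotype's frequency
#' rises across serial cohorts.
#'
#' @param panels named list of haplotype panels (same SNP columns).
#' @param from,to global SNP index range of the core.
#' @return `data.frame` with `hap` and one frequency column per cohort.
#' @export
core_haplotype_frequencies <- function(panels, from, to) {
  stopifnot(length(panels) >= 1L)
  keys <- lapply(panels, function(P)
    apply(P[, from:to, drop = FALSE], 1L, paste, collapse = ""))
  haps <- sort(unique(unlist(keys, use.names = FALSE)))
  freqs <- vapply(keys, function(k) {
    tab <- table(factor(k, levels = haps))
    as.numeric(tab) / length(k)
  }, numeric(length(haps)))
  freqs <- matrix(freqs, nrow = length(haps),
                  dimnames = list(NULL, names(panels)))
  out <- data.frame(hap = haps, freqs, stringsAsFactors = FALSE,
                    check.names = FALSE)
  out[order(-out[[ncol(out)]], out$hap), , drop = FALSE]
}
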