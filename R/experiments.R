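#' Sweep parameter-recovery experiment
#'
#' Runs replicate forward simulations with one implanted sweep at the center
#' of a single 50K-density chromosome, scans each replicate with the
#' windowed Z_AFD statistic at the standard window sizes, and records per
#' replicate: whether any called signature overlaps the sweep locus, the
#' selected-allele frequency in each cohort, the frequency trajectory of the
#' selected core haplotype (the leading 5-SNP haplotype among selected-allele
#' carriers of the final cohort), and the EHH decay distance of each
#' cohort's locally dominant core haplotype at the swept core — under
#' selection the dominant haplotype at the locus is the swept one, and its
#' homozygosity extends much further than the dominant haplotype of the
#' unselected baseline.
#'
#' @param n_reps number of replicates.
#' @param base_seed integer; replicate r uses seed `base_seed + r`.
#' @param s selection coefficient of the implanted sweep.
#' @param pop_size diploid population size.
#' @param generations generations per phase (two phases are run).
#' @param snps_per_chrom,chrom_length_bp map of the simulated chromosome.
#' @param window_sizes bp window sizes for the scan.
#' @param ehh logical; also compute the EHH decay comparison (slower).
#' @return `data.frame`, one row per replicate: `overlap`, `freq_I`,
#'   `freq_II`, `freq_III`, `n_signatures`, and (with `ehh`) `core_freq_I`,
#'   `core_freq_II`, `core_freq_III`, `decay_I`, `decay_III`.
#' @export
sweep_recovery_experiment <- function(n_reps = 100L, base_seed = 1000L,
                                      s = 0.5, pop_size = 500L,
                                      generations = 20L,
                                      snps_per_chrom = 600L,
                                      chrom_length_bp = 30e6,
                                      window_sizes = c(0.5e6, 1e6, 2e6, 3e6),
                                      ehh = TRUE) {
  sweep_snp <- as.integer(snps_per_chrom %/% 2L)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(
      snps_per_chrom = snps_per_chrom, chrom_length_bp = chrom_length_bp,
      pop_size = pop_size,
      generations_phase1 = generations, generations_phase2 = generations,
      sweep_loci = list(list(chrom = 1L, snp = sweep_snp, s = s)),
      seed = base_seed + r
    )
    sim <- simulate_cohorts(cfg)
    ft <- group_frequencies(do.call(rbind, sim$cohorts), sim$groups, map = sim$map)
    sc <- scan_selection(ft, "I", "III", "AFD", window_sizes = window_sizes)
    sweep_pos <- sim$map$pos[sweep_snp]
    m <- sc$merged
    overlap <- nrow(m) > 0 && any(m$start_bp <= sweep_pos & sweep_pos <= m$end_bp)
    # selected allele is coded 1 in the panel (frequency = 1 - p_allele1)
    frq <- 1 - ft$p[sweep_snp, c("I", "II", "III")]
    row <- data.frame(overlap = overlap, freq_I = frq[[1]], freq_II = frq[[2]],
                      freq_III = frq[[3]], n_signatures = nrow(m))
    if (ehh) {
      half <- 2L
      from <- sweep_snp - half; to <- sweep_snp + half
      pIII <- sim$panels$III
      sel <- pIII[, sweep_snp] == 1L
      lead_decay <- function(panel) {
        key <- apply(panel[, from:to, drop = FALSE], 1L, paste, collapse = "")
        lead <- names(sort(table(key), decreasing = TRUE))[1L]
        core <- core_spec("1", from, to, as.integer(strsplit(lead, "")[[1]]))
        if (length(core_carriers(panel, core)) < 2L) return(NA_real_)
        ehh_profile(panel, core, sim$map)$decay_total
      }
      if (sum(sel) >= 2L) {
        key <- apply(pIII[sel, from:to, drop = FALSE], 1L, paste, collapse = "")
        lead <- names(sort(table(key), decreasing = TRUE))[1L]
        cf <- core_haplotype_frequencies(sim$panels, from, to)
        cfl <- cf[cf$hap == lead, , drop = FALSE]
        row$core_freq_I <- cfl$I; row$core_freq_II <- cfl$II
        row$core_freq_III <- cfl$III
      } else {
        row$core_freq_I <- row$core_freq_II <- row$core_freq_III <- NA_real_
      }
      row$decay_I <- lead_decay(sim$panels$I)
      row$decay_III <- lead_decay(pIII)
    }
    out[[r]] <- row
  }
  do.call(rbind, out)
}

#' Neutral false-positive experiment
#'
#' Simulates sweep-free (drift-only) replicates and counts called Z_AFD
#' signatures at increasing call thresholds. Under neutrality the expected
#' signature count is low and decreases as the call threshold rises.
#'
#' @param n_reps number of replicates.
#' @param base_seed integer; replicate r uses seed `base_seed + r`.
#' @param call_threshs increasing call thresholds to evaluate.
#' @param ... passed to [sim_config()] (map and population settings).
#' @return matrix of signature counts, replicates x thresholds.
#' @export
neutral_signature_counts <- function(n_reps = 20L, base_seed = 5000L,
                                     call_threshs = c(3, 3.5, 4), ...) {
  counts <- matrix(0L, nrow = n_reps, ncol = length(call_threshs),
                   dimnames = list(NULL, paste0("thresh", call_threshs)))
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(seed = base_seed + r, ...)
    sim <- simulate_cohorts(cfg)
    ft <- group_frequencies(do.call(rbind, sim$cohorts), sim$groups, map = sim$map)
    track <- afd(ft, "I", "III")
    for (k in seq_along(call_threshs)) {
      n_sig <- 0L
      for (w in c(0.5e6, 1e6, 2e6, 3e6)) {
        z <- standardize(longrange_mean(track, build_windows(sim$map, "distance", w)))
        n_sig <- n_sig + nrow(call_signatures(z, call_thresh = call_threshs[k]))
      }
      counts[r, k] <- n_sig
    }
  }
  counts
}
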