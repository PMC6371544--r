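# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (per-window loops, all-pairs counting) so they cannot
# share a defect with the rolling/grouping implementations they check.

# naive windowed mean: re-sums every window, skipping NAs
naive_window_mean <- function(S, windows) {
  vapply(seq_along(S), function(j) {
    v <- S[windows$l[j]:windows$u[j]]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, 1)
}

# all-pairs EHH: fraction of carrier pairs identical over cols
allpairs_ehh <- function(panel, rows, cols) {
  if (length(cols) == 0) return(1)
  n <- length(rows)
  hits <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (all(panel[rows[i], cols] == panel[rows[j], cols])) hits <- hits + 1L
    }
  }
  hits / choose(n, 2)
}

# per-pair IBS distance loop
loop_ibs <- function(geno) {
  n <- nrow(geno)
  D <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      co <- !is.na(geno[a, ]) & !is.na(geno[b, ])
      D[a, b] <- if (!any(co)) NA_real_ else
        1 - mean((2 - abs(geno[a, co] - geno[b, co])) / 2)
    }
  }
  diag(D) <- 0
  D
}

# two-pass Pearson correlation
twopass_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# small simulation shared by several tests
tiny_sim <- function(seed = 11, s = 0.5, snps = 120L, len_bp = 6e6,
                     pop = 80L, gens = 8L, sweep_snp = snps %/% 2L,
                     cohorts = c(40L, 40L, 40L), founders = 160L) {
  sweeps <- if (is.null(s)) list() else
    list(list(chrom = 1L, snp = sweep_snp, s = s))
  simulate_cohorts(sim_config(
    snps_per_chrom = snps, chrom_length_bp = len_bp,
    n_founder_haplotypes = founders, pop_size = pop,
    generations_phase1 = gens, generations_phase2 = gens,
    sweep_loci = sweeps, cohort_sizes = cohorts, seed = seed
  ))
}

# fabricate a z_track with prescribed Z values (toy signature-calling input)
make_ztrack <- function(z, map, stat = "AFD") {
  structure(
    list(Z = z, X = z, map = map,
         chrom_stats = data.frame(chrom = unique(map$chrom), mean = 0, sd = 1,
                                  n = nrow(map)),
         stat = stat, comparison = c("I", "III"),
         windows = build_windows(map, "count", 1)),
    class = "z_track"
  )
}

even_map <- function(n, chrom = "1", spacing = 50000L) {
  snp_map(paste0("c", chrom, "_s", seq_len(n)), chrom,
          spacing * seq_len(n))
}
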