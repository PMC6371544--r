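#' Configuration for the serial-cohort forward simulator
#'
#' Describes a Wright-Fisher forward simulation of a closed breeding
#' population genotyped on a SNP-array-density map, sampled at three time
#' points: an unselected baseline (generation 0) and two later cohorts after
#' two phases of directional selection (e.g. two consecutive 20-generation
#' periods of a breeding programme). Sweeps are implanted as per-locus
#' viability selection with multiplicative fitness `(1 + s)` per copy of the
#' selected allele; all other loci drift.
#'
#' Defaults emulate a 50K-chip marker density (one SNP per 50 kb) on a single
#' scaled-down 30 Mb chromosome, a diploid population of 500, and cohorts of
#' 100 individuals each.
#'
#' @param n_chrom number of chromosomes.
#' @param snps_per_chrom SNPs per chromosome.
#' @param chrom_length_bp chromosome length in bp.
#' @param n_founder_haplotypes distinct founder haplotypes (must be even).
#'   The default 40 emulates a narrow founding base (a few dozen founder
#'   animals), which is what gives livestock populations their long-range LD.
#' @param pop_size diploid individuals per generation.
#' @param generations_phase1,generations_phase2 generations in the first and
#'   second selection phase.
#' @param sweep_loci list of sweeps, each `list(chrom =, snp =, s =, phase =)`
#'   with `snp` the SNP index within its chromosome, `s >= 0` the selection
#'   coefficient, and `phase` one of "both", "1", "2" (when the sweep is
#'   active).
#' @param recomb_rate_per_bp per-bp, per-meiosis crossover rate (default
#'   1e-8, i.e. 1 cM/Mb).
#' @param cohort_sizes diploid sample sizes of cohorts I, II, III.
#' @param effect_corr target genome-wide correlation between the two simulated
#'   trait effects (in \[-1, 0\]); see [simulate_effect_table()].
#' @param founder_freq_range range of the uniform distribution from which the
#'   founder frequency of allele 1 is drawn at neutral loci.
#' @param sweep_init_freq founder frequency of the selected allele at sweep
#'   loci (a sweep starts from an initially rare favoured variant).
#' @param burnin_generations neutral generations run between founding and the
#'   sampling of cohort I, at `burnin_recomb_mult` times the recombination
#'   rate. This compresses the deep ancestral history that turns exact
#'   founder copies into a mosaic of haplotype blocks (standard forward-
#'   simulation rescaling); selection is off during burn-in.
#' @param burnin_recomb_mult recombination-rate multiplier during burn-in.
#' @param seed integer seed; all randomness in [simulate_cohorts()] flows from
#'   it.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_chrom = 1L,
                       snps_per_chrom = 600L,
                       chrom_length_bp = 30e6,
                       n_founder_haplotypes = 40L,
                       pop_size = 500L,
                       generations_phase1 = 20L,
                       generations_phase2 = 20L,
                       sweep_loci = list(),
                       recomb_rate_per_bp = 1e-8,
                       cohort_sizes = c(100L, 100L, 100L),
                       effect_corr = -0.27,
                       founder_freq_range = c(0.05, 0.95),
                       sweep_init_freq = 0.10,
                       burnin_generations = 20L,
                       burnin_recomb_mult = 20,
                       seed = 1L) {
  cfg <- list(
    n_chrom = as.integer(n_chrom),
    snps_per_chrom = as.integer(snps_per_chrom),
    chrom_length_bp = as.numeric(chrom_length_bp),
    n_founder_haplotypes = as.integer(n_founder_haplotypes),
    pop_size = as.integer(pop_size),
    generations_phase1 = as.integer(generations_phase1),
    generations_phase2 = as.integer(generations_phase2),
    sweep_loci = sweep_loci,
    recomb_rate_per_bp = as.numeric(recomb_rate_per_bp),
    cohort_sizes = as.integer(cohort_sizes),
    effect_corr = as.numeric(effect_corr),
    founder_freq_range = as.numeric(founder_freq_range),
    sweep_init_freq = as.numeric(sweep_init_freq),
    burnin_generations = as.integer(burnin_generations),
    burnin_recomb_mult = as.numeric(burnin_recomb_mult),
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      n_chrom >= 1L, snps_per_chrom >= 1L, chrom_length_bp > 0,
      n_founder_haplotypes >= 2L, n_founder_haplotypes %% 2L == 0L,
      pop_size >= 1L,
      generations_phase1 >= 0L, generations_phase2 >= 0L,
      recomb_rate_per_bp >= 0,
      length(cohort_sizes) == 3L, all(cohort_sizes >= 1L),
      all(cohort_sizes <= pop_size),
      abs(effect_corr) <= 1,
      length(founder_freq_range) == 2L,
      founder_freq_range[1] > 0, founder_freq_range[2] < 1,
      sweep_init_freq > 0, sweep_init_freq < 1,
      burnin_generations >= 0L, burnin_recomb_mult >= 0
    )
  })
  cfg$sweep_loci <- lapply(cfg$sweep_loci, function(sw) {
    stopifnot(!is.null(sw$chrom), !is.null(sw$snp), !is.null(sw$s))
    sw$chrom <- as.integer(sw$chrom)
    sw$snp <- as.integer(sw$snp)
    sw$s <- as.numeric(sw$s)
    if (is.null(sw$phase)) sw$phase <- "both"
    if (sw$s < 0) stop("selection coefficient s must be >= 0")
    if (sw$chrom < 1L || sw$chrom > cfg$n_chrom) stop("sweep chrom out of range")
    if (sw$snp < 1L || sw$snp > cfg$snps_per_chrom) stop("sweep snp index out of range")
    if (!sw$phase %in% c("both", "1", "2")) {
      stop("sweep phase must be 'both', '1' or '2'")
    }
    sw
  })
  class(cfg) <- "sim_config"
  cfg
}

# map of evenly spaced SNPs implied by a sim_config; A/C alleles throughout
sim_snp_map <- function(config) {
  spacing <- config$chrom_length_bp / config$snps_per_chrom
  pos <- as.integer(round(seq_len(config$snps_per_chrom) * spacing))
  chrom <- rep(as.character(seq_len(config$n_chrom)), each = config$snps_per_chrom)
  snp_map(
    snp_id = paste0("c", chrom, "_s",
                    rep(seq_len(config$snps_per_chrom), config$n_chrom)),
    chrom = chrom,
    pos = rep(pos, config$n_chrom)
  )
}

# global column index of a sweep locus
sweep_col <- function(config, sw) (sw$chrom - 1L) * config$snps_per_chrom + sw$snp

#' Simulate founder haplotypes
#'
#' Draws per-SNP founder frequencies of allele 1 from
#' `Unif(founder_freq_range)` (array-ascertained common variants) and founder
#' haplotype alleles as independent Bernoulli draws. At sweep loci the
#' selected allele (coded 1) starts at `sweep_init_freq`.
#'
#' @param config a [sim_config()].
#' @return list with `panel` (founder haplotypes x SNPs 0/1 matrix,
#'   0 = allele1) and `map` (`snp_map`). Uses the current RNG state; seed it
#'   yourself (or use [simulate_cohorts()], which seeds from `config$seed`).
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  map <- sim_snp_map(config)
  L <- nrow(map)
  H <- config$n_founder_haplotypes
  p1 <- stats::runif(L, config$founder_freq_range[1], config$founder_freq_range[2])
  # panel codes 0 = allele1, so P(entry = 1) = 1 - p1
  panel <- matrix(
    as.integer(stats::runif(H * L) >= rep(p1, each = H)),
    nrow = H, ncol = L
  )
  for (sw in config$sweep_loci) {
    j <- sweep_col(config, sw)
    # selected allele is the one coded 1; implant it on a fixed number of
    # founder haplotypes so every replicate starts its sweep at
    # sweep_init_freq (at least one carrier)
    n_car <- max(1L, round(config$sweep_init_freq * H))
    panel[, j] <- 0L
    panel[sample.int(H, n_car), j] <- 1L
  }
  rownames(panel) <- paste0("fh", seq_len(H))
  colnames(panel) <- map$snp_id
  list(panel = panel, map = map)
}

# one gamete set: M gametes from parents `par` (diploid indices into H's rows
# taken pairwise); crossover count per chromosome ~ Poisson(r * length).
# Leading-haplotype rows are bulk-copied; only recombinant gametes get their
# trailing segments overwritten (fast path for the common 1-crossover case).
make_gametes <- function(H, par, map, config) {
  M <- length(par)
  r <- config$recomb_rate_per_bp
  start <- sample.int(2L, M, replace = TRUE) - 1L  # which parental hap leads
  rows_a <- 2L * par - 1L + start
  rows_b <- 2L * par - start  # = 2*par - 1 + (1 - start)
  G <- H[rows_a, , drop = FALSE]
  for (ch in seq_len(config$n_chrom)) {
    col0 <- (ch - 1L) * config$snps_per_chrom
    n_c <- config$snps_per_chrom
    pos <- map$pos[col0 + seq_len(n_c)]
    ncx <- stats::rpois(M, r * config$chrom_length_bp)
    one <- which(ncx == 1L)
    if (length(one)) {
      brk <- findInterval(stats::runif(length(one), 0, config$chrom_length_bp), pos)
      for (i in seq_along(one)) {
        if (brk[i] >= n_c) next                    # crossover beyond last SNP
        cols <- col0 + (brk[i] + 1L):n_c
        G[one[i], cols] <- H[rows_b[one[i]], cols]
      }
    }
    for (k in which(ncx >= 2L)) {
      cx <- sort(stats::runif(ncx[k], 0, config$chrom_length_bp))
      from_b <- which(findInterval(pos, cx) %% 2L == 1L)
      if (length(from_b)) {
        cols <- col0 + from_b
        G[k, cols] <- H[rows_b[k], cols]
      }
    }
  }
  rownames(G) <- NULL
  G
}

#' Evolve a haplotype panel under Wright-Fisher reproduction
#'
#' Random mating with recombination in a population of `config$pop_size`
#' diploids. Each generation, parents are sampled with probability
#' proportional to their viability `prod (1 + s)^dose`, where `dose` is the
#' individual's copy number of the selected allele at each active sweep
#' locus; gametes recombine with a Poisson number of crossovers per
#' chromosome. Neutral loci drift.
#'
#' @param panel haplotypes x SNPs 0/1 matrix with an even number of rows equal
#'   to `2 * config$pop_size` (consecutive row pairs are individuals). A
#'   founder panel smaller than `2 * pop_size` is expanded by sampling founder
#'   haplotypes with replacement.
#' @param config a [sim_config()].
#' @param n_generations number of generations to run (0 returns the panel
#'   unchanged).
#' @param map the `snp_map` for the panel (defaults to the config-implied map).
#' @param active_sweeps subset of `config$sweep_loci` in force during this
#'   call (default: all).
#' @param recomb_mult multiplier on the recombination rate (used by the
#'   burn-in phase of [simulate_cohorts()]).
#' @return list with `panel` (the evolved panel) and `traj` (matrix of
#'   selected-allele frequency per generation, one column per sweep locus in
#'   `config$sweep_loci`, rows = generations 0..n).
#' @export
evolve <- function(panel, config, n_generations,
                   map = sim_snp_map(config),
                   active_sweeps = config$sweep_loci,
                   recomb_mult = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(panel) || nrow(panel) == 0L) stop("empty haplotype panel")
  for (sw in active_sweeps) if (sw$s < 0) stop("selection coefficient s must be >= 0")
  n_generations <- as.integer(n_generations)
  stopifnot(n_generations >= 0L)

  sweep_cols <- vapply(config$sweep_loci, function(sw) sweep_col(config, sw), 1L)
  traj <- matrix(NA_real_, nrow = n_generations + 1L, ncol = length(sweep_cols))
  colnames(traj) <- names(sweep_cols) <- vapply(
    config$sweep_loci, function(sw) paste0("chr", sw$chrom, "_snp", sw$snp), ""
  )
  if (length(sweep_cols)) traj[1L, ] <- colMeans(panel[, sweep_cols, drop = FALSE])
  if (n_generations == 0L) return(list(panel = panel, traj = traj))

  N <- config$pop_size
  H <- panel
  if (nrow(H) != 2L * N) {
    idx <- sample.int(nrow(H), 2L * N, replace = TRUE)
    H <- H[idx, , drop = FALSE]
  }
  if (recomb_mult != 1) {
    config$recomb_rate_per_bp <- config$recomb_rate_per_bp * recomb_mult
  }
  act_cols <- vapply(active_sweeps, function(sw) sweep_col(config, sw), 1L)
  act_s <- vapply(active_sweeps, function(sw) as.numeric(sw$s), 1)

  for (g in seq_len(n_generations)) {
    if (length(act_cols)) {
      odd <- seq(1L, 2L * N, 2L)
      dose <- H[odd, act_cols, drop = FALSE] + H[odd + 1L, act_cols, drop = FALSE]
      w <- exp(dose %*% log1p(act_s))[, 1L]
    } else {
      w <- rep(1, N)
    }
    parents <- sample.int(N, 2L * N, replace = TRUE, prob = w)
    gam <- make_gametes(H, parents, map, config)
    # gametes 1..N are maternal, N+1..2N paternal; interleave into individuals
    H <- gam[as.vector(rbind(seq_len(N), N + seq_len(N))), , drop = FALSE]
    if (length(sweep_cols)) traj[g + 1L, ] <- colMeans(H[, sweep_cols, drop = FALSE])
  }
  rownames(H) <- paste0("h", seq_len(nrow(H)))
  colnames(H) <- map$snp_id
  list(panel = H, traj = traj)
}

#' Draw diploid cohorts from panels at three time points
#'
#' Individuals are formed from consecutive haplotype pairs and sampled
#' without replacement from each panel. Dosage matrices follow the allele1
#' convention (`dosage = 2 - h1 - h2`); the phased panels of the sampled
#' individuals are retained.
#'
#' @param panels list of three haplotype panels (generations 0, g1, g1+g2).
#' @param config a [sim_config()].
#' @param map the shared `snp_map`.
#' @return list with `cohorts` (dosage matrices named I/II/III), `panels`
#'   (the sampled phased panels), `groups` (named cohort label per sample)
#'   and `map`.
#' @export
sample_cohorts <- function(panels, config, map = sim_snp_map(config)) {
  stopifnot(length(panels) == 3L)
  labels <- c("I", "II", "III")
  cohorts <- list(); kept <- list()
  for (i in 1:3) {
    P <- panels[[i]]
    n_ind <- nrow(P) %/% 2L
    size <- config$cohort_sizes[i]
    if (size > n_ind) {
      stop("cohort ", labels[i], " size ", size,
           " exceeds available haplotype pairs (", n_ind, ")")
    }
    pick <- sort(sample.int(n_ind, size))
    rows <- as.vector(rbind(2L * pick - 1L, 2L * pick))
    sub <- P[rows, , drop = FALSE]
    ids <- paste0(labels[i], "_", seq_len(size))
    rownames(sub) <- paste(rep(ids, each = 2L), c("h1", "h2"), sep = "_")
    colnames(sub) <- map$snp_id
    kept[[labels[i]]] <- sub
    cohorts[[labels[i]]] <- panel_to_dosage(sub, ids)
  }
  groups <- rep(labels, times = config$cohort_sizes)
  names(groups) <- unlist(lapply(cohorts, rownames), use.names = FALSE)
  list(cohorts = cohorts, panels = kept, groups = groups, map = map)
}

#' Run the full serial-cohort simulation
#'
#' Seeds the RNG from `config$seed`, simulates the founder haplotypes,
#' expands them into the diploid breeding population, runs the neutral
#' burn-in (compressed ancestral recombination; see [sim_config()]), then
#' evolves the population through two phases of selection (phase-"1" sweeps
#' act in the first, phase-"2" in the second, "both" in both). Cohorts I, II
#' and III are sampled at generations 0 (post-burn-in), g1 and g1+g2.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_result`: list with `cohorts`, `panels`,
#'   `groups`, `map`, `truth` (data.frame of selected-allele frequency per
#'   generation per sweep locus) and `config`.
#' @examples
#' cfg <- sim_config(snps_per_chrom = 50, chrom_length_bp = 2.5e6,
#'                   pop_size = 60, cohort_sizes = c(20, 20, 20),
#'                   generations_phase1 = 5, generations_phase2 = 5, seed = 7)
#' sim <- simulate_cohorts(cfg)
#' dim(sim$cohorts$I)
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fd <- simulate_founders(config)
  map <- fd$map

  # bottleneck founding: the breeding population is pairs drawn (with
  # replacement) from the distinct founder haplotypes; burn-in then breaks
  # exact founder copies into haplotype blocks
  idx0 <- sample.int(nrow(fd$panel), 2L * config$pop_size, replace = TRUE)
  H0 <- fd$panel[idx0, , drop = FALSE]
  if (config$burnin_generations > 0L) {
    H0 <- evolve(H0, config, config$burnin_generations, map,
                 active_sweeps = list(),
                 recomb_mult = config$burnin_recomb_mult)$panel
  }

  phase_of <- function(sw) if (is.null(sw$phase)) "both" else sw$phase
  sweeps1 <- Filter(function(sw) phase_of(sw) %in% c("both", "1"), config$sweep_loci)
  sweeps2 <- Filter(function(sw) phase_of(sw) %in% c("both", "2"), config$sweep_loci)

  e1 <- evolve(H0, config, config$generations_phase1, map, sweeps1)
  e2 <- evolve(e1$panel, config, config$generations_phase2, map, sweeps2)

  res <- sample_cohorts(list(H0, e1$panel, e2$panel), config, map)

  truth <- NULL
  if (length(config$sweep_loci)) {
    tr <- rbind(e1$traj, e2$traj[-1L, , drop = FALSE])
    truth <- data.frame(
      generation = rep(0:(nrow(tr) - 1L), ncol(tr)),
      locus = rep(colnames(tr), each = nrow(tr)),
      freq = as.vector(tr),
      stringsAsFactors = FALSE
    )
  }
  out <- c(res, list(truth = truth, config = config))
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Serial-cohort simulation:",
      paste(vapply(x$cohorts, nrow, 1L), collapse = "/"),
      "individuals (I/II/III),", nrow(x$map), "SNPs,",
      length(x$config$sweep_loci), "sweep locus/loci\n")
  invisible(x)
}

#' Write a simulation result to disk
#'
#' Emits each cohort as PLINK-style .ped/.map text and as a phased minimal
#' VCF, plus the truth trajectories as TSV and the configuration as a flat
#' `key=value` text file. All writers are deterministic.
#'
#' @param sim a [simulate_cohorts()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_sim_result <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (g in names(sim$cohorts)) {
    ped <- file.path(dir, paste0("cohort_", g, ".ped"))
    mp <- file.path(dir, paste0("cohort_", g, ".map"))
    vcf <- file.path(dir, paste0("cohort_", g, ".vcf"))
    write_ped_map(sim$cohorts[[g]], sim$map, ped, mp)
    write_vcf(sim$panels[[g]], sim$map, vcf, phased = TRUE)
    files <- c(files, ped, mp, vcf)
  }
  if (!is.null(sim$truth)) {
    tf <- file.path(dir, "truth.tsv")
    utils::write.table(sim$truth, tf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, tf)
  }
  cf <- file.path(dir, "config.txt")
  flat <- vapply(names(sim$config), function(k) {
    v <- sim$config[[k]]
    if (k == "sweep_loci") {
      v <- vapply(v, function(sw) paste0(sw$chrom, ":", sw$snp, ":", sw$s,
                                         ":", sw$phase), "")
    }
    paste0(k, "=", paste(unlist(v), collapse = ","))
  }, "")
  writeLines(unname(flat), cf)
  invisible(c(files, cf))
}

#' Simulate a bivariate per-SNP trait-effect table
#'
#' Draws standard bivariate-normal effects for two traits with a target
#' genome-wide correlation `effect_corr`, optionally with a different
#' (typically stronger negative) correlation inside designated genomic
#' intervals — emulating antagonistic pleiotropy concentrated in regions
#' carrying e.g. fertility genes.
#'
#' @param map `snp_map` giving SNP ids and positions.
#' @param effect_corr target correlation in \[-1, 1\] outside `intervals`.
#' @param intervals optional data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open, as from [read_bed_intervals()]) where `interval_corr` applies.
#' @param interval_corr target correlation inside `intervals`; either one
#'   value or one per interval row (later rows win where intervals overlap).
#' @param traits names of the two trait columns.
#' @param seed optional integer seed.
#' @return `data.frame`: `snp_id` plus one column per trait.
#' @export
simulate_effect_table <- function(map, effect_corr = -0.27,
                                  intervals = NULL, interval_corr = effect_corr,
                                  traits = c("trait1", "trait2"),
                                  seed = NULL) {
  stopifnot(abs(effect_corr) <= 1, all(abs(interval_corr) <= 1),
            length(traits) == 2L)
  if (!is.null(seed)) set.seed(seed)
  L <- nrow(map)
  rho <- rep(effect_corr, L)
  if (!is.null(intervals) && nrow(intervals)) {
    ic <- rep_len(interval_corr, nrow(intervals))
    for (k in seq_len(nrow(intervals))) {
      inside <- map$chrom == as.character(intervals$chrom[k]) &
        intervals$start[k] < map$pos & map$pos <= intervals$end[k]
      rho[inside] <- ic[k]
    }
  }
  e1 <- stats::rnorm(L)
  e2 <- rho * e1 + sqrt(1 - rho^2) * stats::rnorm(L)
  out <- data.frame(snp_id = map$snp_id, e1, e2, stringsAsFactors = FALSE)
  names(out)[2:3] <- traits
  out
}
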