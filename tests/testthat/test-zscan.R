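test_that("window construction truncates at chromosome edges", {
  map5 <- even_map(5)
  w <- build_windows(map5, "count", 3)
  expect_equal(w$l, c(1L, 1L, 2L, 3L, 4L))
  expect_equal(w$u, c(2L, 3L, 4L, 5L, 5L))

  # distance mode: +/- half the span around each center
  mapd <- snp_map(paste0("s", 1:4), "1", c(1, 400000, 800000, 1600000))
  wd <- build_windows(mapd, "distance", 1e6)
  expect_equal(wd$l[2], 1L)
  expect_equal(wd$u[2], 3L)   # SNP at 1.6 Mb is outside 0.4 +/- 0.5 Mb
  expect_equal(wd$l[4], 4L)   # nothing within 0.5 Mb of 1.6 Mb but itself

  # windows never leak across chromosomes
  map2 <- snp_map(paste0("s", 1:10), rep(c("1", "2"), each = 5),
                  rep(50000 * (1:5), 2))
  w2 <- build_windows(map2, "count", 5)
  expect_true(all(w2$l[1:5] >= 1 & w2$u[1:5] <= 5))
  expect_true(all(w2$l[6:10] >= 6 & w2$u[6:10] <= 10))
  expect_error(build_windows(map5, "count", 4), "odd")
})

test_that("windowed means match arithmetic and the naive oracle", {
  map3 <- even_map(3)
  tr <- structure(list(values = c(0.1, 0.2, 0.3), stat = "AFD",
                       comparison = c("I", "III"), map = map3),
                  class = "site_track")
  x <- longrange_mean(tr, build_windows(map3, "count", 3))
  expect_equal(x$X, c(0.15, 0.2, 0.25))

  # constant track stays constant
  trc <- structure(list(values = rep(0.4, 3), stat = "AFD",
                        comparison = c("I", "III"), map = map3),
                   class = "site_track")
  expect_equal(longrange_mean(trc, build_windows(map3, "count", 3))$X,
               rep(0.4, 3))

  # rolling implementation vs naive re-summation, with missing values,
  # both window modes, two chromosomes
  set.seed(71)
  map <- snp_map(paste0("s", 1:400), rep(c("1", "2"), each = 200),
                 rep(as.integer(cumsum(sample(10000:90000, 200, TRUE))), 2))
  S <- runif(400)
  S[sample(400, 30)] <- NA
  trr <- structure(list(values = S, stat = "AFD",
                        comparison = c("I", "III"), map = map),
                   class = "site_track")
  for (w in list(c("count", 11), c("distance", 5e5), c("distance", 2e6))) {
    ws <- build_windows(map, w[1], as.numeric(w[2]))
    expect_equal(longrange_mean(trr, ws)$X, naive_window_mean(S, ws),
                 tolerance = 1e-12)
  }
})

test_that("standardization is per-chromosome, centered, and affine-invariant", {
  map3 <- even_map(3)
  x <- structure(list(X = c(1, 2, 3), stat = "AFD", comparison = c("I", "III"),
                      windows = build_windows(map3, "count", 1), map = map3),
                 class = "x_track")
  z <- standardize(x)
  expect_equal(z$Z, c(-1, 0, 1))  # sample sd convention

  set.seed(72)
  map <- snp_map(paste0("s", 1:300), rep(c("1", "2"), each = 150),
                 rep(50000 * (1:150), 2))
  S <- c(runif(150), 10 + 5 * runif(150))  # very different scales
  tr <- structure(list(values = S, stat = "AFD", comparison = c("I", "III"),
                       map = map), class = "site_track")
  ws <- build_windows(map, "count", 7)
  z2 <- standardize(longrange_mean(tr, ws))
  for (ch in c("1", "2")) {
    idx <- which(map$chrom == ch)
    expect_lt(abs(mean(z2$Z[idx])), 1e-12)
    expect_equal(sd(z2$Z[idx]), 1, tolerance = 1e-12)
    # per-chromosome oracle recomputation
    xv <- naive_window_mean(S, ws)[idx]
    expect_equal(z2$Z[idx], (xv - mean(xv)) / sd(xv), tolerance = 1e-12)
  }

  # affine invariance: Z of a*S + b equals Z of S for a > 0
  tr2 <- structure(list(values = 3.7 * S + 0.2, stat = "AFD",
                        comparison = c("I", "III"), map = map),
                   class = "site_track")
  z3 <- standardize(longrange_mean(tr2, ws))
  expect_equal(z3$Z, z2$Z, tolerance = 1e-9)

  # constant chromosome is flagged, not standardized
  trc <- structure(list(values = rep(0.2, 300), stat = "AFD",
                        comparison = c("I", "III"), map = map),
                   class = "site_track")
  zc <- standardize(longrange_mean(trc, ws))
  expect_true(all(is.na(zc$Z)))
})

test_that("signature calling applies the peak-and-extend rule", {
  z <- make_ztrack(c(0, 2.5, 3.5, 2.2, 1.0), even_map(5))
  sig <- call_signatures(z)
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$start_bp, 100000)   # SNP 2
  expect_equal(sig$end_bp, 200000)     # SNP 4
  expect_equal(sig$peak_bp, 150000)    # SNP 3
  expect_equal(sig$n_snps, 3L)

  # no peak reaching 3: nothing called
  expect_equal(nrow(call_signatures(make_ztrack(c(2.9, 2.9, 2.9), even_map(3)))), 0L)

  # AFD is one-sided: a deeply negative excursion is not a signature
  expect_equal(nrow(call_signatures(make_ztrack(c(-3.5, -3.5, -3.5), even_map(3)))), 0L)

  # HD is two-sided and runs must be sign-consistent
  zh <- make_ztrack(c(3.5, 2.5, -2.5, -3.5), even_map(4), stat = "HD")
  sigh <- call_signatures(zh)
  expect_equal(nrow(sigh), 2L)
  expect_equal(sigh$sign, c(1, -1))

  # ties broken by the leftmost peak
  zt <- call_signatures(make_ztrack(c(3.2, 3.2, 2.1), even_map(3)))
  expect_equal(zt$peak_bp, 50000)
  expect_error(call_signatures(z, call_thresh = 2, extend_thresh = 3), ">=")
})

test_that("every called signature satisfies its own invariants", {
  sim <- tiny_sim(seed = 73, snps = 600L, len_bp = 3e7, pop = 150L,
                  gens = 15L, sweep_snp = 300L, cohorts = c(50L, 50L, 50L),
                  founders = 120L)
  ft <- group_frequencies(do.call(rbind, sim$cohorts), sim$groups, map = sim$map)
  tr <- afd(ft, "I", "III")
  n_called <- 0L
  for (w in c(1e6, 3e6)) {
    z <- standardize(longrange_mean(tr, build_windows(sim$map, "distance", w)))
    sig <- call_signatures(z)
    n_called <- n_called + nrow(sig)
    for (i in seq_len(nrow(sig))) {
      inside <- sim$map$pos >= sig$start_bp[i] & sim$map$pos <= sig$end_bp[i]
      expect_gte(max(z$Z[inside]), 3)
      expect_true(all(z$Z[inside] >= 2))
      expect_gte(abs(sig$peak_z[i]), 3)
    }
  }
  expect_gte(n_called, 1L)  # the implanted sweep is detected
})

test_that("merging across window sizes unions overlapping regions", {
  base <- list(chrom = "1", stat = "AFD", comparison = "I-III",
               window_mode = "distance")
  mk <- function(s, e, peak, z, w) {
    data.frame(chrom = "1", start_bp = s, end_bp = e, peak_bp = peak,
               peak_z = z, sign = 1, n_snps = 3L, stat = "AFD",
               window_mode = "distance", window_size = w,
               comparison = "I-III", stringsAsFactors = FALSE)
  }
  # disjoint inputs concatenate
  m1 <- merge_across_windows(list(mk(1e6, 2e6, 1.5e6, 3.5, 5e5),
                                  mk(5e6, 6e6, 5.5e6, 4.2, 1e6)))
  expect_equal(nrow(m1), 2L)
  # nested intervals collapse to the covering one, keeping the best peak
  m2 <- merge_across_windows(list(mk(1e6, 4e6, 2e6, 3.2, 1e6),
                                  mk(2e6, 3e6, 2.5e6, 5.0, 5e5)))
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$start_bp, 1e6)
  expect_equal(m2$end_bp, 4e6)
  expect_equal(m2$best_peak_z, 5.0)
  expect_equal(m2$n_contributing, 2L)
  # merged count never exceeds the sum of inputs
  expect_lte(nrow(m1), 2L)
  expect_error(
    merge_across_windows(list(mk(1e6, 2e6, 1.5e6, 3.5, 5e5),
                              transform(mk(3e6, 4e6, 3.5e6, 3.5, 5e5),
                                        comparison = "II-III"))),
    "different comparisons"
  )
})
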