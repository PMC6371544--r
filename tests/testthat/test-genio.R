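test_that("ped/map parsing counts the alphabetically lower allele", {
  tdir <- withr::local_tempdir()
  ped <- file.path(tdir, "x.ped"); mp <- file.path(tdir, "x.map")
  writeLines(c("F1 s1 0 0 0 -9 A G 0 0",
               "F1 s2 0 0 0 -9 G G C C"), ped)
  writeLines(c("1 snp1 0 1000", "1 snp2 0 2000"), mp)
  r <- read_ped_map(ped, mp)
  expect_equal(r$map$allele1, c("A", "C"))
  expect_equal(unname(r$geno[, "snp1"]), c(1L, 0L))   # A-dosage
  expect_true(is.na(r$geno["s1", "snp2"]))            # "0 0" is missing
  expect_equal(unname(r$geno["s2", "snp2"]), 2L)
})

test_that("SNPs with unknown chromosome positions are dropped on read", {
  tdir <- withr::local_tempdir()
  ped <- file.path(tdir, "x.ped"); mp <- file.path(tdir, "x.map")
  writeLines(c("F1 s1 0 0 0 -9 A G C C T T",
               "F1 s2 0 0 0 -9 G G C T T A"), ped)
  writeLines(c("1 snp1 0 1000", "0 snp2 0 0", "2 snp3 0 500"), mp)
  expect_message(r <- read_ped_map(ped, mp), "dropping 1")
  expect_equal(r$map$snp_id, c("snp1", "snp3"))
  expect_equal(unname(r$geno[, "snp3"]), c(0L, 1L))
})

test_that("ped/map errors name the offending SNP or line", {
  tdir <- withr::local_tempdir()
  ped <- file.path(tdir, "x.ped"); mp <- file.path(tdir, "x.map")
  writeLines("1 snp1 0 1000", mp)
  writeLines(c("F1 s1 0 0 0 -9 A G", "F1 s2 0 0 0 -9 C T"), ped)
  expect_error(read_ped_map(ped, mp), "snp1")
  writeLines(c("F1 s1 0 0 0 -9 A G", "F1 s2 0 0 0 -9 C"), ped)
  expect_error(read_ped_map(ped, mp), "line 2")
})

test_that("ped/map round-trips a simulated cohort exactly", {
  sim <- tiny_sim(seed = 51, snps = 30L, cohorts = c(12L, 12L, 12L))
  geno <- sim$cohorts$I
  # text PED cannot preserve the unobserved allele of a monomorphic SNP;
  # restrict the bit-exactness claim to SNPs where both alleles are seen
  poly <- apply(geno, 2, function(d) any(d > 0, na.rm = TRUE) &&
                  any(d < 2, na.rm = TRUE))
  geno <- geno[, poly, drop = FALSE]
  map <- sim$map[poly, ]
  class(map) <- c("snp_map", "data.frame")
  tdir <- withr::local_tempdir()
  ped <- file.path(tdir, "c.ped"); mp <- file.path(tdir, "c.map")
  write_ped_map(geno, map, ped, mp)
  r <- read_ped_map(ped, mp)
  expect_identical(r$geno[, colnames(geno)], geno)
  expect_equal(r$map$pos, map$pos)
  expect_equal(r$map$chrom, map$chrom)
  expect_equal(r$map$allele1, map$allele1)
})

test_that("VCF reading re-orients REF/ALT to the allele1 convention", {
  tdir <- withr::local_tempdir()
  vcf <- file.path(tdir, "t.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\trs1\tG\tA\t.\tPASS\t.\tGT\t0/1\t1/1",
    "1\t200\trs2\tA\tC\t.\tPASS\t.\tGT\t0/0\t./.",
    "1\t300\trs3\tC\tT,G\t.\tPASS\t.\tGT\t0/1\t0/0"
  ), vcf)
  expect_message(r <- read_vcf(vcf), "skipped 1")
  expect_equal(r$map$snp_id, c("rs1", "rs2"))
  expect_equal(r$map$allele1, c("A", "A"))
  # rs1: REF=G ALT=A, so allele1 = A and dosage counts A (the ALT here)
  expect_equal(unname(r$geno[, "rs1"]), c(1L, 2L))
  expect_equal(unname(r$geno[, "rs2"]), c(2L, NA_integer_))
  expect_null(r$panel)  # unphased
})

test_that("phase detection: panel only when every GT is phased and complete", {
  tdir <- withr::local_tempdir()
  vcf <- file.path(tdir, "p.vcf")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t1|0\t0|0"
  )
  writeLines(lines, vcf)
  r <- read_vcf(vcf)
  expect_false(is.null(r$panel))
  expect_equal(dim(r$panel), c(4L, 2L))
  # s1 is 0|1 at rs1 with REF=A=allele1: haplotype codes 0 then 1
  expect_equal(unname(r$panel[1:2, "rs1"]), c(0L, 1L))

  lines[4] <- "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1\t1|1"
  writeLines(lines, vcf)
  expect_null(read_vcf(vcf)$panel)
})

test_that("VCF write/read round-trips dosages and phased panels", {
  sim <- tiny_sim(seed = 52, snps = 25L, cohorts = c(10L, 10L, 10L))
  tdir <- withr::local_tempdir()
  v1 <- file.path(tdir, "g.vcf"); v2 <- file.path(tdir, "h.vcf")
  write_vcf(sim$cohorts$II, sim$map, v1)
  r1 <- read_vcf(v1)
  expect_identical(unname(r1$geno), unname(sim$cohorts$II))
  expect_equal(r1$map$pos, sim$map$pos)

  write_vcf(sim$panels$II, sim$map, v2, phased = TRUE)
  r2 <- read_vcf(v2)
  expect_identical(unname(r2$panel), unname(sim$panels$II))
})

test_that("orientation canonicalization is an involution", {
  # the same genotypes presented with swapped REF/ALT give complementary
  # dosages on disk but identical canonical matrices after reading
  tdir <- withr::local_tempdir()
  a <- file.path(tdir, "a.vcf"); b <- file.path(tdir, "b.vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2")
  writeLines(c(hdr, "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0"), a)
  writeLines(c(hdr, "1\t100\trs1\tG\tA\t.\tPASS\t.\tGT\t0/1\t1/1"), b)
  ra <- read_vcf(a); rb <- read_vcf(b)
  expect_identical(ra$geno, rb$geno)
  expect_identical(ra$map, rb$map)
})

test_that("BED intervals load, validate and answer containment queries", {
  tdir <- withr::local_tempdir()
  bed <- file.path(tdir, "g.bed")
  writeLines("23\t25160000\t28510000\tMHC", bed)
  iv <- read_bed_intervals(bed)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$chrom, "23")
  expect_equal(iv$end - iv$start, 28510000 - 25160000)
  expect_true(interval_contains(iv, "23", 26000000))
  expect_false(interval_contains(iv, "23", 25160000))  # start is 0-based open
  expect_true(interval_contains(iv, "23", 25160001))
  expect_false(interval_contains(iv, "1", 26000000))

  writeLines(character(0), bed)
  expect_equal(nrow(read_bed_intervals(bed)), 0L)

  writeLines("1\t500\t400\tbad", bed)
  expect_error(read_bed_intervals(bed), "line 1")
})

test_that("a simulation result is exported completely and re-readable", {
  sim <- tiny_sim(seed = 54, snps = 20L, cohorts = c(8L, 8L, 8L))
  tdir <- withr::local_tempdir()
  files <- write_sim_result(sim, tdir)
  expect_true(all(file.exists(files)))
  r <- read_vcf(file.path(tdir, "cohort_III.vcf"))
  expect_identical(unname(r$panel), unname(sim$panels$III))
  truth <- utils::read.delim(file.path(tdir, "truth.tsv"))
  expect_equal(truth$freq, sim$truth$freq, tolerance = 1e-12)
  cfgtxt <- readLines(file.path(tdir, "config.txt"))
  expect_true(any(grepl("^pop_size=80$", cfgtxt)))
})

test_that("effect tables round-trip through TSV", {
  eff <- simulate_effect_table(even_map(20), effect_corr = -0.5, seed = 53)
  tdir <- withr::local_tempdir()
  f <- file.path(tdir, "e.tsv")
  write_effect_table(eff, f)
  r <- read_effect_table(f)
  expect_equal(r$snp_id, eff$snp_id)
  expect_equal(r$trait1, eff$trait1, tolerance = 1e-12)
})
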