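#' Read PLINK-style .ped/.map text files
#'
#' Parses whitespace-delimited PLINK text genotypes into a dosage matrix and a
#' [snp_map()]. Alleles at each SNP are re-oriented so that `allele1` is the
#' alphabetically lower base, and dosages count copies of `allele1`. The PLINK
#' missing code "0" becomes `NA`. At a monomorphic SNP the unobserved allele is
#' recorded as the placeholder "N".
#'
#' @param ped_path path to the .ped file (6 leading columns, then two allele
#'   columns per SNP).
#' @param map_path path to the .map file (3 or 4 columns: chrom, snp_id,
#'   \[cM,\] bp).
#' @return list with elements `geno` (samples x SNPs integer dosage matrix of
#'   allele1 copies) and `map` (a `snp_map`).
#' @seealso [write_ped_map()], [read_vcf()]
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  mfields <- strsplit(trimws(map_lines), "[ \t]+")
  ncol_map <- unique(lengths(mfields))
  if (length(ncol_map) != 1L || !ncol_map %in% c(3L, 4L)) {
    stop("map file must have 3 or 4 whitespace-delimited columns on every line")
  }
  m <- do.call(rbind, mfields)
  pos_col <- ncol_map  # bp is the last column
  chrom <- m[, 1L]
  snp_id <- m[, 2L]
  pos <- as.integer(m[, pos_col])
  n_snp <- length(snp_id)
  known <- chrom != "0" & !is.na(pos) & pos > 0L
  if (!all(known)) {
    message("read_ped_map: dropping ", sum(!known),
            " SNP(s) with unknown chromosome position")
  }

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  pfields <- strsplit(trimws(ped_lines), "[ \t]+")
  want <- 6L + 2L * n_snp
  for (i in seq_along(pfields)) {
    if (length(pfields[[i]]) != want) {
      stop(sprintf(
        "ped line %d has %d fields, expected %d (6 + 2 alleles x %d SNPs)",
        i, length(pfields[[i]]), want, n_snp
      ))
    }
  }
  p <- do.call(rbind, pfields)
  sample_ids <- p[, 2L]
  if (anyDuplicated(sample_ids)) sample_ids <- paste(p[, 1L], p[, 2L], sep = "_")

  a_odd <- p[, 6L + seq(1L, 2L * n_snp, by = 2L), drop = FALSE]
  a_even <- p[, 6L + seq(2L, 2L * n_snp, by = 2L), drop = FALSE]
  a_odd[a_odd == "0"] <- NA
  a_even[a_even == "0"] <- NA

  a_odd <- a_odd[, known, drop = FALSE]
  a_even <- a_even[, known, drop = FALSE]
  snp_id <- snp_id[known]; chrom <- chrom[known]; pos <- pos[known]
  n_snp <- length(snp_id)

  allele1 <- allele2 <- character(n_snp)
  geno <- matrix(NA_integer_, nrow = nrow(p), ncol = n_snp,
                 dimnames = list(sample_ids, snp_id))
  for (j in seq_len(n_snp)) {
    obs <- sort(unique(c(a_odd[, j], a_even[, j])))
    obs <- obs[!is.na(obs)]
    if (length(obs) > 2L) {
      stop("SNP ", snp_id[j], " has more than two alleles: ",
           paste(obs, collapse = "/"))
    }
    if (length(obs) == 0L) obs <- c("A", "N")      # fully missing column
    if (length(obs) == 1L) {
      obs <- sort(c(obs, "N"))
      if (obs[1L] == obs[2L]) obs <- c(obs[1L], "Z")
    }
    allele1[j] <- obs[1L]
    allele2[j] <- obs[2L]
    d <- (a_odd[, j] == allele1[j]) + (a_even[, j] == allele1[j])
    geno[, j] <- as.integer(d)                     # NA propagates
  }
  map <- snp_map(snp_id, chrom, pos, allele1, allele2)
  list(geno = geno, map = map)
}

#' Write a dosage matrix as PLINK-style .ped/.map text
#'
#' Inverse of [read_ped_map()]: dosages of allele1 become allele pairs
#' (heterozygotes written "allele1 allele2"), missing dosages "0 0".
#'
#' @param geno samples x SNPs integer dosage matrix (allele1 copies).
#' @param map matching `snp_map`.
#' @param ped_path,map_path output paths.
#' @export
write_ped_map <- function(geno, map, ped_path, map_path) {
  stopifnot(ncol(geno) == nrow(map))
  utils::write.table(
    data.frame(map$chrom, map$snp_id, 0L, map$pos),
    map_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  n_snp <- nrow(map)
  alle <- matrix("0", nrow = nrow(geno), ncol = 2L * n_snp)
  for (j in seq_len(n_snp)) {
    d <- geno[, j]
    o1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, map$allele1[j], map$allele2[j]))
    o2 <- ifelse(is.na(d), "0", ifelse(d == 2L, map$allele1[j], map$allele2[j]))
    alle[, 2L * j - 1L] <- o1
    alle[, 2L * j] <- o2
  }
  ids <- rownames(geno)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(geno)))
  lead <- cbind("FAM", ids, "0", "0", "0", "-9")
  utils::write.table(cbind(lead, alle), ped_path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  invisible(NULL)
}

#' Read genotypes (and phased haplotypes) from a VCF
#'
#' Reads a VCF 4.x file with a GT field through \pkg{vcfR}. Only biallelic
#' SNP records are kept (multiallelic records are skipped with a message).
#' REF/ALT are re-oriented to the allele1 convention (alphabetically lower
#' base), with dosages flipped as needed. A haplotype panel is returned only
#' when every genotype is phased ("|" separator) and none is missing.
#'
#' @param path path to an (uncompressed or gzipped) VCF file.
#' @return list with `geno` (allele1 dosage matrix), `map` (`snp_map`), and
#'   `panel` (0/1 haplotype matrix, 0 = allele1, or `NULL` when any genotype
#'   is unphased or missing).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    message("read_vcf: skipped ", n_skip, " non-biallelic-SNP record(s)")
  }
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ref <- ref[keep]
  alt <- alt[keep]
  snp_id <- fix[, "ID"]
  blank <- is.na(snp_id) | snp_id == "."
  snp_id[blank] <- paste(fix[blank, "CHROM"], fix[blank, "POS"], sep = "_")

  ref_is_a1 <- ref < alt
  allele1 <- ifelse(ref_is_a1, ref, alt)
  allele2 <- ifelse(ref_is_a1, alt, ref)
  map <- snp_map(snp_id, fix[, "CHROM"], as.integer(fix[, "POS"]), allele1, allele2)

  # parse GT strings; gt is SNPs x samples
  sep_bar <- grepl("|", gt, fixed = TRUE)
  miss <- is.na(gt) | grepl("\\.", gt)
  a_first <- suppressWarnings(as.integer(substr(gt, 1L, 1L)))
  a_second <- suppressWarnings(as.integer(substr(gt, 3L, 3L)))
  alt_count <- a_first + a_second
  ref_count <- 2L - alt_count
  dos <- ifelse(rep(ref_is_a1, ncol(gt)), ref_count, alt_count)
  dos[miss] <- NA_integer_
  geno <- t(matrix(as.integer(dos), nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = dimnames(gt)))
  colnames(geno) <- snp_id

  panel <- NULL
  if (!any(miss) && all(sep_bar)) {
    # 0 = allele1 coding per haplotype
    h1 <- ifelse(rep(ref_is_a1, ncol(gt)), a_first, 1L - a_first)
    h2 <- ifelse(rep(ref_is_a1, ncol(gt)), a_second, 1L - a_second)
    h1 <- matrix(h1, nrow = nrow(gt))
    h2 <- matrix(h2, nrow = nrow(gt))
    panel <- matrix(0L, nrow = 2L * ncol(gt), ncol = nrow(gt))
    panel[seq(1L, nrow(panel), 2L), ] <- t(h1)
    panel[seq(2L, nrow(panel), 2L), ] <- t(h2)
    rownames(panel) <- paste(rep(colnames(gt), each = 2L), c("h1", "h2"), sep = "_")
    colnames(panel) <- snp_id
  }
  list(geno = geno, map = map, panel = panel)
}

#' Write a minimal VCF 4.2 file
#'
#' Emits one GT-only VCF record per SNP with REF = allele1, ALT = allele2
#' (deterministic orientation, so write/read round-trips are exact). Given a
#' haplotype panel, genotypes are written phased with "|"; given a dosage
#' matrix, unphased with "/".
#'
#' @param x dosage matrix (samples x SNPs) or 0/1 haplotype panel
#'   (haplotypes x SNPs, even row count) when `phased = TRUE`.
#' @param map matching `snp_map`.
#' @param path output path.
#' @param phased logical; interpret `x` as a haplotype panel.
#' @export
write_vcf <- function(x, map, path, phased = FALSE) {
  stopifnot(ncol(x) == nrow(map))
  if (phased) {
    stopifnot(nrow(x) %% 2L == 0L)
    odd <- seq(1L, nrow(x), 2L)
    ids <- sub("_h1$", "", rownames(x)[odd])
    if (is.null(ids) || !length(ids)) ids <- paste0("ind", seq_along(odd))
    gt <- matrix(paste0(t(x[odd, , drop = FALSE]), "|", t(x[odd + 1L, , drop = FALSE])),
                 nrow = nrow(map))
  } else {
    ids <- rownames(x)
    if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(x)))
    code <- c(`0` = "1/1", `1` = "0/1", `2` = "0/0")  # dosage of allele1 = REF
    gt <- matrix("./.", nrow = nrow(map), ncol = nrow(x))
    ok <- !is.na(t(x))
    gt[ok] <- code[as.character(t(x)[ok])]
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  body <- paste(map$chrom, map$pos, map$snp_id, map$allele1, map$allele2,
                ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(NULL)
}

#' Read gene/region intervals from a BED file
#'
#' Validates and imports BED3+ records via \pkg{rtracklayer}. Intervals are
#' returned in the internal convention: 0-based half-open `[start, end)`,
#' exactly as stored in BED.
#'
#' @param path path to a BED file (3+ tab- or space-delimited columns; track
#'   and comment lines ignored).
#' @return `data.frame` with columns `chrom`, `start` (0-based), `end`
#'   (exclusive), `name` (4th column or a synthesized label).
#' @export
read_bed_intervals <- function(path) {
  lines <- readLines(path)
  dat <- which(nzchar(trimws(lines)) &
                 !grepl("^(track|browser|#)", trimws(lines)))
  if (length(dat) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      stringsAsFactors = FALSE))
  }
  for (i in dat) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 3L) stop("BED line ", i, ": fewer than 3 columns")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) stop("BED line ", i, ": non-numeric coordinates")
    if (e <= s) stop("BED line ", i, ": end <= start")
  }
  gr <- rtracklayer::import(path, format = "BED")
  df <- as.data.frame(gr)
  nm <- if ("name" %in% names(df) && !all(is.na(df$name))) as.character(df$name) else
    paste0("iv", seq_len(nrow(df)))
  data.frame(
    chrom = as.character(df$seqnames),
    start = df$start - 1,          # back to 0-based half-open
    end = df$end,
    name = nm,
    stringsAsFactors = FALSE
  )
}

#' Point-in-interval query
#'
#' @param intervals data.frame as returned by [read_bed_intervals()]
#'   (0-based half-open).
#' @param chrom chromosome label of the query point.
#' @param pos 1-based bp position of the query point.
#' @return logical vector, one element per interval.
#' @export
interval_contains <- function(intervals, chrom, pos) {
  intervals$chrom == as.character(chrom) &
    intervals$start < pos & pos <= intervals$end
}

#' Read / write a per-SNP trait-effect table
#'
#' Tab-delimited with a header row: `snp_id` then one numeric column per
#' trait.
#'
#' @param path file path.
#' @return `data.frame` with `snp_id` and one column per trait.
#' @export
read_effect_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "snp_id") stop("effect table must start with a snp_id column")
  if (ncol(tab) < 2L) stop("effect table needs at least one trait column")
  tab
}

#' @rdname read_effect_table
#' @param effects effect table data.frame (first column `snp_id`).
#' @export
write_effect_table <- function(effects, path) {
  utils::write.table(effects, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
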