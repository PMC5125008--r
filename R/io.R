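# PLINK text and VCF input, PLINK text output, and a versioned study cache.

#' Read a study from PLINK text files (.ped/.map)
#'
#' Parses whitespace-delimited PLINK pedigree/map files.  Each `.ped` row
#' carries six leading fields (family, individual, paternal, maternal, sex,
#' phenotype) followed by two allele calls per SNP; the `.map` file supplies
#' chromosome, SNP identifier, genetic distance and base-pair position.
#'
#' Allele calls are mapped to minor-allele counts, the minor allele being the
#' less frequent allele pooled over all subjects (ties at 50% broken towards
#' the lexicographically smaller character).  `0` allele calls denote missing
#' genotypes.  Phenotype 2 becomes case (+1), 1 becomes control (-1);
#' subjects with phenotype 0 or -9 are dropped with a warning.
#'
#' @param pedPath,mapPath paths to the `.ped` and `.map` files.
#' @return a [GenotypeStudy-class].
#' @seealso [writePlinkText()]
#' @export
readPlinkText <- function(pedPath, mapPath) {
  map <- data.table::fread(mapPath, header = FALSE, colClasses = "character",
                           data.table = FALSE)
  if (ncol(map) < 4L) stop("malformed .map file: expected 4 columns",
                           call. = FALSE)
  d <- nrow(map)
  ped <- data.table::fread(pedPath, header = FALSE, colClasses = "character",
                           data.table = FALSE)
  if (ncol(ped) != 6L + 2L * d)
    stop(sprintf(".ped/.map mismatch: %d allele columns for %d mapped SNPs",
                 ncol(ped) - 6L, d), call. = FALSE)
  pheno_raw <- ped[[6L]]
  if (!all(pheno_raw %in% c("1", "2", "0", "-9")))
    stop("phenotype column must be one of 1, 2, 0, -9", call. = FALSE)
  keep <- pheno_raw %in% c("1", "2")
  if (any(!keep)) {
    warning(sprintf("dropping %d subjects with missing phenotype",
                    sum(!keep)))
    ped <- ped[keep, , drop = FALSE]
  }
  n <- nrow(ped)
  y <- ifelse(ped[[6L]] == "2", 1L, -1L)
  sampleIds <- make.unique(ped[[2L]])

  g <- matrix(NA_integer_, nrow = d, ncol = n)
  major <- minor <- character(d)
  for (j in seq_len(d)) {
    a1 <- ped[[6L + 2L * j - 1L]]
    a2 <- ped[[6L + 2L * j]]
    missing <- a1 == "0" | a2 == "0"
    alleles <- c(a1[!missing], a2[!missing])
    lev <- sort(unique(alleles))
    if (length(lev) > 2L)
      stop(sprintf("SNP %s has more than two alleles: %s",
                   map[[2L]][j], paste(lev, collapse = "/")), call. = FALSE)
    if (length(lev) == 0L) lev <- c("A", "N")      # fully missing column
    if (length(lev) == 1L) lev <- c(lev, "N")      # monomorphic: placeholder
    counts <- c(sum(alleles == lev[1L]), sum(alleles == lev[2L]))
    # minor = strictly less frequent; at a tie the lexicographically
    # smaller character (lev[1]) is declared minor
    minorIdx <- if (counts[2L] < counts[1L]) 2L else 1L
    minor[j] <- lev[minorIdx]
    major[j] <- lev[c(2L, 1L)[minorIdx]]
    gj <- (a1 == minor[j]) + (a2 == minor[j])
    gj[missing] <- NA_integer_
    g[j, ] <- as.integer(gj)
  }
  info <- DataFrame(snp_id = map[[2L]], chromosome = map[[1L]],
                    position = as.integer(map[[4L]]),
                    allele_major = major, allele_minor = minor)
  GenotypeStudy(g, y, snpInfo = info, sampleIds = sampleIds)
}

#' Write a study as PLINK text files
#'
#' @param study a [GenotypeStudy-class].
#' @param basePath path prefix; `<basePath>.ped` and `<basePath>.map` are
#'   written.
#' @return invisibly, the two file paths.
#' @export
writePlinkText <- function(study, basePath) {
  g <- genotypes(study)
  info <- snpInfo(study)
  y <- phenotypes(study)
  n <- nSubjects(study)
  d <- nSnps(study)
  map <- data.frame(chrom = info$chromosome, snp = info$snp_id,
                    cm = 0, pos = info$position)
  mapPath <- paste0(basePath, ".map")
  pedPath <- paste0(basePath, ".ped")
  write.table(map, mapPath, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  allele <- matrix("0", nrow = 2L * d, ncol = n)
  for (j in seq_len(d)) {
    gj <- g[j, ]
    a1 <- ifelse(is.na(gj), "0", ifelse(gj >= 1L, info$allele_minor[j],
                                        info$allele_major[j]))
    a2 <- ifelse(is.na(gj), "0", ifelse(gj == 2L, info$allele_minor[j],
                                        info$allele_major[j]))
    allele[2L * j - 1L, ] <- a1
    allele[2L * j, ] <- a2
  }
  ids <- colData(study)$sample_id
  lead <- cbind(ids, ids, "0", "0", "0", ifelse(y == 1L, "2", "1"))
  ped <- cbind(lead, t(allele))
  write.table(ped, pedPath, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(ped = pedPath, map = mapPath))
}

#' Read a study from a VCF plus a phenotype table
#'
#' Consumes the GT field of biallelic records of a VCF v4.x file.
#' ALT-allele counts are re-oriented so that the stored value always counts
#' the study-wide minor allele (pooled cases + controls).  Multi-allelic
#' records are skipped with a warning.
#'
#' @param vcfPath path to a VCF file.
#' @param phenotypeTsv path to a tab-separated table with columns
#'   `sample_id` and `phenotype`; phenotypes may be coded 1/2 (control/case)
#'   or -1/+1.  Every sample in the VCF must appear in the table.
#' @return a [GenotypeStudy-class].
#' @export
readVcf <- function(vcfPath, phenotypeTsv) {
  vcf <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = 7L,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warning(sprintf("skipping %d multi-allelic records", sum(multi)))
  }
  gt <- vcfR::extract.gt(vcf)
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  d <- nrow(gt)
  samples <- colnames(gt)

  ph <- read.table(phenotypeTsv, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("sample_id", "phenotype") %in% colnames(ph)))
    stop("phenotype table needs columns 'sample_id' and 'phenotype'",
         call. = FALSE)
  missing <- setdiff(samples, ph$sample_id)
  if (length(missing))
    stop(sprintf("samples absent from phenotype table: %s",
                 paste(head(missing, 5), collapse = ", ")), call. = FALSE)
  phv <- ph$phenotype[match(samples, ph$sample_id)]
  if (!all(phv %in% c("1", "2", "-1", "+1")))
    stop("phenotypes must be coded 1/2 or -1/+1", call. = FALSE)
  # a "-1" anywhere marks the +1/-1 coding (then "1" is a case); otherwise
  # PLINK-style 1 = control, 2 = case
  y <- if (any(phv == "-1")) ifelse(phv %in% c("1", "+1"), 1L, -1L)
       else ifelse(phv == "2", 1L, -1L)

  alt <- gsub("\\|", "/", gt)
  cnt <- matrix(NA_integer_, d, length(samples))
  cnt[alt == "0/0"] <- 0L
  cnt[alt %in% c("0/1", "1/0")] <- 1L
  cnt[alt == "1/1"] <- 2L
  bad <- !is.na(alt) & !alt %in% c("0/0", "0/1", "1/0", "1/1")
  if (any(bad)) cnt[bad] <- NA_integer_

  refA <- fix[, "REF"]; altA <- fix[, "ALT"]
  major <- refA; minor <- altA
  for (j in seq_len(d)) {
    nn <- sum(!is.na(cnt[j, ]))
    altFreq <- if (nn) sum(cnt[j, ], na.rm = TRUE) / (2 * nn) else 0
    flip <- altFreq > 0.5 ||
      (altFreq == 0.5 && refA[j] < altA[j])   # tie: lexicographic minor
    if (flip) {
      cnt[j, ] <- 2L - cnt[j, ]
      major[j] <- altA[j]; minor[j] <- refA[j]
    }
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  info <- DataFrame(snp_id = make.unique(ids), chromosome = fix[, "CHROM"],
                    position = as.integer(fix[, "POS"]),
                    allele_major = major, allele_minor = minor)
  GenotypeStudy(cnt, y, snpInfo = info, sampleIds = samples)
}

# versioned binary cache --------------------------------------------------

.CACHE_VERSION <- "combiscreen-cache-1"

#' Cache a study to a compact binary file
#'
#' Serializes the study together with an explicit format version tag, so a
#' stale cache is rejected on read rather than silently misread.
#'
#' @param study a [GenotypeStudy-class].
#' @param path destination file.
#' @return invisibly, `path`.
#' @export
writeStudyCache <- function(study, path) {
  saveRDS(list(version = .CACHE_VERSION, study = study), path)
  invisible(path)
}

#' @rdname writeStudyCache
#' @export
readStudyCache <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, .CACHE_VERSION))
    stop("unrecognized study cache version", call. = FALSE)
  obj$study
}
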