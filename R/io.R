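## File formats: PLINK 1 .bed/.bim/.fam, a TSV genotype dialect, GMT gene
## sets, gene annotations, and typed TSV tables. All tables are TSV with
## header, UTF-8, '.' decimal, NA sentinel "NA". Genomic coordinates are
## 1-based closed internally; BED-style input is converted at the
## boundary.

## 256 x 4 lookup table: byte -> four allele doses. PLINK 1 bit pairs
## (low bits first): 00 hom A1 -> dose 2, 11 hom A2 -> dose 0,
## 10 het -> NA (inbred-line convention: only homozygous calls are used),
## 01 missing -> NA.
.plink_lut <- local({
  lut <- matrix(NA_real_, 256, 4)
  dec <- c(`0` = 2, `1` = NA, `2` = NA, `3` = 0)
  for (b in 0:255) {
    codes <- bitwAnd(bitwShiftR(b, c(0L, 2L, 4L, 6L)), 3L)
    lut[b + 1, ] <- dec[as.character(codes)]
  }
  lut
})

#' Read PLINK 1 binary genotypes
#'
#' Decodes a SNP-major `.bed` (magic bytes `0x6C 0x1B`, mode `0x01`) with
#' its `.bim`/`.fam` companions. Heterozygote calls are converted to
#' missing: the pipeline analyses fully inbred lines and uses only
#' homozygous calls.
#'
#' @param prefix path prefix; `.bed`, `.bim`, `.fam` are appended unless
#'   the explicit paths are given.
#' @param bed,bim,fam explicit file paths.
#' @return a [genotype_matrix()].
#' @export
read_plink <- function(prefix, bed = paste0(prefix, ".bed"),
                       bim = paste0(prefix, ".bim"),
                       fam = paste0(prefix, ".fam")) {
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              colClasses = c("character", "character",
                                             "numeric", "integer",
                                             "character", "character"))
  n <- nrow(fam_df); m <- nrow(bim_df)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop2("%s is not a PLINK 1 .bed file (bad magic bytes)", bed)
  if (raw[3] != as.raw(0x01))
    stop2("%s is not SNP-major (mode byte %s)", bed, format(raw[3]))
  bpm <- ceiling(n / 4)
  if (length(raw) != 3 + bpm * m)
    stop2(".bed size (%d bytes) does not match %d lines x %d markers from .fam/.bim",
          length(raw), n, m)
  codes <- .plink_lut[as.integer(raw[-(1:3)]) + 1L, , drop = FALSE]
  doses <- matrix(as.numeric(t(codes)), nrow = 4 * bpm, ncol = m)[seq_len(n), ,
                                                                  drop = FALSE]
  map <- data.frame(chrom = bim_df[[1]], pos = bim_df[[4]], id = bim_df[[2]],
                    a1 = bim_df[[5]], a2 = bim_df[[6]],
                    stringsAsFactors = FALSE)
  genotype_matrix(doses, map, as.character(fam_df[[2]]))
}

#' Write PLINK 1 binary genotypes
#'
#' Inverse of [read_plink()]: doses 2/0 become homozygous A1/A2 calls and
#' NA becomes the missing code (heterozygotes never occur for inbred
#' lines).
#'
#' @param G a [genotype_matrix()].
#' @param prefix output path prefix (`.bed`, `.bim`, `.fam` are written).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(G, prefix) {
  n <- nrow(G$doses); m <- ncol(G$doses)
  bpm <- ceiling(n / 4)
  code <- matrix(1L, 4 * bpm, m)             # 01 = missing
  d <- G$doses
  code[seq_len(n), ][!is.na(d) & d == 2] <- 0L
  code[seq_len(n), ][!is.na(d) & d == 0] <- 3L
  pad <- seq_len(4 * bpm) > n
  code[pad, ] <- 0L                          # padding bits are zero
  i4 <- matrix(seq_len(4 * bpm), nrow = 4)
  bytes <- code[i4[1, ], ] + bitwShiftL(code[i4[2, ], ], 2L) +
    bitwShiftL(code[i4[3, ], ], 4L) + bitwShiftL(code[i4[4, ], ], 6L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  utils::write.table(
    data.frame(G$map$chrom, G$map$id, 0, G$map$pos, G$map$a1, G$map$a2),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(G$line_ids, G$line_ids, 0, 0, 0, -9),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read and write the TSV genotype dialect
#'
#' Two files: `<prefix>.map.tsv` (marker metadata) and
#' `<prefix>.doses.tsv` (line column followed by one dose column per
#' marker).
#'
#' @param G a [genotype_matrix()].
#' @param prefix path prefix.
#' @return [read_genotypes_tsv()] returns a [genotype_matrix()];
#'   [write_genotypes_tsv()] returns `prefix` invisibly.
#' @export
write_genotypes_tsv <- function(G, prefix) {
  write_tsv(G$map, paste0(prefix, ".map.tsv"))
  write_tsv(data.frame(line = G$line_ids, G$doses, check.names = FALSE),
            paste0(prefix, ".doses.tsv"))
  invisible(prefix)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(prefix) {
  map <- read_tsv(paste0(prefix, ".map.tsv"))
  dt <- read_tsv(paste0(prefix, ".doses.tsv"))
  doses <- as.matrix(dt[, -1, drop = FALSE])
  genotype_matrix(doses, map, as.character(dt$line))
}

#' Read a GMT gene-set file
#'
#' One set per line: id, description, then member gene ids. Single-gene
#' sets are retained at read time and filtered at feature building.
#'
#' @param path GMT file.
#' @return named list mapping set id to gene ids.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets)))
    stop2("duplicate gene-set ids in %s: %s", path,
          paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of gene-id vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene annotations
#'
#' TSV format: header with `gene`, `chrom`, `start`, `end` (1-based
#' closed intervals). BED format: no header, columns chrom, start, end,
#' gene; 0-based half-open intervals are converted to 1-based closed
#' (`start + 1`).
#'
#' @param path input file.
#' @param format `"tsv"` or `"bed"`.
#' @return data.frame `gene`, `chrom`, `start`, `end`.
#' @export
read_annotations <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    ann <- read_tsv(path)
    need <- c("gene", "chrom", "start", "end")
    if (!all(need %in% names(ann)))
      stop2("annotation TSV must have columns %s", paste(need, collapse = ", "))
  } else {
    raw <- utils::read.table(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    ann <- data.frame(gene = raw[[4]], chrom = raw[[1]],
                      start = raw[[2]] + 1L, end = raw[[3]],
                      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(ann$gene))
    stop2("duplicate gene ids in %s: %s", path,
          paste(unique(ann$gene[duplicated(ann$gene)]), collapse = ", "))
  if (any(ann$end < ann$start)) stop2("annotation with end < start in %s", path)
  ann
}

#' TSV read/write with the pipeline's conventions
#'
#' Header row, tab separator, UTF-8, '.' decimal, `NA` sentinel, no
#' quoting or row names.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_tsv()` returns a data.frame; `write_tsv()` returns
#'   `path` invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE,
                    fileEncoding = "UTF-8")
}

#' Read per-vial pupation records
#'
#' @param path TSV with columns `vial`, `line`, `treatment`, `batch`,
#'   `day`, `count`.
#' @return a `pupation_records` data.frame.
#' @export
read_pupation_records <- function(path) {
  rec <- read_tsv(path)
  need <- c("vial", "line", "treatment", "batch", "day", "count")
  if (!all(need %in% names(rec))) {
    malformed <- setdiff(need, names(rec))
    stop2("pupation TSV %s is missing column(s): %s", path,
          paste(malformed, collapse = ", "))
  }
  bad <- which(is.na(rec$count) | rec$count < 0)
  if (length(bad)) stop2("malformed count at %s line %d", path, bad[1] + 1L)
  class(rec) <- c("pupation_records", "data.frame")
  rec
}

#' Read a line covariate table
#'
#' @param path TSV with a `line` column plus binary covariate columns
#'   (Wolbachia status, inversion genotypes).
#' @return data.frame.
#' @export
read_covariates <- function(path) {
  cov <- read_tsv(path)
  if (!"line" %in% names(cov)) stop2("covariate TSV needs a `line` column")
  if (anyDuplicated(cov$line)) stop2("duplicate line ids in %s", path)
  cov
}

#' Read a metabolite matrix and its sample metadata
#'
#' @param intensity_path TSV: `sample` column then one column per
#'   metabolite.
#' @param meta_path TSV: `sample`, `line`, `class`, `treatment`, `batch`.
#' @param normalized whether the table is already normalized.
#' @return a [metabolite_matrix()].
#' @export
read_metabolome <- function(intensity_path, meta_path, normalized = FALSE) {
  ix <- read_tsv(intensity_path)
  meta <- read_tsv(meta_path)
  if (!identical(as.character(ix$sample), as.character(meta$sample)))
    stop2("sample ids differ between %s and %s", intensity_path, meta_path)
  m <- as.matrix(ix[, -1, drop = FALSE])
  rownames(m) <- ix$sample
  metabolite_matrix(m, meta, normalized = normalized)
}

#' Write a metabolite matrix and its sample metadata
#'
#' @param M a [metabolite_matrix()].
#' @param intensity_path,meta_path output TSV paths.
#' @return `intensity_path`, invisibly.
#' @export
write_metabolome <- function(M, intensity_path, meta_path) {
  write_tsv(data.frame(sample = M$meta$sample, M$intensity,
                       check.names = FALSE), intensity_path)
  write_tsv(M$meta, meta_path)
  invisible(intensity_path)
}
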