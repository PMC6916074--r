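# Readers and writers for the pipeline's plain-text interchange formats.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a genotype panel as a minimal VCF
#'
#' One record per variant, 1-based positions, GT fields only. REF is allele
#' A2 and ALT is allele A1, so the dosage (count of A1) equals the ALT allele
#' count; missing calls are `./.`.
#'
#' @param panel a [genotype_panel()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=phenonet",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$sample_id), collapse = "\t")),
             con)
  v <- panel$variants
  D <- t(panel$dosage)                  # variants x samples
  gt <- matrix(gt_code[as.character(D)], nrow(D), ncol(D))
  gt[is.na(D)] <- "./."
  lines <- paste(v$chrom, v$pos, v$variant_id, v$A2, v$A1, ".", "PASS", ".",
                 "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a genotype panel from a VCF
#'
#' Expects diploid GT calls; the dosage counts the ALT (A1) allele. Requires
#' the vcfR package.
#'
#' @param path VCF file.
#' @return A [genotype_panel()].
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  count_alt <- function(g) {
    out <- rep(NA_integer_, length(g))
    ok <- !is.na(g) & !grepl("\\.", g)
    alleles <- strsplit(g[ok], "[/|]")
    out[ok] <- vapply(alleles, function(a) sum(a == "1"), integer(1))
    out
  }
  D <- apply(gt, 2, count_alt)
  variants <- data.frame(variant_id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         A1 = fix$ALT, A2 = fix$REF,
                         stringsAsFactors = FALSE)
  genotype_panel(colnames(gt), variants, t(D))
}

#' Write/read a genotype panel as a dosage TSV
#'
#' Long header columns `variant_id`, `chrom`, `pos`, `A1`, `A2` followed by
#' one column per sample holding the A1 dosage (`NA` for missing).
#'
#' @param panel a [genotype_panel()].
#' @param path file path.
#' @return The path (writer) or a [genotype_panel()] (reader).
#' @export
write_dosage_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  df <- cbind(panel$variants[, c("variant_id", "chrom", "pos", "A1", "A2")],
              as.data.frame(t(panel$dosage)))
  write_tsv(df, path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- read_tsv(path)
  meta <- c("variant_id", "chrom", "pos", "A1", "A2")
  samples <- setdiff(names(df), meta)
  D <- t(as.matrix(df[, samples, drop = FALSE]))
  genotype_panel(samples, df[, meta], D)
}

#' Write/read a phenotype panel as TSV
#'
#' One row per sample: `sample_id`, covariate columns, then trait columns.
#'
#' @param pheno a `phenotype_panel`.
#' @param path file path.
#' @export
write_phenotype_tsv <- function(pheno, path) {
  stopifnot(inherits(pheno, "phenotype_panel"))
  df <- data.frame(sample_id = pheno$sample_id, pheno$covariates,
                   pheno$traits, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_phenotype_tsv
#' @param covariate_cols names of the covariate columns in the file.
#' @export
read_phenotype_tsv <- function(path, covariate_cols = "age") {
  df <- read_tsv(path)
  traits <- setdiff(names(df), c("sample_id", covariate_cols))
  phenotype_panel(as.matrix(df[, traits, drop = FALSE]),
                  covariates = df[, covariate_cols, drop = FALSE],
                  sample_id = df$sample_id)
}

#' Write/read a gene map as BED (0-based half-open)
#'
#' @param gene_map data frame `gene_id`, `chrom`, `start`, `end`.
#' @param path file path.
#' @export
write_gene_map_bed <- function(gene_map, path) {
  utils::write.table(gene_map[, c("chrom", "start", "end", "gene_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_map_bed
#' @export
read_gene_map_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "gene_id"))
  df$chrom <- as.character(df$chrom)
  df[, c("gene_id", "chrom", "start", "end")]
}

#' Write/read a PPI network as a two-column edge TSV
#'
#' @param ppi a [ppi_network()].
#' @param path file path.
#' @export
write_ppi_tsv <- function(ppi, path) {
  stopifnot(inherits(ppi, "ppi_network"))
  write_tsv(ppi$edges, path)
}

#' @rdname write_ppi_tsv
#' @export
read_ppi_tsv <- function(path) ppi_network(read_tsv(path))

#' Write/read LDSC summary statistics TSV (SNP, A1, A2, N, Z)
#'
#' @param ss a `sumstats` table.
#' @param path file path.
#' @export
write_sumstats_tsv <- function(ss, path) write_tsv(ss, path)

#' @rdname write_sumstats_tsv
#' @param trait trait label to attach.
#' @export
read_sumstats_tsv <- function(path, trait = NA_character_) {
  ss <- read_tsv(path)
  attr(ss, "trait") <- trait
  class(ss) <- c("sumstats", "data.frame")
  ss
}
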