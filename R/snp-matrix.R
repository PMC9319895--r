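# SNP matrix container and genotype-code helpers
#
# Genotypes follow the one-character-per-call concatenated-SNP convention of
# RADseq assemblers: A/C/G/T for homozygotes, the two-base IUPAC ambiguity
# codes (R, Y, S, W, K, M) for heterozygotes, and N or - for missing calls.

IUPAC_HET <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")
SNP_ALPHABET <- c("A", "C", "G", "T", names(IUPAC_HET), "N", "-")

# lookup tables: code -> two allele integers (A=1, C=2, G=3, T=4), NA = missing
.allele_tab <- local({
  bases <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  a1 <- a2 <- setNames(rep(NA_integer_, length(SNP_ALPHABET)), SNP_ALPHABET)
  for (b in names(bases)) a1[b] <- a2[b] <- bases[[b]]
  for (h in names(IUPAC_HET)) {
    pq <- strsplit(IUPAC_HET[[h]], "")[[1]]
    a1[h] <- bases[[pq[1]]]
    a2[h] <- bases[[pq[2]]]
  }
  list(a1 = a1, a2 = a2)
})

# code for an unordered diploid genotype of two allele integers
genotype_code <- function(a1, a2) {
  bases <- c("A", "C", "G", "T")
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  hom <- lo == hi
  het_key <- paste0(bases[lo], bases[hi])
  het_map <- setNames(names(IUPAC_HET), IUPAC_HET)
  # IUPAC_HET strings are alphabetically ordered pairs
  out <- ifelse(hom, bases[lo], het_map[het_key])
  unname(out)
}

#' Construct a SNP matrix
#'
#' @param codes character matrix, samples in rows and SNP sites in columns,
#'   over the alphabet A, C, G, T, the two-base IUPAC ambiguity codes and
#'   N or - for missing calls. Row names are taken as sample ids when
#'   `sample_ids` is missing.
#' @param taxon character vector of taxon labels, one per sample.
#' @param sample_ids character vector of unique sample ids.
#' @return an object of class `snp_matrix`.
#' @export
snp_matrix <- function(codes, taxon, sample_ids = rownames(codes)) {
  codes <- as.matrix(codes)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(codes)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (length(sample_ids) != nrow(codes)) stop("one sample id per row required")
  if (length(taxon) != nrow(codes)) stop("one taxon label per sample required")
  bad <- setdiff(unique(as.vector(codes)), SNP_ALPHABET)
  if (length(bad)) stop("invalid genotype codes: ", paste(bad, collapse = ", "))
  miss <- codes == "N" | codes == "-"
  if (any(rowSums(!miss) == 0L)) {
    stop("every sample needs at least one non-missing call")
  }
  rownames(codes) <- sample_ids
  structure(list(codes = codes,
                 sample_ids = sample_ids,
                 taxon = setNames(as.character(taxon), sample_ids)),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("snp_matrix: %d samples x %d sites, %d taxa, %.1f%% missing\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$taxon)),
              100 * mean(x$codes == "N" | x$codes == "-")))
  invisible(x)
}

#' @export
dim.snp_matrix <- function(x) dim(x$codes)

#' Decode genotype codes into two allele matrices
#'
#' @param m a [snp_matrix] or a character code matrix.
#' @return list with integer matrices `a1`, `a2` (A=1, C=2, G=3, T=4;
#'   NA for missing) of the same shape as the code matrix.
#' @export
snp_alleles <- function(m) {
  codes <- if (inherits(m, "snp_matrix")) m$codes else m
  dm <- dim(codes)
  a1 <- .allele_tab$a1[codes]
  a2 <- .allele_tab$a2[codes]
  dim(a1) <- dm; dim(a2) <- dm
  dimnames(a1) <- dimnames(a2) <- dimnames(codes)
  list(a1 = a1, a2 = a2)
}

#' Subset samples of a SNP matrix
#' @param m a [snp_matrix].
#' @param keep sample ids (character) or logical/integer row index.
#' @return a [snp_matrix].
#' @export
snp_subset <- function(m, keep) {
  if (is.character(keep)) keep <- match(keep, m$sample_ids)
  snp_matrix(m$codes[keep, , drop = FALSE], m$taxon[keep])
}

#' Write a PHYLIP-like concatenated SNP matrix
#'
#' Relaxed sequential dialect used by RADseq assemblers: a header line with
#' sample and site counts, then one `name<whitespace>sequence` line per sample.
#'
#' @param m a [snp_matrix].
#' @param path output file.
#' @export
write_snps_phy <- function(m, path) {
  lines <- c(sprintf("%d %d", nrow(m$codes), ncol(m$codes)),
             sprintf("%s  %s", format(m$sample_ids),
                     apply(m$codes, 1, paste0, collapse = "")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PHYLIP-like concatenated SNP matrix
#'
#' @param path input file.
#' @param taxon optional named vector mapping sample id to taxon label;
#'   defaults to the part of the sample id before the last underscore (or the
#'   full id when there is none).
#' @return a [snp_matrix].
#' @export
read_snps_phy <- function(path, taxon = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- strsplit(trimws(lines[-1]), "\\s+")
  ids <- vapply(body, `[[`, "", 1L)
  seqs <- vapply(body, `[[`, "", 2L)
  codes <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(codes) <- ids
  if (!is.na(hdr[1]) && hdr[1] != nrow(codes)) {
    stop("header sample count disagrees with body")
  }
  if (!is.na(hdr[2]) && hdr[2] != ncol(codes)) {
    stop("header site count disagrees with body")
  }
  if (is.null(taxon)) taxon <- sub("_[^_]*$", "", ids)
  if (!is.null(names(taxon))) taxon <- taxon[ids]
  snp_matrix(codes, taxon)
}

#' Write a minimal GT-only VCF for a SNP matrix
#'
#' Sites are encoded against the majority allele (REF) per site; heterozygous
#' calls become 0/1. Sites with more than two observed alleles are written
#' with the two most frequent ones and other calls set missing.
#'
#' @param m a [snp_matrix].
#' @param path output file (plain text).
#' @export
write_snps_vcf <- function(m, path) {
  al <- snp_alleles(m)
  bases <- c("A", "C", "G", "T")
  n_sites <- ncol(m$codes)
  rows <- character(n_sites)
  for (s in seq_len(n_sites)) {
    counts <- tabulate(c(al$a1[, s], al$a2[, s]), nbins = 4L)
    ord <- order(counts, decreasing = TRUE)
    ref <- ord[1]; alt <- if (counts[ord[2]] > 0) ord[2] else ord[1]
    g1 <- ifelse(is.na(al$a1[, s]), ".",
                 ifelse(al$a1[, s] == ref, "0", ifelse(al$a1[, s] == alt, "1", ".")))
    g2 <- ifelse(is.na(al$a2[, s]), ".",
                 ifelse(al$a2[, s] == ref, "0", ifelse(al$a2[, s] == alt, "1", ".")))
    gt <- ifelse(g1 == "." | g2 == ".", "./.",
                 paste(pmin(g1, g2), pmax(g1, g2), sep = "/"))
    rows[s] <- paste(c("1", s, paste0("snp", s), bases[ref],
                       if (alt == ref) "." else bases[alt],
                       ".", "PASS", ".", "GT", gt), collapse = "\t")
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=1>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", m$sample_ids), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a GT-only biallelic VCF into a SNP matrix
#'
#' @param path VCF file.
#' @param taxon optional sample id to taxon map as in [read_snps_phy()].
#' @return a [snp_matrix].
#' @export
read_snps_vcf <- function(path, taxon = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ref <- vcfR::getREF(v)
  alt <- vcfR::getALT(v)
  alt[is.na(alt) | alt == "."] <- ref[is.na(alt) | alt == "."]
  keep <- !grepl(",", alt)  # biallelic rows only
  gt <- gt[keep, , drop = FALSE]; ref <- ref[keep]; alt <- alt[keep]
  base_int <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  n_sites <- length(ref); ids <- colnames(gt)
  codes <- matrix("N", nrow = length(ids), ncol = n_sites,
                  dimnames = list(ids, NULL))
  for (s in seq_len(n_sites)) {
    g <- gsub("\\|", "/", gt[s, ])
    ok <- !is.na(g) & g %in% c("0/0", "0/1", "1/0", "1/1")
    pick <- function(tok) ifelse(tok == "0", base_int[[ref[s]]], base_int[[alt[s]]])
    parts <- strsplit(g[ok], "/")
    a1 <- pick(vapply(parts, `[[`, "", 1L))
    a2 <- pick(vapply(parts, `[[`, "", 2L))
    codes[ok, s] <- genotype_code(a1, a2)
  }
  ids2 <- ids
  if (is.null(taxon)) taxon <- sub("_[^_]*$", "", ids2)
  if (!is.null(names(taxon))) taxon <- taxon[ids2]
  snp_matrix(codes, taxon)
}
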