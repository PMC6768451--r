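# Plain-text I/O: FASTA (via Biostrings), pileup/variant/count TSVs and a
# minimal VCF 4.2 writer for the fixed-variant table.

#' Write named sequences to FASTA
#' @param seqs named character vector or DNAStringSet
#' @param path output path
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(unlist(as.list(seqs)))
  }
  Biostrings::writeXStringSet(seqs, path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a pileup table as TSV (gene, pos, ref, A, C, G, T, ins, del)
#' @param pileup pileup data.frame
#' @param path output path
#' @export
write_pileup <- function(pileup, path) {
  utils::write.table(pileup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a pileup TSV
#' @param path input path
#' @export
read_pileup <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(gene = "character", ref = "character"),
                    stringsAsFactors = FALSE)
}

#' Write a fixed-variant table as VCF 4.2
#'
#' CHROM is the reference-clone gene id, POS 1-based; the observation
#' direction is carried in INFO (DIR=both|B_on_A|A_on_B).
#'
#' @param variants consolidated `FixedVariantTable`
#'   (from [consolidate_bidirectional()])
#' @param path output path
#' @param source_tag value for the `##source` header line
#' @export
write_variants_vcf <- function(variants, path, source_tag = "clonescan") {
  header <- c("##fileformat=VCFv4.2",
              paste0("##source=", source_tag),
              "##INFO=<ID=DIR,Number=1,Type=String,Description=\"Direction(s) observed\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(variants) > 0) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDIR=%s",
            variants$geneA, variants$posA, variants$alleleA,
            variants$alleleB, variants$directions)
  } else character(0)
  writeLines(c(header, body), path)
}

#' Write a count matrix as TSV (gene column + one column per sample)
#' @param counts genes x samples matrix
#' @param path output path
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a count matrix TSV written by [write_counts()]
#' @param path input path
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
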