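#' Read and write long-format callsets and sample tables as TSV
#'
#' The long format has one row per (sample, variant): sample_id, pos, ref,
#' alt, HL, AD, DP, filter (plus any extra columns, preserved).
#'
#' @param callset,samples data.frames.
#' @param path file path.
#' @export
write_callset_tsv <- function(callset, path) {
  utils::write.table(callset, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_callset_tsv
#' @export
read_callset_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(sample_id = "character"))
}

#' @rdname write_callset_tsv
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_callset_tsv
#' @export
read_sample_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(sample_id = "character"))
}

#' Write one sample's calls as a minimal VCF
#'
#' Emits a VCFv4.2 file with contig chrM, site FILTER, and FORMAT fields
#' GT/AD/DP plus INFO/HL, one sample per file.
#'
#' @param callset long-format callset.
#' @param sample_id which sample to write.
#' @param path output path.
#' @param contig_length contig length for the header.
#' @export
write_callset_vcf <- function(callset, sample_id, path, contig_length = 16569) {
  cs <- callset[callset$sample_id == sample_id, , drop = FALSE]
  cs <- cs[order(cs$pos, cs$alt), , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chrM,length=%d>", contig_length),
    "##INFO=<ID=HL,Number=1,Type=Float,Description=\"Heteroplasmy fraction\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=1,Type=Integer,Description=\"Alt allele depth\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Site depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  filt <- ifelse(is.na(cs$filter) | cs$filter == "", "PASS", cs$filter)
  body <- sprintf("chrM\t%d\t.\t%s\t%s\t.\t%s\tHL=%.6g\tGT:AD:DP\t0/1:%d:%d",
                  cs$pos, cs$ref, cs$alt, filt, cs$HL, cs$AD, cs$DP)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a minimal single-sample VCF back into long format
#' @param path VCF path.
#' @return long-format callset data.frame.
#' @export
read_callset_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  sample_id <- utils::tail(strsplit(hdr, "\t")[[1]], 1)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    return(data.frame(sample_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0), HL = numeric(0),
                      AD = integer(0), DP = integer(0), filter = character(0)))
  }
  f <- do.call(rbind, strsplit(body, "\t"))
  gt <- do.call(rbind, strsplit(f[, 10], ":"))
  data.frame(
    sample_id = sample_id,
    pos = as.integer(f[, 2]),
    ref = f[, 4], alt = f[, 5],
    HL = as.numeric(sub("HL=", "", f[, 8])),
    AD = as.integer(gt[, 2]),
    DP = as.integer(gt[, 3]),
    filter = f[, 7],
    stringsAsFactors = FALSE
  )
}
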