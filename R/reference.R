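#' Circular mtDNA reference genome
#'
#' A reference genome is a circular sequence over \{A, C, G, T, N\} with
#' 1-based coordinates. Placeholder positions (base \code{N}) stand in for
#' unresolvable reference positions (the rCRS carries one, at 3107) and are
#' excluded from all denominators. The object also records the bounds of the
#' replication-origin control region ("Ori"), which wraps the sequence
#' origin: a position is in Ori iff it is >= \code{ori[1]} or <= \code{ori[2]}.
#'
#' @param sequence character vector of single bases.
#' @param ori length-2 numeric, Ori region bounds (start, end), wrapping.
#' @return An object of class \code{mt_reference}: a list with elements
#'   \code{seq} (character vector of bases), \code{length},
#'   \code{placeholder_positions} (integer vector) and \code{ori}.
#' @export
mt_reference <- function(sequence, ori) {
  sequence <- toupper(as.character(sequence))
  stopifnot(all(sequence %in% c("A", "C", "G", "T", "N")))
  placeholders <- which(sequence == "N")
  structure(
    list(
      seq = sequence,
      length = length(sequence),
      placeholder_positions = as.integer(placeholders),
      ori = as.integer(ori)
    ),
    class = "mt_reference"
  )
}

#' @export
print.mt_reference <- function(x, ...) {
  cat(sprintf(
    "Circular mtDNA reference: %d bp, %d placeholder position(s), Ori %d-%d (wrapping)\n",
    x$length, length(x$placeholder_positions), x$ori[1], x$ori[2]
  ))
  invisible(x)
}

#' Default Ori bounds for a genome length
#'
#' rCRS coordinates (16172, 210) for the canonical 16,569 bp genome; scaled
#' proportionally (and kept wrapping) for shorter synthetic genomes.
#' @param length genome length in bases.
#' @return integer vector c(start, end).
#' @export
default_ori_bounds <- function(length) {
  if (length >= 16569) return(c(16172L, 210L))
  start <- max(2L, as.integer(round(length * 16172 / 16569)))
  end <- max(1L, as.integer(round(length * 210 / 16569)))
  if (end >= start) end <- start - 1L  # keep the interval wrapping
  c(start, end)
}

#' Generate a random circular reference genome
#'
#' Bases are drawn uniformly from \{A,C,G,T\} except at placeholder
#' positions, which are set to \code{N}. Deterministic under \code{seed}.
#'
#' @param length genome length (>= 100).
#' @param placeholder_positions integer positions to set to N (default: the
#'   rCRS-analogous 3107 when the genome is long enough, none otherwise).
#' @param seed integer random seed.
#' @param ori Ori region bounds; defaults via [default_ori_bounds()].
#' @return An [mt_reference] object.
#' @export
generate_reference <- function(length, placeholder_positions = NULL, seed = 1,
                               ori = default_ori_bounds(length)) {
  if (length < 100) stop("reference length must be >= 100")
  if (is.null(placeholder_positions)) {
    placeholder_positions <- if (length >= 3107) 3107L else integer(0)
  }
  placeholder_positions <- as.integer(placeholder_positions)
  if (length(placeholder_positions) &&
      (any(placeholder_positions < 1) || any(placeholder_positions > length))) {
    stop("placeholder positions out of range [1, length]")
  }
  set.seed(seed)
  seq <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  seq[placeholder_positions] <- "N"
  mt_reference(seq, ori)
}

#' Circular position arithmetic
#'
#' Wraps any integer offset onto 1-based circular coordinates.
#' @param pos integer positions (may lie outside 1..length).
#' @param length genome length.
#' @return positions wrapped into 1..length.
#' @export
wrap_position <- function(pos, length) {
  ((as.integer(pos) - 1L) %% as.integer(length)) + 1L
}

#' Reference base at circular positions
#' @param reference an [mt_reference].
#' @param pos positions (wrapped circularly).
#' @return character vector of bases.
#' @export
ref_base <- function(reference, pos) {
  reference$seq[wrap_position(pos, reference$length)]
}

#' Complement / reverse complement of base strings
#' @param x character vector of base strings.
#' @return complemented (and for [revcomp()], reversed) strings.
#' @export
complement_bases <- function(x) chartr("ACGTN", "TGCAN", x)

#' @rdname complement_bases
#' @export
revcomp <- function(x) {
  vapply(strsplit(complement_bases(x), ""), function(b) {
    paste(rev(b), collapse = "")
  }, character(1))
}

#' Is a position inside the Ori control region?
#' @param reference an [mt_reference].
#' @param pos positions.
#' @return logical vector.
#' @export
in_ori <- function(reference, pos) {
  pos >= reference$ori[1] | pos <= reference$ori[2]
}

#' Write / read a reference as FASTA
#'
#' Thin wrappers over Biostrings; the single record is named \code{chrM}.
#' @param reference an [mt_reference].
#' @param path file path.
#' @param ori Ori bounds to attach when reading (default scaled bounds).
#' @export
write_reference_fasta <- function(reference, path) {
  x <- Biostrings::DNAStringSet(paste(reference$seq, collapse = ""))
  names(x) <- "chrM"
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path, ori = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  seq <- strsplit(as.character(x[[1]]), "")[[1]]
  if (is.null(ori)) ori <- default_ori_bounds(length(seq))
  mt_reference(seq, ori)
}

# positions covered by a (possibly origin-wrapping) span, in reading order
# along ascending light-strand coordinates
gene_positions <- function(start, end, length) {
  if (start <= end) seq.int(start, end) else c(seq.int(start, length), seq.int(1L, end))
}

#' Generate a non-overlapping coding gene model
#'
#' Packs \code{n_genes} coding genes of span divisible by 3 into
#' non-placeholder, non-Ori territory, assigning strands per
#' \code{strand_mix}. Light-strand genes model the ND6 analogue. Genes never
#' overlap each other or placeholder positions. Deterministic under
#' \code{seed}.
#'
#' @param reference an [mt_reference].
#' @param n_genes number of genes.
#' @param strand_mix named numeric \code{c(heavy=, light=)} summing to
#'   \code{n_genes}; at least one light-strand gene is required.
#' @param gene_length target span per gene in bases (multiple of 3); default
#'   scales to fit.
#' @param seed integer seed.
#' @return data.frame with columns gene, start, end, strand, coding, frame.
#' @export
generate_gene_model <- function(reference, n_genes,
                                strand_mix = c(heavy = n_genes - 1L, light = 1L),
                                gene_length = NULL, seed = 1) {
  stopifnot(n_genes >= 1, sum(strand_mix) == n_genes)
  if (is.na(strand_mix["light"]) || strand_mix["light"] < 1) {
    stop("strand_mix must include at least one light-strand gene")
  }
  L <- reference$length
  # usable territory: outside Ori, no placeholders
  usable <- setdiff(which(!in_ori(reference, seq_len(L))), reference$placeholder_positions)
  if (is.null(gene_length)) {
    gene_length <- max(9L, 3L * ((length(usable) %/% (2L * n_genes)) %/% 3L))
  }
  if (gene_length %% 3 != 0) stop("gene_length must be a multiple of 3")
  # find runs of consecutive usable positions and pack genes greedily
  runs <- split(usable, cumsum(c(1L, diff(usable) != 1L)))
  set.seed(seed)
  slots <- list()
  gap <- 2L
  for (r in runs) {
    p <- r[1]
    while (p + gene_length - 1L <= r[length(r)] && length(slots) < n_genes) {
      slots[[length(slots) + 1L]] <- as.integer(c(p, p + gene_length - 1L))
      p <- p + gene_length + gap
    }
    if (length(slots) >= n_genes) break
  }
  if (length(slots) < n_genes) {
    stop(sprintf("cannot pack %d genes of %d bp into available territory",
                 n_genes, gene_length))
  }
  strands <- sample(c(rep("heavy", strand_mix["heavy"]), rep("light", strand_mix["light"])))
  data.frame(
    gene = sprintf("GENE%02d", seq_len(n_genes)),
    start = vapply(slots, `[`, integer(1), 1L)[seq_len(n_genes)],
    end = vapply(slots, `[`, integer(1), 2L)[seq_len(n_genes)],
    strand = strands,
    coding = TRUE,
    frame = 0L,
    stringsAsFactors = FALSE
  )
}

#' Write / read a gene model as BED-like TSV (1-based inclusive)
#' @param gene_model data.frame from [generate_gene_model()].
#' @param path file path.
#' @export
write_gene_model <- function(gene_model, path) {
  utils::write.table(gene_model, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_model
#' @export
read_gene_model <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
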