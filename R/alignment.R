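#' Construct an in-frame haplotype alignment
#'
#' Lightweight container for one gene: `n >= 2` ingroup haplotype sequences
#' of equal length divisible by 3, an optional single outgroup sequence, and
#' bookkeeping metadata. Sequences use the alphabet `A C G T N -`.
#' Coordinates are 0-based half-open internally; GFF-style I/O converts to
#' 1-based.
#'
#' @param sequences Named character vector of ingroup haplotype sequences.
#' @param outgroup Optional single outgroup sequence (same length).
#' @param gene_id Gene identifier.
#' @param arrangement Optional arrangement / population label per haplotype
#'   (recycled if length 1).
#' @param start,end Optional genomic coordinates (0-based half-open).
#' @return An object of class `haplotype_alignment`.
#' @export
haplotype_alignment <- function(sequences, outgroup = NULL, gene_id = "gene",
                                arrangement = NA_character_, start = NA, end = NA) {
  sequences <- toupper(sequences)
  if (length(sequences) < 2L) stop("need n >= 2 ingroup haplotypes", call. = FALSE)
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences must have equal length", call. = FALSE)
  if (L %% 3L != 0L) stop("alignment length must be divisible by 3", call. = FALSE)
  if (!is.null(outgroup)) {
    outgroup <- toupper(outgroup)
    if (length(outgroup) != 1L || nchar(outgroup) != L) {
      stop("outgroup must be a single sequence of matching length", call. = FALSE)
    }
  }
  bad <- grepl("[^ACGTN-]", c(sequences, outgroup))
  if (any(bad)) stop("sequences contain characters outside {A,C,G,T,N,-}", call. = FALSE)
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("hap", seq_along(sequences))
  }
  structure(
    list(
      sequences = sequences,
      outgroup = outgroup,
      gene_id = gene_id,
      arrangement = rep_len(arrangement, length(sequences)),
      start = start, end = end
    ),
    class = "haplotype_alignment"
  )
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat(
    "<haplotype_alignment> gene", x$gene_id, "-", length(x$sequences),
    "haplotypes x", nchar(x$sequences[1]), "bp",
    if (!is.null(x$outgroup)) "(+ outgroup)" else "(no outgroup)", "\n"
  )
  invisible(x)
}

#' Alignment as a haplotype-by-column character matrix
#'
#' @param aln A `haplotype_alignment`.
#' @param with_outgroup Include the outgroup as the last row.
#' @return Character matrix (haplotypes x positions).
#' @export
alignment_matrix <- function(aln, with_outgroup = FALSE) {
  seqs <- aln$sequences
  if (with_outgroup && !is.null(aln$outgroup)) {
    seqs <- c(seqs, `outgroup|out` = aln$outgroup)
  }
  do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}

#' Read a per-gene haplotype alignment from FASTA
#'
#' One record per strain; a record whose id starts with `outgroup|` is taken
#' as the outgroup. Arrangement labels may be encoded as `id|arrangement`.
#'
#' @param path FASTA file path.
#' @param gene_id Gene identifier (default: file name without extension).
#' @return A `haplotype_alignment`.
#' @export
read_haplotype_alignment <- function(path, gene_id = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- stats::setNames(as.character(ss), names(ss))
  is_out <- startsWith(names(seqs), "outgroup|")
  outgroup <- if (any(is_out)) unname(seqs[is_out][1]) else NULL
  ing <- seqs[!is_out]
  arr <- vapply(strsplit(names(ing), "|", fixed = TRUE), function(p) {
    if (length(p) >= 2) p[[2]] else NA_character_
  }, character(1))
  if (is.null(gene_id)) gene_id <- sub("\\.[^.]+$", "", basename(path))
  haplotype_alignment(ing, outgroup = outgroup, gene_id = gene_id, arrangement = arr)
}

#' Write a haplotype alignment to FASTA
#'
#' The outgroup record id is prefixed `outgroup|`; ingroup ids carry their
#' arrangement label as `id|arrangement`.
#'
#' @param aln A `haplotype_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_haplotype_alignment <- function(aln, path) {
  ids <- names(aln$sequences)
  arr <- aln$arrangement
  ids <- ifelse(is.na(arr), ids, paste(ids, arr, sep = "|"))
  seqs <- aln$sequences
  if (!is.null(aln$outgroup)) {
    seqs <- c(seqs, aln$outgroup)
    ids <- c(ids, "outgroup|out")
  }
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Subset an alignment to the haplotypes of one arrangement
#'
#' @param aln A `haplotype_alignment`.
#' @param arrangement Label to keep.
#' @return A `haplotype_alignment` with only the matching haplotypes.
#' @export
filter_arrangement <- function(aln, arrangement) {
  keep <- !is.na(aln$arrangement) & aln$arrangement == arrangement
  if (sum(keep) < 2L) stop("fewer than 2 haplotypes in arrangement", call. = FALSE)
  haplotype_alignment(aln$sequences[keep],
    outgroup = aln$outgroup,
    gene_id = aln$gene_id, arrangement = aln$arrangement[keep],
    start = aln$start, end = aln$end
  )
}
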