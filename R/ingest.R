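#' Read gene models from a GFF3 file
#'
#' Extracts CDS (or gene) features and returns the 0-based half-open
#' coordinate table the rest of the package uses. Requires the
#' \pkg{rtracklayer} package.
#'
#' @param path GFF3 file path.
#' @param feature Feature type to keep (default `"CDS"`).
#' @return A tibble with `gene_id`, `chrom`, `start` (0-based), `end`,
#'   `strand`.
#' @export
read_gene_models <- function(path, feature = "CDS") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_gene_models() requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == feature]
  id <- if (!is.null(gr$ID)) {
    gr$ID
  } else if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_, character(1))
  } else {
    paste0("feature", seq_along(gr))
  }
  tibble::tibble(
    gene_id = as.character(id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, # GFF is 1-based inclusive
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Build per-gene haplotype alignments from a VCF and a reference
#'
#' Thin ingest path for pre-called variants: each sample's haplotype is the
#' reference CDS sequence with its called alternate alleles substituted.
#' Sites are filtered by the standard thresholds first (SNP quality below
#' `min_quality` dropped; heterozygous calls treated as missing and the
#' site's base set to `N` for that sample, since isochromosomal panels
#' should be homozygous). Only plus-strand, single-exon CDS spans are
#' supported. Requires the \pkg{vcfR} package.
#'
#' @param vcf Path to a VCF file (uncompressed or gzipped).
#' @param genes Gene-model tibble as from [read_gene_models()] (columns
#'   `gene_id`, `chrom`, `start` 0-based, `end`).
#' @param reference Named character vector of chromosome sequences, or a
#'   FASTA path.
#' @param outgroup_sample Optional sample name treated as the outgroup
#'   record of each alignment.
#' @param min_quality Minimum SNP quality (default 30; sites strictly
#'   below are dropped).
#' @return Named list of [haplotype_alignment()] objects.
#' @export
alignments_from_vcf <- function(vcf, genes, reference, outgroup_sample = NULL,
                                min_quality = 30) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("alignments_from_vcf() requires the vcfR package", call. = FALSE)
  }
  if (is.character(reference) && length(reference) == 1 && file.exists(reference)) {
    ss <- Biostrings::readDNAStringSet(reference)
    reference <- stats::setNames(as.character(ss), sub("\\s.*", "", names(ss)))
  }
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(v@fix, stringsAsFactors = FALSE))
  fix$POS <- as.integer(fix$POS)
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  keep <- is.na(qual) | qual >= min_quality
  gt <- vcfR::extract.gt(v)
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  samples <- colnames(gt)
  out <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    ref_seq <- reference[[g$chrom]]
    cds <- substr(ref_seq, g$start + 1L, g$end)
    in_gene <- fix$CHROM == g$chrom & fix$POS > g$start & fix$POS <= g$end
    idx <- which(in_gene)
    seqs <- stats::setNames(rep(cds, length(samples)), samples)
    for (k in idx) {
      pos_local <- fix$POS[k] - g$start
      alleles <- c(fix$REF[k], strsplit(fix$ALT[k], ",", fixed = TRUE)[[1]])
      if (any(nchar(alleles) != 1L)) next # indels are not ingested
      for (s in samples) {
        call <- gt[k, s]
        if (is.na(call)) {
          substr(seqs[[s]], pos_local, pos_local) <- "N"
          next
        }
        parts <- strsplit(call, "[/|]")[[1]]
        if (length(unique(parts)) > 1L) {
          # heterozygous call in an isochromosomal panel: treat as missing
          substr(seqs[[s]], pos_local, pos_local) <- "N"
        } else {
          ai <- suppressWarnings(as.integer(parts[1]))
          if (!is.na(ai) && ai >= 0 && ai < length(alleles)) {
            substr(seqs[[s]], pos_local, pos_local) <- alleles[ai + 1L]
          } else {
            substr(seqs[[s]], pos_local, pos_local) <- "N"
          }
        }
      }
    }
    outg <- NULL
    if (!is.null(outgroup_sample) && outgroup_sample %in% samples) {
      outg <- unname(seqs[[outgroup_sample]])
      seqs <- seqs[setdiff(samples, outgroup_sample)]
    }
    out[[g$gene_id]] <- haplotype_alignment(
      seqs,
      outgroup = outg, gene_id = g$gene_id,
      start = g$start, end = g$end
    )
  }
  out
}
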