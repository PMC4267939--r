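#' Construct a site frequency spectrum object
#'
#' @param counts Numeric vector of length `n + 1` with counts `c_0..c_n` of
#'   sites by the number of haplotypes carrying the focal state.
#' @param n Sample size (number of haplotypes).
#' @param focal Which codon state the spectrum indexes (`"major"` or
#'   `"minor"`).
#' @param excluded Optional named vector of per-reason exclusion counts.
#' @return A tibble of class `sfs` with columns `i` and `count`, and
#'   attributes `n`, `focal`, `excluded`.
#' @export
new_sfs <- function(counts, n, focal = "major", excluded = integer()) {
  counts <- as.numeric(counts)
  if (length(counts) != n + 1L) stop("counts must have length n + 1", call. = FALSE)
  if (any(counts < 0)) stop("negative SFS counts", call. = FALSE)
  out <- tibble::tibble(i = 0:n, count = counts)
  class(out) <- c("sfs", class(out))
  attr(out, "n") <- as.integer(n)
  attr(out, "focal") <- focal
  attr(out, "excluded") <- excluded
  out
}

#' @export
print.sfs <- function(x, ...) {
  cat(
    "<sfs> n =", attr(x, "n"), " focal =", attr(x, "focal"),
    " sites =", sum(x$count), "\n"
  )
  NextMethod()
}

#' Build the major/minor-codon site frequency spectrum
#'
#' Scans every codon column of the alignments. Columns where all called
#' codons are either the amino acid's major codon or one specific minor
#' codon contribute one site: a polymorphic column enters class
#' `i = number of haplotypes carrying the focal state`, and monomorphic
#' eligible columns enter class 0 or `n`. Columns are excluded (with a
#' logged reason) when any haplotype codon is ambiguous
#' (`missing_data`), the amino acid has no major codon (`no_major`), the
#' column segregates two minor codons (`two_minor`), more than two codon
#' states (`multistate`), or a nonsynonymous change (`nonsynonymous`).
#'
#' @param alns A `haplotype_alignment` or list of them, with a common
#'   sample size.
#' @param majors Major-codon table from [major_codons()].
#' @param focal `"major"` (default) or `"minor"`: the state whose carrier
#'   count indexes the spectrum.
#' @return An [new_sfs()] object.
#' @export
site_frequency_spectrum <- function(alns, majors, focal = c("major", "minor")) {
  focal <- match.arg(focal)
  if (inherits(alns, "haplotype_alignment")) alns <- list(alns)
  n <- length(alns[[1]]$sequences)
  if (!all(vapply(alns, function(a) length(a$sequences), integer(1)) == n)) {
    stop("sample size differs across genes; project or subset first", call. = FALSE)
  }
  major_of <- stats::setNames(majors$is_major, majors$codon)
  aa_of <- stats::setNames(majors$aa, majors$codon)
  counts <- numeric(n + 1L)
  excl <- c(
    missing_data = 0L, no_major = 0L, two_minor = 0L,
    multistate = 0L, nonsynonymous = 0L
  )
  for (aln in alns) {
    m <- alignment_matrix(aln)
    cods_mat <- .codon_matrix(m)
    L <- ncol(cods_mat)
    for (ci in seq_len(L)) {
      cods <- cods_mat[, ci]
      if (any(grepl("[^ACGT]", cods))) {
        excl["missing_data"] <- excl["missing_data"] + 1L
        next
      }
      states <- unique(cods)
      known <- states %in% names(major_of)
      if (!all(known)) { # stop codon or onefold amino acid
        excl["no_major"] <- excl["no_major"] + 1L
        next
      }
      if (length(states) == 1L) {
        i <- if (major_of[states]) n else 0L
        if (focal == "minor") i <- n - i
        counts[i + 1L] <- counts[i + 1L] + 1
        next
      }
      if (length(states) > 2L) {
        excl["multistate"] <- excl["multistate"] + 1L
        next
      }
      if (aa_of[states[1]] != aa_of[states[2]]) {
        excl["nonsynonymous"] <- excl["nonsynonymous"] + 1L
        next
      }
      is_mj <- major_of[states]
      if (sum(is_mj) != 1L) {
        excl["two_minor"] <- excl["two_minor"] + 1L
        next
      }
      major_state <- states[is_mj]
      i <- sum(cods == major_state)
      if (focal == "minor") i <- n - i
      counts[i + 1L] <- counts[i + 1L] + 1
    }
  }
  new_sfs(counts, n, focal = focal, excluded = excl)
}

#' Read / write an SFS as TSV
#'
#' Two columns `i` and `count`; the header line carries `n` and the focal
#' state as a comment.
#'
#' @param x An `sfs` object (for writing).
#' @param path File path.
#' @param focal Focal-state label used when reading.
#' @return `read_sfs()` returns an `sfs`; `write_sfs()` returns `path`.
#' @export
write_sfs <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n=%d focal=%s", attr(x, "n"), attr(x, "focal")), con)
  utils::write.table(as.data.frame(x)[, c("i", "count")], con,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path, focal = NULL) {
  first <- readLines(path, n = 1)
  hdr_focal <- sub(".*focal=(\\w+).*", "\\1", first)
  if (is.null(focal)) focal <- if (grepl("focal=", first)) hdr_focal else "major"
  tbl <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  new_sfs(tbl$count, n = max(tbl$i), focal = focal)
}
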