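#' Convert k-mer coverage to per-base read coverage
#'
#' A read of length `r` contributes `r - k + 1` k-mers, so mean k-mer depth
#' understates per-base depth by that factor:
#' `base = kmer * r / (r - k + 1)`.
#'
#' @param kmer_cov Mean k-mer depth (non-negative, vectorised).
#' @param read_length Read length in bp.
#' @param kmer_size k-mer size in bp; must not exceed `read_length`.
#' @return Per-base coverage on the same scale.
#' @examples
#' kmer_to_base_coverage(32, read_length = 100, kmer_size = 21)  # 40
#' @export
kmer_to_base_coverage <- function(kmer_cov, read_length, kmer_size) {
  if (kmer_size < 1 || kmer_size > read_length) {
    stop("kmer_size must satisfy 1 <= kmer_size <= read_length")
  }
  if (any(kmer_cov < 0)) stop("kmer_cov must be non-negative")
  kmer_cov * read_length / (read_length - kmer_size + 1)
}

#' Correct mean contig coverage for the trapezoidal read-depth profile
#'
#' Depth over a contig of length `L` ramps up over the first `r - 1` bases,
#' plateaus, and ramps down, because fully contained reads can start at only
#' `L - r + 1` positions. The mean over the whole trapezoid relative to its
#' plateau is `(L - r + 1) / L`, so the plateau-equivalent coverage is
#' `base_cov * L / (L - r + 1)`.
#'
#' @param base_cov Mean per-base coverage over the contig (vectorised).
#' @param contig_length Contig length in bp; must be >= `read_length`.
#' @param read_length Read length in bp.
#' @return Plateau-corrected coverage.
#' @export
trapezoid_correction <- function(base_cov, contig_length, read_length) {
  if (any(contig_length < read_length)) {
    stop("contig_length must be >= read_length")
  }
  if (any(base_cov < 0)) stop("base_cov must be non-negative")
  base_cov * contig_length / (contig_length - read_length + 1)
}

#' Estimate diploid copy number from per-group coverage
#'
#' Applies (optionally) the k-mer and trapezoid corrections, then normalises
#' by each individual's genome-wide coverage on the diploid scale:
#' `cn = 2 * corrected_coverage / genome_coverage`, so a segment covered at
#' the genome-wide depth is estimated at two copies.
#'
#' @param coverage A data frame with columns `individual_id`, `group_id`,
#'   `coverage` (per-base coverage, or mean k-mer depth when `kmer_size` is
#'   given) and `genome_coverage`; optionally `contig_length` to enable the
#'   trapezoid correction.
#' @param read_length,kmer_size Read and k-mer lengths. When `kmer_size` is
#'   `NULL` (default) the `coverage` column is taken as per-base coverage and
#'   the k-mer conversion is skipped.
#' @return A tibble with `individual_id`, `group_id`, `cn_estimate` and a
#'   `path` provenance column recording which corrections were applied.
#' @seealso [kmer_to_base_coverage()], [trapezoid_correction()]
#' @export
estimate_copy_number <- function(coverage, read_length = NULL,
                                 kmer_size = NULL) {
  req <- c("individual_id", "group_id", "coverage", "genome_coverage")
  missing_cols <- setdiff(req, names(coverage))
  if (length(missing_cols) > 0L) {
    stop("coverage table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(coverage$genome_coverage <= 0)) {
    stop("genome_coverage must be positive for all individuals")
  }
  cov <- coverage$coverage
  path <- "base"
  if (!is.null(kmer_size)) {
    if (is.null(read_length)) stop("read_length required for k-mer conversion")
    cov <- kmer_to_base_coverage(cov, read_length, kmer_size)
    path <- "kmer>base"
  }
  if ("contig_length" %in% names(coverage)) {
    if (is.null(read_length)) stop("read_length required for trapezoid correction")
    cov <- trapezoid_correction(cov, coverage$contig_length, read_length)
    path <- paste0(path, ">trapezoid")
  }
  tibble::tibble(
    individual_id = coverage$individual_id,
    group_id = coverage$group_id,
    cn_estimate = 2 * cov / coverage$genome_coverage,
    path = path
  )
}

#' Copy-number estimates as an individuals-by-groups matrix
#'
#' @param cn Output of [estimate_copy_number()] (long format).
#' @return Numeric matrix with individuals as rows and groups as columns.
#' @export
cn_matrix <- function(cn) {
  inds <- unique(cn$individual_id)
  grps <- unique(cn$group_id)
  m <- matrix(NA_real_, length(inds), length(grps),
              dimnames = list(inds, grps))
  m[cbind(match(cn$individual_id, inds), match(cn$group_id, grps))] <-
    cn$cn_estimate
  m
}

#' Flag groups that behave as two-copy across a cohort
#'
#' A group is designated two-copy when at least `threshold` of the cohort's
#' copy-number estimates round to 2. Two-copy groups are the substrate for
#' SNV/allelic analyses, where copy number would otherwise confound
#' diversity.
#'
#' @param cn Long copy-number table from [estimate_copy_number()].
#' @param threshold Required fraction of estimates rounding to 2
#'   (default 0.95).
#' @return Character vector of two-copy group ids.
#' @export
designate_two_copy_groups <- function(cn, threshold = 0.95) {
  frac2 <- tapply(round(cn$cn_estimate) == 2, cn$group_id, mean)
  names(frac2)[!is.na(frac2) & frac2 >= threshold]
}
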