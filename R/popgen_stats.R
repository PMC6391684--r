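#' Average pairwise base-pair difference between alleles
#'
#' For each segment group with at least two called alleles, the mean Hamming
#' difference (as a percentage of the compared length, the common prefix of
#' each pair) over all unordered distinct-allele pairs; the result is the
#' unweighted mean over groups. A frequency-weighted variant (pairs weighted
#' by the product of haplotype counts) is available via `weights`.
#'
#' @param allele_seqs Tibble with columns `group_id`, `allele_name`, `seq`.
#' @param weights Optional numeric vector (parallel to `allele_seqs` rows) of
#'   haplotype counts for frequency weighting; `NULL` (default) weights all
#'   distinct allele pairs equally.
#' @return Percentage in \[0, 100\]. Groups with fewer than two alleles are
#'   skipped with a warning; if no group qualifies, an error is raised.
#' @export
avg_pairwise_bp_difference <- function(allele_seqs, weights = NULL) {
  per_group <- c()
  for (g in unique(allele_seqs$group_id)) {
    idx <- which(allele_seqs$group_id == g)
    if (length(idx) < 2L) {
      warning("group with <2 alleles skipped: ", g)
      next
    }
    prs <- utils::combn(idx, 2)
    diffs <- apply(prs, 2, function(ij) {
      a <- allele_seqs$seq[ij[1]]; b <- allele_seqs$seq[ij[2]]
      l <- min(nchar(a), nchar(b))
      100 * length(prefix_mismatch_positions(a, b)) / l
    })
    w <- if (is.null(weights)) rep(1, ncol(prs)) else {
      apply(prs, 2, function(ij) weights[ij[1]] * weights[ij[2]])
    }
    per_group <- c(per_group, sum(diffs * w) / sum(w))
  }
  if (length(per_group) == 0L) stop("no group with >= 2 alleles")
  mean(per_group)
}

#' Average number of SNPs per two-copy segment
#'
#' Total SNP positions divided by the number of designated two-copy groups
#' (zero-SNP groups count in the denominator).
#'
#' @param snp_table Output of [identify_snps()].
#' @param two_copy_groups Character vector of all designated two-copy group
#'   ids.
#' @return Mean SNPs per segment group.
#' @export
snps_per_segment <- function(snp_table, two_copy_groups) {
  if (length(two_copy_groups) == 0L) stop("empty two-copy group list")
  n_snps <- nrow(unique(snp_table[, c("group_id", "position")]))
  n_snps / length(two_copy_groups)
}

#' Fraction of novel alleles among called alleles
#'
#' @param callset An `allele_callset`.
#' @return List with `novel`, `total` and `fraction` over distinct called
#'   alleles.
#' @export
novel_fraction <- function(callset) {
  stopifnot(inherits(callset, "allele_callset"))
  tab <- callset$table
  if (nrow(tab) == 0L) stop("no called alleles")
  list(novel = sum(tab$novel), total = nrow(tab),
       fraction = sum(tab$novel) / nrow(tab))
}

#' Variants private to a geographic region
#'
#' A variant (allele or SNV state) is private to region R when every carrier
#' individual belongs to R. Regional frequency is carrier haplotypes over
#' twice the region's cohort size.
#'
#' @param carriers Tibble with columns `kind` (`"allele"` or `"SNV"`),
#'   `variant_id`, `group_id`, `individual_id`, `n_haplotypes` (haplotypes
#'   the individual carries the variant on).
#' @param metadata Tibble with `individual_id`, `region`.
#' @return Tibble of private variants: `kind`, `variant_id`, `group_id`,
#'   `region`, `n_carrier_individuals`, `n_carrier_haplotypes`,
#'   `regional_frequency`.
#' @seealso [allele_carriers()], [snv_carriers()]
#' @export
private_variants <- function(carriers, metadata) {
  if (nrow(carriers) == 0L) {
    return(tibble::tibble(kind = character(0), variant_id = character(0),
                          group_id = character(0), region = character(0),
                          n_carrier_individuals = integer(0),
                          n_carrier_haplotypes = integer(0),
                          regional_frequency = numeric(0)))
  }
  carriers$region <- metadata$region[match(carriers$individual_id,
                                           metadata$individual_id)]
  region_sizes <- table(metadata$region)
  carriers |>
    dplyr::group_by(.data$kind, .data$variant_id, .data$group_id) |>
    dplyr::summarise(
      n_regions = dplyr::n_distinct(.data$region),
      region = .data$region[1],
      n_carrier_individuals = dplyr::n_distinct(.data$individual_id),
      n_carrier_haplotypes = sum(.data$n_haplotypes),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_regions == 1L, .data$n_carrier_individuals >= 1L) |>
    dplyr::mutate(regional_frequency = .data$n_carrier_haplotypes /
                    (2 * as.numeric(region_sizes[.data$region]))) |>
    dplyr::select(-"n_regions")
}

#' Carrier table for called alleles
#'
#' @param callset An `allele_callset`.
#' @return Carrier tibble suitable for [private_variants()].
#' @export
allele_carriers <- function(callset) {
  calls <- callset$calls[callset$calls$called, , drop = FALSE]
  calls |>
    dplyr::group_by(.data$group_id, .data$allele_name, .data$individual_id) |>
    dplyr::summarise(n_haplotypes = dplyr::n(), .groups = "drop") |>
    dplyr::transmute(kind = "allele",
                     variant_id = .data$allele_name,
                     group_id = .data$group_id,
                     individual_id = .data$individual_id,
                     n_haplotypes = .data$n_haplotypes)
}

#' Carrier table for SNV states
#'
#' Expands the per-state carrier lists of [identify_snps()] into one row per
#' carrier individual. SNV identifiers follow the `SEGMENT_{base}{position}`
#' convention (alternative base then 0-based position).
#'
#' @param snp_table Output of [identify_snps()].
#' @param callset The `allele_callset` the SNPs came from (used to count
#'   haplotypes per carrier).
#' @return Carrier tibble suitable for [private_variants()].
#' @export
snv_carriers <- function(snp_table, callset) {
  if (nrow(snp_table) == 0L) {
    return(tibble::tibble(kind = character(0), variant_id = character(0),
                          group_id = character(0),
                          individual_id = character(0),
                          n_haplotypes = integer(0)))
  }
  calls <- callset$calls
  rows <- lapply(seq_len(nrow(snp_table)), function(i) {
    g <- snp_table$group_id[i]; p <- snp_table$position[i]
    b <- snp_table$base[i]
    sub <- calls[calls$group_id == g, , drop = FALSE]
    has <- substr(sub$hap_seq, p + 1L, p + 1L) == b
    carr <- sub[has, , drop = FALSE]
    n_h <- table(carr$individual_id)
    tibble::tibble(kind = "SNV",
                   variant_id = paste0(sub("\\^$", "", g), "_", tolower(b), p),
                   group_id = g,
                   individual_id = names(n_h),
                   n_haplotypes = as.integer(n_h))
  })
  dplyr::bind_rows(rows)
}

#' Weir-Cockerham fixation index for haplotype data
#'
#' The Weir & Cockerham (1984) variance-components estimator theta, applied
#' to haplotype (haploid) counts: for each locus and allele, the
#' among-region component `a = (MSP - MSG) / n_c` and within-region component
#' `b = MSG` are computed from the weighted mean squares of allele indicator
#' variables, and theta is the ratio `sum(a) / sum(a + b)` over alleles
#' (per locus) and over loci and alleles (overall).
#'
#' @param counts Named list, one element per locus, each a numeric matrix of
#'   haplotype counts with regions as rows and alleles as columns.
#' @return List of class `fst_result` with `per_locus` tibble
#'   (`locus`, `theta`), `overall` theta, and `regions`. Monomorphic loci
#'   give `NA` per-locus theta; a fully monomorphic input gives `NA` overall.
#' @export
fst_weir_cockerham <- function(counts) {
  if (!is.list(counts) || length(counts) == 0L) {
    stop("counts must be a non-empty named list of region x allele matrices")
  }
  a_tot <- 0; ab_tot <- 0
  per_locus <- list()
  regions <- rownames(counts[[1]])
  for (locus in names(counts)) {
    m <- counts[[locus]]
    n_i <- rowSums(m)
    keep <- n_i >= 2
    m <- m[keep, , drop = FALSE]
    n_i <- n_i[keep]
    r <- nrow(m)
    if (r < 2L) stop("locus ", locus, ": need >= 2 regions with >= 2 haplotypes")
    N <- sum(n_i)
    n_c <- (N - sum(n_i^2) / N) / (r - 1)
    p <- m / n_i
    a_loc <- 0; ab_loc <- 0
    for (u in seq_len(ncol(m))) {
      p_u <- p[, u]
      pbar <- sum(n_i * p_u) / N
      msp <- sum(n_i * (p_u - pbar)^2) / (r - 1)
      msg <- sum(n_i * p_u * (1 - p_u)) / (N - r)
      a <- (msp - msg) / n_c
      a_loc <- a_loc + a
      ab_loc <- ab_loc + a + msg
    }
    theta_loc <- if (ab_loc == 0) NA_real_ else a_loc / ab_loc
    per_locus[[length(per_locus) + 1L]] <-
      tibble::tibble(locus = locus, theta = theta_loc)
    a_tot <- a_tot + a_loc
    ab_tot <- ab_tot + ab_loc
  }
  structure(list(per_locus = dplyr::bind_rows(per_locus),
                 overall = if (ab_tot == 0) NA_real_ else a_tot / ab_tot,
                 regions = regions),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("<fst_result> overall theta = ",
      if (is.na(x$overall)) "NA (monomorphic)" else format(round(x$overall, 4)),
      " over ", nrow(x$per_locus), " locus/loci, ",
      length(x$regions), " regions\n", sep = "")
  invisible(x)
}

#' Region x allele haplotype count matrices from an allele callset
#'
#' @param callset An `allele_callset`.
#' @param metadata Tibble with `individual_id`, `region`.
#' @return Named list (per group) of region x allele count matrices, ready
#'   for [fst_weir_cockerham()]. Uncalled haplotypes are excluded.
#' @export
allele_counts_by_region <- function(callset, metadata) {
  calls <- callset$calls[callset$calls$called, , drop = FALSE]
  calls$region <- metadata$region[match(calls$individual_id,
                                        metadata$individual_id)]
  out <- list()
  for (g in unique(calls$group_id)) {
    sub <- calls[calls$group_id == g, , drop = FALSE]
    out[[g]] <- unclass(table(sub$region, sub$allele_name))
  }
  out
}

#' Compare two per-segment allele-count distributions
#'
#' Two-sample Kolmogorov-Smirnov test of the per-segment allele counts from
#' two loci (asymptotic p-value by default; exact available for small
#' samples).
#'
#' @param counts_a,counts_b Numeric vectors of per-segment allele counts.
#' @param exact Use the exact p-value (default FALSE, asymptotic).
#' @return List with `statistic` (max ECDF gap) and `p_value`.
#' @export
compare_allele_count_distributions <- function(counts_a, counts_b,
                                               exact = FALSE) {
  if (length(counts_a) == 0L || length(counts_b) == 0L) {
    stop("both count vectors must be non-empty")
  }
  kt <- suppressWarnings(stats::ks.test(counts_a, counts_b, exact = exact))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}
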