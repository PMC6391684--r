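#' Define a copy-number polymorphism
#'
#' A CNV polymorphism is a set of operational groups that co-vary on one
#' haplotype, together with its candidate haploid variant configurations
#' (per-group haploid copy vectors). Diploid genotype classes are derived as
#' all unordered sums of haploid variant pairs. Polymorphism definitions are
#' configuration inputs (mirroring the schematic descriptions of known
#' insertion/deletion blocks), not discovered de novo.
#'
#' @param polymorphism_id Identifier string.
#' @param group_ids Ordered character vector of operational group ids.
#' @param haploid_variants Named list of non-negative integer vectors, one per
#'   variant, each of length `length(group_ids)` giving haploid copies per
#'   group.
#' @return An object of class `cnv_polymorphism` with derived
#'   `diploid_classes`: a list with `label` (e.g. `"ins/del"`), `hap_pair`
#'   and the summed per-group `vector`.
#' @examples
#' poly <- cnv_polymorphism("ins_block", c("gA^", "gB^"),
#'                          list(ins = c(1L, 1L), del = c(0L, 1L)))
#' poly
#' @export
cnv_polymorphism <- function(polymorphism_id, group_ids, haploid_variants) {
  stopifnot(is.character(group_ids), length(group_ids) >= 1L)
  if (is.null(names(haploid_variants)) || anyDuplicated(names(haploid_variants))) {
    stop("haploid_variants must be a uniquely named list")
  }
  for (v in haploid_variants) {
    if (length(v) != length(group_ids) || any(v < 0) || any(v != round(v))) {
      stop("each haploid variant must be a non-negative integer vector over ",
           "the polymorphism's groups")
    }
  }
  vs <- names(haploid_variants)
  pairs <- which(upper.tri(diag(length(vs)), diag = TRUE), arr.ind = TRUE)
  classes <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, "row"]; j <- pairs[k, "col"]
    list(label = paste(vs[i], vs[j], sep = "/"),
         hap_pair = c(vs[i], vs[j]),
         vector = as.integer(haploid_variants[[i]] + haploid_variants[[j]]))
  })
  names(classes) <- vapply(classes, `[[`, character(1), "label")
  structure(list(polymorphism_id = polymorphism_id,
                 group_ids = group_ids,
                 haploid_variants = lapply(haploid_variants, as.integer),
                 diploid_classes = classes),
            class = "cnv_polymorphism")
}

#' @export
print.cnv_polymorphism <- function(x, ...) {
  cat("<cnv_polymorphism> ", x$polymorphism_id, ": ",
      length(x$group_ids), " group(s), ",
      length(x$haploid_variants), " haploid variant(s), ",
      length(x$diploid_classes), " diploid class(es)\n", sep = "")
  invisible(x)
}

#' Call integer CNV genotypes for one polymorphism by clustering
#'
#' Individuals' continuous copy-number estimate vectors over the
#' polymorphism's groups are clustered agglomeratively (Ward linkage on
#' Euclidean distance). The number of clusters equals the number of diploid
#' genotype classes with non-trivial support (each individual's nearest class
#' by Euclidean distance; capped at the number of classes and at the number
#' of distinct estimate vectors). Each cluster is then assigned to the
#' diploid class nearest its centroid, ties broken toward lower total copy
#' number then lexicographic label.
#'
#' Clustering may use only a subset of the polymorphism's groups
#' (`groups` argument); assigned class vectors still cover all groups, which
#' lets held-out groups validate a call.
#'
#' @param estimates Numeric matrix, individuals x groups (rownames are
#'   individual ids), e.g. from [cn_matrix()].
#' @param polymorphism A [cnv_polymorphism()].
#' @param groups Optional subset of the polymorphism's group ids to cluster
#'   on (default: all).
#' @return An object of class `cnv_callset`: list with `polymorphism`,
#'   `calls` (tibble: `individual_id`, `cluster`, `class_label`, plus one
#'   integer `cn_<group>` column per group) and `centroids`.
#' @export
cluster_copy_numbers <- function(estimates, polymorphism, groups = NULL) {
  stopifnot(inherits(polymorphism, "cnv_polymorphism"))
  groups <- groups %||% polymorphism$group_ids
  if (!all(groups %in% polymorphism$group_ids)) {
    stop("groups must be a subset of the polymorphism's group ids")
  }
  missing_g <- setdiff(groups, colnames(estimates))
  if (length(missing_g) > 0L) {
    stop("estimate matrix lacks group(s): ", paste(missing_g, collapse = ", "))
  }
  X <- estimates[, groups, drop = FALSE]
  if (nrow(X) < 2L) stop("need at least 2 individuals")
  gi <- match(groups, polymorphism$group_ids)
  classes <- polymorphism$diploid_classes
  class_mat <- do.call(rbind, lapply(classes, function(cl) cl$vector[gi]))
  rownames(class_mat) <- names(classes)

  # support: nearest class per individual on the clustered groups
  d2 <- outer(rowSums(X^2), rep(1, nrow(class_mat))) -
    2 * X %*% t(class_mat) +
    outer(rep(1, nrow(X)), rowSums(class_mat^2))
  nearest <- apply(d2, 1, which.min)
  k <- length(unique(nearest))
  k <- min(k, nrow(class_mat), nrow(unique(X)))
  if (nrow(unique(X)) == 1L) {
    if (length(classes) > 1L) {
      warning("all estimate vectors identical; returning a single cluster")
    }
    k <- 1L
  }
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)

  centroids <- do.call(rbind, lapply(seq_len(k), function(i) {
    colMeans(X[cl == i, , drop = FALSE])
  }))
  assign_class <- function(centroid) {
    d <- sqrt(colSums((t(class_mat) - centroid)^2))
    cand <- which(d <= min(d) + 1e-12)
    if (length(cand) > 1L) {
      tot <- vapply(classes[cand], function(x) sum(x$vector), numeric(1))
      cand <- cand[tot == min(tot)]
      cand <- cand[order(names(classes)[cand])]
    }
    names(classes)[cand[1]]
  }
  cluster_class <- vapply(seq_len(k), function(i) assign_class(centroids[i, ]),
                          character(1))
  class_label <- cluster_class[cl]
  full_vec <- do.call(rbind, lapply(class_label, function(lbl) classes[[lbl]]$vector))
  colnames(full_vec) <- paste0("cn_", polymorphism$group_ids)
  calls <- tibble::tibble(individual_id = rownames(X),
                          cluster = unname(cl),
                          class_label = unname(class_label))
  calls <- dplyr::bind_cols(calls, tibble::as_tibble(full_vec))
  structure(list(polymorphism = polymorphism, calls = calls,
                 centroids = centroids, groups_used = groups),
            class = "cnv_callset")
}

#' @export
print.cnv_callset <- function(x, ...) {
  cat("<cnv_callset> ", x$polymorphism$polymorphism_id, ": ",
      nrow(x$calls), " individuals, ",
      length(unique(x$calls$class_label)), " diploid class(es) called\n",
      sep = "")
  invisible(x)
}

#' Smallest possible largest haploid copy number
#'
#' Given the largest diploid total copy number observed for a segment group,
#' the most balanced decomposition into two haplotype counts bounds the
#' largest haploid copy number from below: `ceiling(max_diploid / 2)`. For
#' example a diploid total of 13 decomposes most evenly into 6 + 7, so the
#' largest haploid count is at least 7.
#'
#' @param max_diploid Largest observed diploid total copy number (>= 0).
#' @return Integer: the larger part of the most balanced two-part
#'   decomposition.
#' @examples
#' min_max_haploid(13)  # 7
#' min_max_haploid(7)   # 4
#' @export
min_max_haploid <- function(max_diploid) {
  if (length(max_diploid) != 1L || is.na(max_diploid) || max_diploid < 0 ||
      max_diploid != round(max_diploid)) {
    stop("max_diploid must be a single non-negative integer")
  }
  as.integer(ceiling(max_diploid / 2))
}

#' Relative abundance of haploid variants (or diploid totals)
#'
#' For polymorphisms whose diploid classes map uniquely back to haplotype
#' pairs (always true with two haploid variants), haploid variants are
#' counted directly from assigned classes -- each individual contributes two
#' haplotypes -- and fractions over all sampled haplotypes are returned. When
#' different haplotype pairs yield identical diploid vectors (possible with
#' three or more variants, e.g. high-copy single-group polymorphisms), the
#' haplotype-level decomposition is ambiguous, and abundances are instead
#' reported over diploid total copy number, the same summary used for
#' high-copy groups in practice.
#'
#' @param callset A `cnv_callset` from [cluster_copy_numbers()].
#' @param mode `"auto"` (default), `"haploid"` or `"diploid"`.
#' @return Tibble with `variant`, `count`, `fraction` and a `level`
#'   attribute-like column (`"haploid"` or `"diploid_total"`).
#' @export
variant_relative_abundance <- function(callset,
                                       mode = c("auto", "haploid", "diploid")) {
  mode <- match.arg(mode)
  stopifnot(inherits(callset, "cnv_callset"))
  if (nrow(callset$calls) == 0L) stop("empty call set")
  classes <- callset$polymorphism$diploid_classes
  vecs <- vapply(classes, function(x) paste(x$vector, collapse = ","),
                 character(1))
  degenerate <- anyDuplicated(vecs) > 0L
  if (mode == "auto") mode <- if (degenerate) "diploid" else "haploid"
  if (mode == "haploid") {
    if (degenerate) {
      stop("diploid classes are degenerate; haploid decomposition ambiguous")
    }
    haps <- unlist(lapply(callset$calls$class_label,
                          function(lbl) classes[[lbl]]$hap_pair))
    tab <- table(haps)
    tibble::tibble(variant = names(tab),
                   count = as.integer(tab),
                   fraction = as.numeric(tab) / sum(tab),
                   level = "haploid")
  } else {
    tot <- vapply(callset$calls$class_label,
                  function(lbl) sum(classes[[lbl]]$vector), numeric(1))
    tab <- table(tot)
    tibble::tibble(variant = names(tab),
                   count = as.integer(tab),
                   fraction = as.numeric(tab) / sum(tab),
                   level = "diploid_total")
  }
}

#' Pairwise squared Pearson correlation of copy-number estimates
#'
#' @param estimates Numeric matrix, individuals x groups, with at least 3
#'   rows.
#' @return List of class `cnv_r2` with `group_ids` and the symmetric
#'   `r_squared` matrix (diagonal 1). Constant columns give `NA` entries,
#'   which are excluded from averages.
#' @export
pairwise_r_squared <- function(estimates) {
  if (nrow(estimates) < 3L) stop("need at least 3 individuals")
  sds <- apply(estimates, 2, stats::sd)
  r2 <- suppressWarnings(stats::cor(estimates))^2
  r2[sds == 0, ] <- NA_real_
  r2[, sds == 0] <- NA_real_
  diag(r2) <- 1
  structure(list(group_ids = colnames(estimates), r_squared = r2),
            class = "cnv_r2")
}

#' Mean off-block R-squared between polymorphisms
#'
#' Averages the squared correlation over group pairs belonging to different
#' polymorphisms -- the quantity summarising whether copy-number
#' polymorphisms segregate independently.
#'
#' @param r2 A `cnv_r2` from [pairwise_r_squared()].
#' @param polymorphisms List of [cnv_polymorphism()] objects defining the
#'   blocks.
#' @return Mean off-block R-squared (NA entries dropped).
#' @export
mean_off_block_r2 <- function(r2, polymorphisms) {
  stopifnot(inherits(r2, "cnv_r2"))
  block <- rep(NA_character_, length(r2$group_ids))
  names(block) <- r2$group_ids
  for (p in polymorphisms) {
    block[p$group_ids[p$group_ids %in% names(block)]] <- p$polymorphism_id
  }
  m <- r2$r_squared
  keep <- outer(block, block, FUN = function(a, b) a != b)
  vals <- m[upper.tri(m) & keep]
  mean(vals, na.rm = TRUE)
}

#' Estimated number of locus-wide CNV haplotypes under independence
#'
#' With independent polymorphisms the number of locus-wide haplotypes is the
#' product of the per-polymorphism haploid variant counts (e.g.
#' `2 x 2 x 2 x 7 x 4 = 224` for five common polymorphisms).
#'
#' @param variant_counts Integer vector of per-polymorphism haploid variant
#'   counts, each >= 1.
#' @return Integer product.
#' @examples
#' haplotype_count_estimate(c(2, 2, 2, 7, 4))  # 224
#' @export
haplotype_count_estimate <- function(variant_counts) {
  if (length(variant_counts) == 0L) stop("variant_counts must be non-empty")
  if (any(variant_counts < 1) || any(variant_counts != round(variant_counts))) {
    stop("variant_counts must be integers >= 1")
  }
  as.integer(prod(variant_counts))
}

#' Chi-squared goodness-of-fit of regional genotype distributions
#'
#' Tests, for each geographic region, whether the distribution of assigned
#' diploid classes differs from the global distribution: expected counts are
#' the global class proportions scaled to the region's size, and the
#' statistic is `sum((O - E)^2 / E)` on `k - 1` degrees of freedom. The
#' asymptotic distribution is used even at small expected counts (regions as
#' small as 2 individuals occur); a warning notes expected counts below 5.
#'
#' @param callset A `cnv_callset`.
#' @param metadata Tibble with `individual_id` and `region`.
#' @param alpha Flagging level (default 0.01); a region is flagged when
#'   `p < alpha`.
#' @return Tibble with `region`, `n`, `statistic`, `df`, `p_value`,
#'   `flagged`, `min_expected`.
#' @export
regional_distribution_test <- function(callset, metadata, alpha = 0.01) {
  stopifnot(inherits(callset, "cnv_callset"))
  calls <- dplyr::inner_join(callset$calls, metadata, by = "individual_id")
  levels_cls <- sort(unique(calls$class_label))
  if (length(levels_cls) < 2L) {
    stop("need at least 2 genotype categories globally")
  }
  global <- table(factor(calls$class_label, levels = levels_cls))
  props <- as.numeric(global) / sum(global)
  regions <- unique(metadata$region)
  rows <- lapply(regions, function(r) {
    obs_all <- calls[calls$region == r, , drop = FALSE]
    if (nrow(obs_all) == 0L) {
      warning("region with zero individuals skipped: ", r)
      return(NULL)
    }
    o <- as.numeric(table(factor(obs_all$class_label, levels = levels_cls)))
    e <- props * sum(o)
    keep <- e > 0
    stat <- sum((o[keep] - e[keep])^2 / e[keep])
    df <- sum(keep) - 1L
    p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
    tibble::tibble(region = r, n = sum(o), statistic = stat, df = df,
                   p_value = p, flagged = p < alpha,
                   min_expected = min(e[keep]))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0L && any(out$min_expected < 5)) {
    warning("expected counts below 5 in some regions; ",
            "asymptotic chi-squared p-values are approximate")
  }
  out
}

#' Probability that two individuals differ in segment presence sets
#'
#' Two individuals differ when at least one operational group is present (in
#' any copy number) in one but absent in the other. Returns the fraction of
#' unordered pairs that differ, optionally stratified by region.
#'
#' @param presence Logical matrix, individuals x groups (TRUE = present), or
#'   an integer copy-number matrix (positive = present).
#' @param metadata Optional tibble with `individual_id`, `region`; required
#'   when `stratify_by_region` is TRUE.
#' @param stratify_by_region Compute per-region probabilities as well.
#' @return List with `overall` probability and (if stratified) a `by_region`
#'   tibble. Strata with fewer than 2 individuals are omitted with a warning.
#' @export
segment_set_difference_probability <- function(presence, metadata = NULL,
                                               stratify_by_region = FALSE) {
  if (is.numeric(presence)) presence <- presence > 0
  if (nrow(presence) < 2L) stop("need at least 2 individuals")
  sig <- apply(presence, 1, function(x) paste(as.integer(x), collapse = ""))
  prob_from_sig <- function(s) {
    n <- length(s)
    same <- sum(vapply(table(s), function(k) choose(k, 2), numeric(1)))
    1 - same / choose(n, 2)
  }
  out <- list(overall = prob_from_sig(sig))
  if (stratify_by_region) {
    if (is.null(metadata)) stop("metadata required for stratification")
    reg <- metadata$region[match(rownames(presence), metadata$individual_id)]
    rows <- lapply(unique(reg), function(r) {
      s <- sig[reg == r]
      if (length(s) < 2L) {
        warning("stratum with <2 individuals omitted: ", r)
        return(NULL)
      }
      tibble::tibble(region = r, n = length(s),
                     probability = prob_from_sig(s))
    })
    out$by_region <- dplyr::bind_rows(rows)
  }
  out
}
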