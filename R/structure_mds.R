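#' Allele copy matrix (individuals x alleles)
#'
#' Builds the genotype vectors underlying the population-structure embedding:
#' entry (i, m) is the number of copies of allele m carried by individual i,
#' in {0, 1, 2} for two-copy segments (homozygote 2, heterozygote 1 per
#' allele). Uncalled haplotypes contribute 0 and are recorded in a
#' missingness attribute; `complete_cases = TRUE` drops individuals with any
#' uncalled haplotype instead.
#'
#' @param callset An `allele_callset` restricted to two-copy groups.
#' @param allele_universe Optional character vector of `group|allele` column
#'   labels fixing the column set (default: all called alleles observed).
#' @param complete_cases Drop individuals with uncalled haplotypes.
#' @return Integer matrix with rownames = individual ids, colnames =
#'   `group|allele`; attribute `missingness` gives per-individual uncalled
#'   haplotype counts.
#' @export
allele_copy_matrix <- function(callset, allele_universe = NULL,
                               complete_cases = FALSE) {
  stopifnot(inherits(callset, "allele_callset"))
  calls <- callset$calls
  per_ind_grp <- table(calls$individual_id, calls$group_id)
  if (any(per_ind_grp > 2L)) {
    stop("individual with >2 haplotypes for a segment group")
  }
  inds <- sort(unique(calls$individual_id))
  called <- calls[calls$called, , drop = FALSE]
  lab <- paste(called$group_id, called$allele_name, sep = "|")
  cols <- allele_universe %||% sort(unique(lab))
  m <- matrix(0L, length(inds), length(cols), dimnames = list(inds, cols))
  keep <- lab %in% cols
  tab <- table(called$individual_id[keep], lab[keep])
  m[rownames(tab), colnames(tab)] <- as.integer(tab)
  miss <- table(factor(calls$individual_id[!calls$called], levels = inds))
  attr(m, "missingness") <- as.integer(miss)
  if (complete_cases) m <- m[miss == 0L, , drop = FALSE]
  m
}

#' Metric multidimensional scaling of allele copy vectors
#'
#' Embeds individuals so that Euclidean distances between their allele copy
#' vectors are preserved as well as possible, by SMACOF-style iterative
#' stress majorization. The default initialisation is classical scaling
#' (principal coordinates), which is deterministic; `init = "random"` draws
#' seeded Gaussian starting coordinates. Stress is normalised Kruskal
#' stress-1.
#'
#' @param x Numeric matrix (individuals x features) or a `dist` object.
#' @param dims Embedding dimension (default 2).
#' @param seed Seed for the random initialisation (ignored for
#'   `init = "classical"`).
#' @param init `"classical"` (default) or `"random"`.
#' @param max_iter,tol Majorization iteration controls.
#' @return Object of class `mds_embedding`: list with `coords` (matrix with
#'   individual rownames), `stress`, `iterations`, `converged`.
#' @export
mds_embed <- function(x, dims = 2L, seed = 1L, init = c("classical", "random"),
                      max_iter = 500L, tol = 1e-10) {
  init <- match.arg(init)
  D <- if (inherits(x, "dist")) as.matrix(x) else as.matrix(stats::dist(x))
  n <- nrow(D)
  if (n < dims + 1L) stop("need at least dims + 1 individuals")
  ids <- rownames(D) %||% as.character(seq_len(n))
  if (init == "classical") {
    Y <- suppressWarnings(stats::cmdscale(D, k = dims))
    if (ncol(Y) < dims) {
      Y <- cbind(Y, matrix(0, n, dims - ncol(Y)))
    }
  } else {
    set.seed(seed)
    Y <- matrix(stats::rnorm(n * dims, sd = stats::sd(D) + 1e-9), n, dims)
  }
  denom <- sum(D[upper.tri(D)]^2)
  if (denom == 0) {
    # all points coincide
    coords <- matrix(0, n, dims, dimnames = list(ids, NULL))
    return(structure(list(coords = coords, stress = 0, iterations = 0L,
                          converged = TRUE), class = "mds_embedding"))
  }
  stress_of <- function(Y) {
    d <- as.matrix(stats::dist(Y))
    sqrt(sum((D[upper.tri(D)] - d[upper.tri(d)])^2) / denom)
  }
  s_old <- stress_of(Y)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    d <- as.matrix(stats::dist(Y))
    ratio <- ifelse(d > 0, D / d, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    Y <- B %*% Y / n
    s_new <- stress_of(Y)
    if (abs(s_old - s_new) < tol) {
      converged <- TRUE
      s_old <- s_new
      break
    }
    s_old <- s_new
  }
  rownames(Y) <- ids
  structure(list(coords = Y, stress = s_old, iterations = it,
                 converged = converged),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat("<mds_embedding> ", nrow(x$coords), " individuals in ",
      ncol(x$coords), "D, stress-1 = ", format(signif(x$stress, 4)),
      " (", x$iterations, " iterations)\n", sep = "")
  invisible(x)
}

#' Silhouette score of regional separation in an embedding
#'
#' Mean silhouette width of the region labels over Euclidean distances in
#' the embedding: near 1 for well-separated regional clouds, near 0 for no
#' structure.
#'
#' @param embedding An `mds_embedding` (or a coordinate matrix).
#' @param regions Character/factor vector of region labels, parallel to the
#'   embedding rows.
#' @return Mean silhouette width in \[-1, 1\].
#' @export
region_separation_score <- function(embedding, regions) {
  coords <- if (inherits(embedding, "mds_embedding")) embedding$coords else embedding
  if (length(regions) != nrow(coords)) {
    stop("regions must be parallel to embedding rows")
  }
  f <- factor(regions)
  if (nlevels(f) < 2L) stop("need at least 2 regions")
  if (any(table(f) == 1L)) {
    warning("region(s) of size 1 included per standard silhouette convention")
  }
  sil <- cluster::silhouette(as.integer(f), stats::dist(coords))
  mean(sil[, "sil_width"])
}
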