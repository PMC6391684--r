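test_that("average pairwise bp difference follows the per-segment mean", {
  tbl <- tibble::tibble(
    group_id = c("g1", "g1"),
    allele_name = c("a", "b"),
    seq = c(strrep("A", 100), strrep("A", 100)))
  expect_equal(avg_pairwise_bp_difference(tbl), 0)

  tbl$seq[2] <- paste0(strrep("A", 99), "C")
  expect_equal(avg_pairwise_bp_difference(tbl), 1)

  # 3 alleles, pairwise differences {1, 2, 3}/100 -> mean 2%
  s <- strrep("A", 100)
  s1 <- mutate_at(s, 1)
  s2 <- mutate_at(s, 2:3)
  # s1 vs s: 1; s2 vs s: 2; s1 vs s2: 3
  tbl3 <- tibble::tibble(group_id = "g", allele_name = c("x", "y", "z"),
                         seq = c(s, s1, s2))
  expect_equal(avg_pairwise_bp_difference(tbl3), 2)
  # permutation invariance
  expect_equal(avg_pairwise_bp_difference(tbl3[c(3, 1, 2), ]), 2)

  # groups with a single allele are skipped with a warning
  tbl4 <- dplyr::bind_rows(tbl3, tibble::tibble(group_id = "lonely",
                                                allele_name = "only",
                                                seq = s))
  expect_warning(res <- avg_pairwise_bp_difference(tbl4), "skipped")
  expect_equal(res, 2)
  expect_error(suppressWarnings(avg_pairwise_bp_difference(tbl4[4, ])),
               ">= 2")
})

test_that("SNPs per segment divides by all designated groups", {
  empty <- tibble::tibble(group_id = character(0), position = integer(0))
  expect_equal(snps_per_segment(empty, letters[1:5]), 0)
  snp <- tibble::tibble(group_id = rep(paste0("g", 1:5), times = c(5, 4, 3, 3, 2)),
                        position = c(1:5, 1:4, 1:3, 1:3, 1:2))
  expect_equal(snps_per_segment(snp, paste0("g", 1:10)), 1.7)
  one <- tibble::tibble(group_id = "g", position = 1:3)
  expect_equal(snps_per_segment(one, "g"), 3)
  expect_error(snps_per_segment(snp, character(0)), "empty")
})

test_that("novel fraction counts distinct called alleles", {
  fake <- structure(list(table = tibble::tibble(
    group_id = "g", allele_name = paste0("a", 1:10),
    novel = rep(c(TRUE, FALSE), c(4, 6)))), class = "allele_callset")
  nf <- novel_fraction(fake)
  expect_equal(nf$novel, 4L)
  expect_equal(nf$total, 10L)
  expect_equal(nf$fraction, 0.4)
})

test_that("private variants require all carriers in one region", {
  meta <- tibble::tibble(individual_id = paste0("i", 1:10),
                         region = rep(c("Africa", "Europe"), each = 5))
  carriers <- tibble::tibble(
    kind = "allele",
    variant_id = c("v1", "v1", "v2", "v2", "v2"),
    group_id = "g",
    individual_id = c("i1", "i6", "i1", "i2", "i3"),
    n_haplotypes = c(1L, 1L, 1L, 1L, 1L))
  pv <- private_variants(carriers, meta)
  expect_equal(pv$variant_id, "v2")           # v1 spans two regions
  expect_equal(pv$region, "Africa")
  expect_equal(pv$regional_frequency, 3 / (2 * 5))
})

test_that("privateness agrees with a brute-force oracle on random cohorts", {
  set.seed(91)
  for (trial in 1:20) {
    n <- sample(6:20, 1)
    meta <- tibble::tibble(individual_id = paste0("i", 1:n),
                           region = sample(c("A", "B", "C"), n, replace = TRUE))
    n_var <- sample(3:6, 1)
    carriers <- dplyr::bind_rows(lapply(seq_len(n_var), function(v) {
      carr <- sample(meta$individual_id, sample(1:4, 1))
      tibble::tibble(kind = "SNV", variant_id = paste0("v", v),
                     group_id = "g", individual_id = carr,
                     n_haplotypes = sample(1:2, length(carr), replace = TRUE))
    }))
    pv <- private_variants(carriers, meta)
    # oracle: direct loop over the definition
    for (v in unique(carriers$variant_id)) {
      regs <- unique(meta$region[match(
        carriers$individual_id[carriers$variant_id == v],
        meta$individual_id)])
      expect_equal(v %in% pv$variant_id, length(regs) == 1L)
    }
  }
})

# independent FST oracle: random-effects ANOVA on allele indicators via aov()
fst_anova_oracle <- function(counts_matrix) {
  n_i <- rowSums(counts_matrix)
  r <- nrow(counts_matrix)
  N <- sum(n_i)
  n_c <- (N - sum(n_i^2) / N) / (r - 1)
  a_sum <- 0; ab_sum <- 0
  for (u in seq_len(ncol(counts_matrix))) {
    y <- unlist(lapply(seq_len(r), function(i) {
      rep(c(1, 0), c(counts_matrix[i, u], n_i[i] - counts_matrix[i, u]))
    }))
    if (stats::var(y) == 0) next  # fixed allele: no variance components
    g <- factor(rep(rownames(counts_matrix), n_i))
    ms <- summary(stats::aov(y ~ g))[[1]][["Mean Sq"]]
    msb <- ms[1]; msw <- ms[2]
    a <- (msb - msw) / n_c
    a_sum <- a_sum + a
    ab_sum <- ab_sum + a + msw
  }
  if (ab_sum == 0) NA_real_ else a_sum / ab_sum
}

test_that("FST behaves at the boundaries of differentiation", {
  # identical frequencies in all regions, large n -> near zero
  eq <- list(l1 = rbind(r1 = c(A = 500, B = 500), r2 = c(A = 500, B = 500)))
  expect_lt(abs(fst_weir_cockerham(eq)$overall), 0.01)
  # alternate alleles fixed in the two regions -> ~1
  fix <- list(l1 = rbind(r1 = c(A = 50, B = 0), r2 = c(A = 0, B = 50)))
  expect_gt(fst_weir_cockerham(fix)$overall, 0.97)
  # monomorphic data: undefined, reported as NA
  mono <- list(l1 = rbind(r1 = c(A = 10), r2 = c(A = 10)))
  expect_true(is.na(fst_weir_cockerham(mono)$overall))
  expect_error(fst_weir_cockerham(list(l1 = rbind(r1 = c(A = 10, B = 2)))),
               "2 regions")
})

test_that("the worked two-region toy matches the variance-components oracle", {
  toy <- rbind(r1 = c(A = 10, B = 0), r2 = c(A = 5, B = 5))
  got <- fst_weir_cockerham(list(locus = toy))
  expect_equal(got$overall, fst_anova_oracle(toy), tolerance = 1e-12)
  expect_equal(got$per_locus$theta, got$overall)
})

test_that("KS comparison matches direct ECDF computation", {
  same <- compare_allele_count_distributions(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  disjoint <- compare_allele_count_distributions(rep(1, 4), rep(5, 4))
  expect_equal(disjoint$statistic, 1)

  a <- c(1, 1, 2, 3, 5); b <- c(2, 2, 3, 4, 4, 6)
  got <- compare_allele_count_distributions(a, b)
  grid <- sort(unique(c(a, b)))
  gap <- max(abs(stats::ecdf(a)(grid) - stats::ecdf(b)(grid)))
  expect_equal(got$statistic, gap)
  expect_error(compare_allele_count_distributions(numeric(0), b), "non-empty")
})
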