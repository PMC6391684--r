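test_that("diploid classes enumerate unordered haploid pairs", {
  poly <- cnv_polymorphism("p", c("a^", "b^"),
                           list(ins = c(1L, 1L), del = c(0L, 1L)))
  expect_equal(length(poly$diploid_classes), 3L)
  expect_equal(poly$diploid_classes[["ins/del"]]$vector, c(1L, 2L))
  expect_equal(poly$diploid_classes[["del/del"]]$vector, c(0L, 2L))
  expect_error(cnv_polymorphism("p", "a^", list(x = c(1L, 2L))), "groups")
  expect_error(cnv_polymorphism("p", "a^", list(c(1L))), "named")
})

test_that("noiseless planted genotypes are recovered exactly", {
  cfg <- small_sim_config(cv = 0, seed = 21L,
                          ins_freq = c(North = 0.4, South = 0.6))
  coh <- simulate_population(cfg)
  est <- cn_matrix(estimate_copy_number(coh$coverage))
  cs <- cluster_copy_numbers(est, cfg$polymorphisms[[1]])
  tc <- true_cn_matrix(coh)
  expect_equal(cs$calls$`cn_gIns1^`,
               unname(tc[cs$calls$individual_id, "gIns1^"]))
  expect_equal(cs$calls$`cn_gIns2^`,
               unname(tc[cs$calls$individual_id, "gIns2^"]))
})

test_that("genotype accuracy at cv = 0.08 exceeds 95% and degrades with noise", {
  acc_at <- function(cv, seed = 22L) {
    cfg <- small_sim_config(n_per_region = c(North = 100L, South = 100L),
                            cv = cv, seed = seed,
                            ins_freq = c(North = 0.4, South = 0.6))
    coh <- simulate_population(cfg)
    est <- cn_matrix(estimate_copy_number(coh$coverage))
    cs <- cluster_copy_numbers(est, cfg$polymorphisms[[1]])
    tc <- true_cn_matrix(coh)
    mean(cs$calls$`cn_gIns1^` == tc[cs$calls$individual_id, "gIns1^"] &
           cs$calls$`cn_gIns2^` == tc[cs$calls$individual_id, "gIns2^"])
  }
  expect_gte(acc_at(0.08), 0.95)
  expect_gte(acc_at(0.02), acc_at(0.30))
})

test_that("clustering on a subset of groups still resolves held-out groups", {
  cfg <- small_sim_config(n_per_region = c(North = 100L, South = 100L),
                          cv = 0.05, seed = 23L,
                          ins_freq = c(North = 0.5, South = 0.5))
  coh <- simulate_population(cfg)
  est <- cn_matrix(estimate_copy_number(coh$coverage))
  cs <- cluster_copy_numbers(est, cfg$polymorphisms[[1]], groups = "gIns1^")
  tc <- true_cn_matrix(coh)
  # the held-out group's class-implied CN agrees with its simulated truth
  acc <- mean(cs$calls$`cn_gIns2^` == tc[cs$calls$individual_id, "gIns2^"])
  expect_gte(acc, 0.95)
})

test_that("degenerate all-identical estimates collapse to one cluster", {
  poly <- cnv_polymorphism("p", "g^", list(one = 1L, two = 2L))
  est <- matrix(2, 10, 1, dimnames = list(paste0("i", 1:10), "g^"))
  expect_warning(cs <- cluster_copy_numbers(est, poly), "identical")
  expect_equal(length(unique(cs$calls$cluster)), 1L)
  expect_error(cluster_copy_numbers(est[1, , drop = FALSE], poly), "2 individuals")
})

test_that("balanced decomposition bounds the largest haploid copy number", {
  expect_identical(min_max_haploid(13), 7L)
  expect_identical(min_max_haploid(7), 4L)
  expect_identical(min_max_haploid(2), 1L)
  expect_identical(min_max_haploid(0), 0L)
  expect_error(min_max_haploid(-1))
  for (d in 0:25) {
    expect_equal(min_max_haploid(d) + floor(d / 2), d)
  }
})

test_that("relative abundances count haplotypes and sum to one", {
  poly <- cnv_polymorphism("p", c("a^", "b^"),
                           list(A = c(1L, 1L), B = c(0L, 1L)))
  fake_callset <- function(labels) {
    structure(list(polymorphism = poly,
                   calls = tibble::tibble(
                     individual_id = paste0("i", seq_along(labels)),
                     cluster = 1L, class_label = labels)),
              class = "cnv_callset")
  }
  ra <- variant_relative_abundance(fake_callset(rep("A/A", 20)))
  expect_equal(ra$variant, "A")
  expect_equal(ra$fraction, 1)

  ra2 <- variant_relative_abundance(
    fake_callset(c(rep("A/A", 50), rep("A/B", 50))))
  expect_equal(ra2$fraction[ra2$variant == "A"], 0.75)
  expect_equal(ra2$fraction[ra2$variant == "B"], 0.25)
  expect_equal(sum(ra2$fraction), 1)
  expect_equal(sum(ra2$count), 200L)  # 2 haplotypes per individual

  # planted frequencies recovered within 3 binomial SDs at n = 2000 haplotypes
  cfg <- small_sim_config(n_per_region = c(North = 1000L), cv = 0.05,
                          ins_freq = c(North = 0.72), seed = 24L)
  coh <- simulate_population(cfg)
  est <- cn_matrix(estimate_copy_number(coh$coverage))
  cs <- cluster_copy_numbers(est, cfg$polymorphisms[[1]])
  ra3 <- variant_relative_abundance(cs)
  p_hat <- ra3$fraction[ra3$variant == "ins"]
  expect_lt(abs(p_hat - 0.72), 3 * sqrt(0.72 * 0.28 / 2000))
})

test_that("degenerate diploid classes fall back to diploid totals", {
  poly <- cnv_polymorphism("high", "g^",
                           stats::setNames(as.list(0:2), c("0", "1", "2")))
  # 0+2 and 1+1 share the diploid vector 2 -> haploid decomposition ambiguous
  cs <- structure(list(polymorphism = poly,
                       calls = tibble::tibble(individual_id = c("a", "b"),
                                              cluster = 1L,
                                              class_label = c("0/2", "2/2"))),
                  class = "cnv_callset")
  ra <- variant_relative_abundance(cs)
  expect_equal(ra$level[1], "diploid_total")
  expect_setequal(ra$variant, c("2", "4"))
  expect_error(variant_relative_abundance(cs, mode = "haploid"), "ambiguous")
})

test_that("squared correlations flag linkage and clear independence", {
  set.seed(31)
  x <- rnorm(1000)
  m <- cbind(a = x, b = x, c = -x, d = rnorm(1000), e = rep(1, 1000))
  r2 <- pairwise_r_squared(m)
  expect_equal(r2$r_squared["a", "b"], 1)
  expect_equal(r2$r_squared["a", "c"], 1)  # sign-invariant
  expect_lt(r2$r_squared["a", "d"], 0.02)
  expect_true(is.na(r2$r_squared["a", "e"]))  # constant column
  expect_equal(diag(r2$r_squared), rep(1, 5), ignore_attr = TRUE)
  expect_true(isSymmetric(r2$r_squared))
  expect_error(pairwise_r_squared(m[1:2, ]), "3 individuals")
})

test_that("independent polymorphisms give near-zero off-block R-squared", {
  cfgA <- small_sim_config(n_per_region = c(North = 1000L), cv = 0.05,
                           ins_freq = c(North = 0.5), seed = 25L)
  cohA <- simulate_population(cfgA)
  estA <- cn_matrix(estimate_copy_number(cohA$coverage))
  cfgB <- small_sim_config(n_per_region = c(North = 1000L), cv = 0.05,
                           ins_freq = c(North = 0.3), seed = 26L)
  cohB <- simulate_population(cfgB)
  estB <- cn_matrix(estimate_copy_number(cohB$coverage))
  colnames(estB) <- c("gOther1^", "gOther2^")
  m <- cbind(estA, estB)
  polyA <- cfgA$polymorphisms[[1]]
  polyB <- cnv_polymorphism("other_block", c("gOther1^", "gOther2^"),
                            list(ins = c(1L, 1L), del = c(0L, 1L)))
  r2 <- pairwise_r_squared(m)
  expect_lt(mean_off_block_r2(r2, list(polyA, polyB)), 0.02)
})

test_that("haplotype counts multiply across independent polymorphisms", {
  expect_identical(haplotype_count_estimate(c(2, 2, 2, 7, 4)), 224L)
  expect_identical(haplotype_count_estimate(c(2, 2)), 4L)
  expect_identical(haplotype_count_estimate(1), 1L)
  expect_error(haplotype_count_estimate(integer(0)), "non-empty")
  expect_error(haplotype_count_estimate(c(2, 0)), ">= 1")
})

test_that("regional chi-squared flags only genuine departures", {
  poly <- cnv_polymorphism("p", "g^", list(A = 1L, B = 0L))
  mk <- function(labels, regions) {
    list(callset = structure(list(polymorphism = poly,
                                  calls = tibble::tibble(
                                    individual_id = paste0("i", seq_along(labels)),
                                    cluster = 1L, class_label = labels)),
                             class = "cnv_callset"),
         meta = tibble::tibble(individual_id = paste0("i", seq_along(labels)),
                               region = regions))
  }
  # proportions identical to global in both regions -> statistic 0
  x <- mk(rep(c("A/A", "A/B"), times = c(60, 60)),
          rep(c("r1", "r2"), 60))
  res <- suppressWarnings(
    regional_distribution_test(x$callset, x$meta, alpha = 0.01))
  expect_equal(res$statistic, c(0, 0))
  expect_false(any(res$flagged))

  # region r1 at 90/10 against a global 50/50 -> statistic 64, flagged
  y <- mk(c(rep("A/A", 90), rep("A/B", 10), rep("A/A", 10), rep("A/B", 90)),
          rep(c("r1", "r2"), each = 100))
  resy <- suppressWarnings(
    regional_distribution_test(y$callset, y$meta, alpha = 0.01))
  expect_equal(resy$statistic[resy$region == "r1"], 64)
  expect_true(all(resy$flagged))
  resy0 <- suppressWarnings(
    regional_distribution_test(y$callset, y$meta, alpha = 0))
  expect_false(any(resy0$flagged))

  # small expected counts emit a warning
  z <- mk(c("A/A", "A/B", "A/A", "A/B", "A/A"),
          c("r1", "r1", "r2", "r2", "r2"))
  expect_warning(regional_distribution_test(z$callset, z$meta), "expected")
})

test_that("segment-set difference probability counts differing pairs", {
  same <- matrix(TRUE, 5, 3,
                 dimnames = list(paste0("i", 1:5), paste0("g", 1:3)))
  expect_equal(segment_set_difference_probability(same)$overall, 0)

  two <- rbind(i1 = c(TRUE, TRUE), i2 = c(TRUE, FALSE))
  expect_equal(segment_set_difference_probability(two)$overall, 1)

  # sets {S, S, T, U}: 5 of 6 pairs differ
  m <- rbind(i1 = c(TRUE, TRUE, FALSE),
             i2 = c(TRUE, TRUE, FALSE),
             i3 = c(TRUE, FALSE, FALSE),
             i4 = c(FALSE, TRUE, TRUE))
  expect_equal(segment_set_difference_probability(m)$overall, 5 / 6)

  # stratification and the copy-number (integer) input path
  meta <- tibble::tibble(individual_id = rownames(m),
                         region = c("r1", "r1", "r1", "r2"))
  expect_warning(
    res <- segment_set_difference_probability(m * 2L, meta,
                                              stratify_by_region = TRUE),
    "omitted")
  expect_equal(res$by_region$probability[res$by_region$region == "r1"], 2 / 3)
})
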