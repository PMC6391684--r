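# phasing -------------------------------------------------------------------

test_that("homozygous error-free reads phase to the consensus", {
  ref <- rand_dna(200, 71)
  reads <- simulate_segment_reads(c(h1 = ref, h2 = ref), read_length = 80,
                                  depth = 20, seed = 1)
  ph <- phase_segment_reads(reads, ref)
  expect_equal(ph$hap1, ref)
  expect_equal(ph$hap2, ref)
  expect_equal(length(ph$het_positions), 0L)
  expect_false(ph$unlinked)
  expect_error(phase_segment_reads(reads[0, ], ref), "no reads")
})

test_that("linked heterozygous sites recover both planted haplotypes", {
  ref <- rand_dna(200, 72)
  alt <- mutate_at(ref, c(60, 100))  # two het sites 40 bp apart
  reads <- simulate_segment_reads(c(h1 = ref, h2 = alt), read_length = 80,
                                  depth = 25, seed = 2)
  ph <- phase_segment_reads(reads, ref)
  expect_setequal(c(ph$hap1, ph$hap2), c(ref, alt))
  expect_equal(ph$het_positions, c(60L, 100L))
  expect_false(ph$unlinked)
})

test_that("unlinkable het sites are flagged and phased deterministically", {
  ref <- rand_dna(400, 73)
  alt <- mutate_at(ref, c(50, 350))  # farther apart than any read
  reads <- simulate_segment_reads(c(h1 = ref, h2 = alt), read_length = 60,
                                  depth = 30, seed = 3)
  ph <- phase_segment_reads(reads, ref)
  expect_true(ph$unlinked)
  expect_equal(ph$het_positions, c(50L, 350L))
  ph2 <- phase_segment_reads(reads, ref)
  expect_identical(ph[c("hap1", "hap2")], ph2[c("hap1", "hap2")])
})

test_that("pileups with three strong base states are rejected", {
  ref <- paste(rep("A", 50), collapse = "")
  mk <- function(base) {
    s <- ref
    substr(s, 25, 25) <- base
    s
  }
  reads <- tibble::tibble(seq = c(mk("A"), mk("C"), mk("G")), start = 1L)
  expect_error(phase_segment_reads(reads, ref), "ambiguous")
})

test_that("phasing tolerates realistic read error rates", {
  ref <- rand_dna(250, 74)
  alt <- mutate_at(ref, c(120, 160))
  reads <- simulate_segment_reads(c(h1 = ref, h2 = alt), read_length = 100,
                                  depth = 30, error_rate = 0.005, seed = 4)
  ph <- phase_segment_reads(reads, ref)
  expect_setequal(c(ph$hap1, ph$hap2), c(ref, alt))
})

# matching and naming --------------------------------------------------------

test_that("haplotypes match the closest allele with mutation records", {
  db <- shared_test_db()
  ref <- db$alleles$nt_seq[db$alleles$full_name == "IGHV1-18*01"]
  m <- match_allele(ref, db, "IGHV1-18^")
  expect_equal(m$allele, "IGHV1-18*01")
  expect_equal(nrow(m$mutations), 0L)
  expect_false(m$truncated)

  hap <- mutate_at(ref, 45)
  m2 <- match_allele(hap, db, "IGHV1-18^")
  expect_equal(m2$allele, "IGHV1-18*01")
  expect_equal(nrow(m2$mutations), 1L)
  expect_equal(m2$mutations$position, 44L)  # 0-based
  expect_equal(toupper(m2$mutations$ref_base), substr(ref, 45, 45))
  expect_error(match_allele("", db, "IGHV1-18^"), "empty")
  expect_error(match_allele(ref, db, "NOPE^"), "group")
})

test_that("equidistant matches break ties lexicographically and record them", {
  base01 <- rand_dna(90, 75)
  base02 <- mutate_at(base01, c(10, 20))
  db <- make_db(c("SEGX*01", "SEGX*02"), c(base01, base02), grouped = TRUE)
  hap <- mutate_at(base01, 10)  # 1 mismatch to each allele
  m <- match_allele(hap, db, "SEGX^")
  expect_equal(m$allele, "SEGX*01")
  expect_true(m$tie)
})

test_that("novel-allele names reproduce the published conventions", {
  db <- shared_test_db()
  # a -> g at 0-based 168 inside an AAC codon: N -> D
  ref <- db$alleles$nt_seq[db$alleles$full_name == "IGHV1-18*01"]
  hap <- ref
  substr(hap, 169, 169) <- "G"
  m <- match_allele(hap, db, "IGHV1-18^")
  expect_equal(m$mutations$ref_aa, "N")
  expect_equal(m$mutations$alt_aa, "D")
  expect_equal(name_novel_allele(m$allele, m$mutations),
               "IGHV1-18*01_ag168ND")

  # g -> t at 0-based 234 inside a GAA codon: E -> stop, "(P)" suffix
  ref7 <- db$alleles$nt_seq[db$alleles$full_name == "IGHV3-7*01"]
  hap7 <- ref7
  substr(hap7, 235, 235) <- "T"
  m7 <- match_allele(hap7, db, "IGHV3-7^")
  expect_equal(name_novel_allele(m7$allele, m7$mutations),
               "IGHV3-7*01_gt234E_(P)")

  # no mutations: the database name; truncation appends "(T)"
  none <- m$mutations[0, ]
  expect_equal(name_novel_allele("TRBV12-5*01", none), "TRBV12-5*01")
  expect_equal(name_novel_allele("TRBV12-5*01", none, truncated = TRUE),
               "TRBV12-5*01(T)")
  unsorted <- m7$mutations[c(1, 1), ]
  unsorted$position <- c(5L, 2L)
  expect_error(name_novel_allele("X*01", unsorted), "sorted")
})

test_that("allele names round-trip through parse and re-application", {
  db <- shared_test_db()
  ref <- db$alleles$nt_seq[db$alleles$full_name == "IGHV1-18*01"]
  set.seed(81)
  for (i in 1:250) {
    k <- sample(1:4, 1)
    pos <- sort(sample(0:(nchar(ref) - 1L), k))
    alt <- vapply(pos, function(p) {
      sample(setdiff(c("A", "C", "G", "T"),
                     substr(ref, p + 1, p + 1)), 1)
    }, character(1))
    hap <- ref
    for (j in seq_len(k)) substr(hap, pos[j] + 1, pos[j] + 1) <- alt[j]
    m <- match_allele(hap, db, "IGHV1-18^")
    nm <- name_novel_allele(m$allele, m$mutations)
    parsed <- parse_allele_name(nm)
    expect_equal(parsed$base, m$allele)
    base_seq <- db$alleles$nt_seq[db$alleles$full_name == parsed$base]
    expect_equal(apply_mutations(base_seq, parsed$mutations), hap)
  }
})

test_that("closest-match agrees with exhaustive minimum-Hamming search", {
  set.seed(82)
  for (trial in 1:30) {
    n_all <- sample(3:8, 1)
    len <- sample(30:60, 1)
    base <- rand_dna(len, 8200 + trial)
    seqs <- vapply(seq_len(n_all), function(i) {
      mutate_at(base, sample(len, sample(0:5, 1)))
    }, character(1))
    db <- make_db(sprintf("SEGT*%02d", seq_len(n_all)), seqs, grouped = TRUE)
    hap <- mutate_at(base, sample(len, sample(0:6, 1)))
    m <- match_allele(hap, db, "SEGT^")
    hd <- vapply(seqs, function(s) {
      sum(strsplit(s, "")[[1]] != strsplit(hap, "")[[1]])
    }, numeric(1))
    expect_equal(nrow(m$mutations), min(hd))
    # lexicographic tie-break among equidistant alleles
    best <- sprintf("SEGT*%02d", which(hd == min(hd)))
    expect_equal(m$allele, sort(best)[1])
  }
})

# cohort-level calling -------------------------------------------------------

make_phased_cohort <- function(assignments, db, group = "IGHV1-18^") {
  # assignments: list of c(hap1_label, hap2_label) per individual;
  # labels are database names or "novel" (ag168ND planted mutation)
  ref <- db$alleles$nt_seq[db$alleles$full_name == "IGHV1-18*01"]
  novel <- ref
  substr(novel, 169, 169) <- "G"
  seq_of <- function(lab) {
    if (lab == "novel") return(novel)
    db$alleles$nt_seq[db$alleles$full_name == lab]
  }
  tibble::tibble(
    individual_id = paste0("i", seq_along(assignments)),
    group_id = group,
    hap1_seq = vapply(assignments, function(a) seq_of(a[1]), character(1)),
    hap2_seq = vapply(assignments, function(a) seq_of(a[2]), character(1))
  )
}

test_that("alleles below the two-individual threshold are dropped", {
  db <- shared_test_db()
  phased <- make_phased_cohort(list(
    c("IGHV1-18*01", "novel"),
    c("IGHV1-18*01", "IGHV1-18*02"),
    c("IGHV1-18*01", "IGHV1-18*01")
  ), db)
  cs <- call_alleles_cohort(phased, db)
  expect_false("IGHV1-18*01_ag168ND" %in% cs$table$allele_name)
  # both the singleton novel and the singleton *02 are uncalled
  expect_false("IGHV1-18*02" %in% cs$table$allele_name)
  expect_equal(sum(cs$calls$allele_name == "uncalled"), 2L)

  # the same novel allele in two individuals is kept with 2 haplotypes
  phased2 <- make_phased_cohort(list(
    c("IGHV1-18*01", "novel"),
    c("novel", "IGHV1-18*02"),
    c("IGHV1-18*01", "IGHV1-18*01")
  ), db)
  cs2 <- call_alleles_cohort(phased2, db)
  row <- cs2$table[cs2$table$allele_name == "IGHV1-18*01_ag168ND", ]
  expect_equal(row$n_haplotypes, 2L)
  expect_equal(row$n_individuals, 2L)
  expect_true(row$novel)
  # frequencies sum to one over called alleles within the group
  expect_equal(sum(cs2$table$frequency), 1)
})

test_that("homozygotes count two haplotypes but one individual", {
  db <- shared_test_db()
  phased <- make_phased_cohort(list(
    c("novel", "novel"),
    c("IGHV1-18*01", "IGHV1-18*01")
  ), db)
  cs <- call_alleles_cohort(phased, db)
  # each allele seen in only one individual -> nothing called
  expect_equal(nrow(cs$table), 0L)
  cs1 <- call_alleles_cohort(phased, db, min_individuals = 1L)
  expect_equal(sort(cs1$table$n_haplotypes), c(2L, 2L))
})

test_that("raising the calling threshold never adds alleles", {
  db <- shared_test_db()
  set.seed(83)
  labs <- c("IGHV1-18*01", "IGHV1-18*02", "novel")
  assignments <- lapply(1:25, function(i) sample(labs, 2, replace = TRUE,
                                                 prob = c(0.6, 0.3, 0.1)))
  phased <- make_phased_cohort(assignments, db)
  called_at <- function(k) {
    call_alleles_cohort(phased, db, min_individuals = k)$table$allele_name
  }
  prev <- called_at(1)
  for (k in 2:6) {
    cur <- called_at(k)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("SNPs require two states each in two or more individuals", {
  db <- shared_test_db()
  # monomorphic cohort
  mono <- make_phased_cohort(rep(list(c("IGHV1-18*01", "IGHV1-18*01")), 4), db)
  expect_equal(nrow(identify_snps(call_alleles_cohort(mono, db))), 0L)

  # *01 vs *02 differ at 0-based 150 and 210: 5 vs 3 individuals
  poly <- make_phased_cohort(c(
    rep(list(c("IGHV1-18*01", "IGHV1-18*01")), 5),
    rep(list(c("IGHV1-18*02", "IGHV1-18*02")), 3)
  ), db)
  snps <- identify_snps(call_alleles_cohort(poly, db))
  expect_setequal(unique(snps$position), c(150L, 210L))
  expect_equal(nrow(snps), 4L)  # two states at each of two positions
  expect_setequal(snps$n_individuals, c(5L, 3L))

  # a state in a single individual does not create a SNP
  single <- make_phased_cohort(c(
    rep(list(c("IGHV1-18*01", "IGHV1-18*01")), 5),
    list(c("novel", "IGHV1-18*01"))
  ), db)
  expect_equal(nrow(identify_snps(call_alleles_cohort(single, db,
                                                      min_individuals = 1L))),
               0L)
})

test_that("planted cohort frequencies are recovered within sampling error", {
  db <- shared_test_db()
  set.seed(84)
  p <- c(0.55, 0.30, 0.15)
  labs <- c("IGHV1-18*01", "IGHV1-18*02", "novel")
  n <- 400L
  assignments <- lapply(seq_len(n), function(i) {
    sample(labs, 2, replace = TRUE, prob = p)
  })
  phased <- make_phased_cohort(assignments, db)
  cs <- call_alleles_cohort(phased, db)
  freq <- stats::setNames(cs$table$frequency, cs$table$allele_name)
  for (k in 1:3) {
    nm <- c("IGHV1-18*01", "IGHV1-18*02", "IGHV1-18*01_ag168ND")[k]
    expect_lt(abs(freq[[nm]] - p[k]), 3 * sqrt(p[k] * (1 - p[k]) / (2 * n)))
  }
})
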