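# Synthetic SGDP-like cohorts with known ground truth.
#
# The generator fixes the study conditions: 286 individuals across the seven
# SGDP geographic regions (44 Africans, 73 West Eurasians, 27 Central
# Asians-Siberians, 45 East Asians, 49 South Asians, 22 Oceanians, 26 Native
# Americans), of which 109 come from blood or saliva DNA (14/31/23/2/27/4/8
# per region) and are therefore usable for IGHV; median-scale genome
# coverage 42x from 100-bp reads assembled with k = 21.

# region order is fixed so that draws are reproducible
SGDP_REGIONS <- c("Africa", "WestEurasia", "CentralAsiaSiberia", "EastAsia",
                  "SouthAsia", "Oceania", "America")
SGDP_N_PER_REGION <- stats::setNames(
  c(44L, 73L, 27L, 45L, 49L, 22L, 26L), SGDP_REGIONS)
SGDP_BLOOD_SALIVA_PER_REGION <- stats::setNames(
  c(14L, 31L, 23L, 2L, 27L, 4L, 8L), SGDP_REGIONS)

# regional frequency matrix: global vector with per-region overrides
make_freq_matrix <- function(global, regions = SGDP_REGIONS,
                             overrides = list()) {
  m <- matrix(rep(global, each = length(regions)),
              nrow = length(regions),
              dimnames = list(regions, names(global)))
  for (r in names(overrides)) m[r, ] <- overrides[[r]]
  m
}

default_polymorphisms <- function(locus) {
  if (locus == "IGHV") {
    list(
      cnv_polymorphism("IGHV1-8_block",
                       c("IGHV1-8^", "IGHV3-9^", "IGHV5-10-1^", "IGHV3-64^"),
                       list(insA = c(1L, 1L, 0L, 1L), insB = c(0L, 0L, 1L, 1L))),
      cnv_polymorphism("IGHV4-38-2_block",
                       c("IGHV4-38-2^", "IGHV3-43^"),
                       list(ins = c(1L, 1L), del = c(0L, 1L))),
      cnv_polymorphism("IGHV1-69_block",
                       c("IGHV1-69^", "IGHV1-69-2^", "IGHV2-70^"),
                       list(single = c(1L, 0L, 1L), dup_ins = c(2L, 1L, 2L))),
      cnv_polymorphism("IGHV3-30_block", "IGHV3-30^",
                       stats::setNames(as.list(1:7), as.character(1:7))),
      cnv_polymorphism("IGHV3-23_block", "IGHV3-23^",
                       stats::setNames(as.list(1:4), as.character(1:4)))
    )
  } else {
    list(
      cnv_polymorphism("TRBV4-2_block",
                       c("TRBV4-2^", "TRBV6-2^"),
                       list(ins = c(1L, 1L), del = c(0L, 0L))),
      cnv_polymorphism("TRBV5-8_block",
                       c("TRBV5-8^", "TRBV6-9^", "TRBV7-8^"),
                       list(present = c(1L, 1L, 1L), del = c(0L, 0L, 0L)))
    )
  }
}

default_variant_freqs <- function(locus) {
  if (locus == "IGHV") {
    list(
      # mild regional variation around a balanced global split
      `IGHV1-8_block` = make_freq_matrix(
        c(insA = 0.55, insB = 0.45),
        overrides = list(Africa = c(0.45, 0.55), EastAsia = c(0.65, 0.35))),
      `IGHV4-38-2_block` = make_freq_matrix(
        c(ins = 0.5, del = 0.5),
        overrides = list(America = c(0.62, 0.38))),
      # insertion variant: minor globally (28%) but major in Africa
      `IGHV1-69_block` = make_freq_matrix(
        c(single = 0.72, dup_ins = 0.28),
        overrides = list(Africa = c(0.40, 0.60))),
      `IGHV3-30_block` = make_freq_matrix(
        stats::setNames(c(0.04, 0.30, 0.28, 0.16, 0.12, 0.06, 0.04),
                        as.character(1:7))),
      `IGHV3-23_block` = make_freq_matrix(
        stats::setNames(c(0.10, 0.62, 0.18, 0.10), as.character(1:4)))
    )
  } else {
    list(
      `TRBV4-2_block` = make_freq_matrix(
        c(ins = 0.6, del = 0.4),
        overrides = list(Oceania = c(0.5, 0.5))),
      # three-gene deletion: rare globally, major in the Americas
      `TRBV5-8_block` = make_freq_matrix(
        c(present = 0.95, del = 0.05),
        overrides = list(America = c(0.45, 0.55)))
    )
  }
}

default_novel_alleles <- function(locus) {
  if (locus == "IGHV") {
    tibble::tibble(
      group_id = c("IGHV1-18^", "IGHV3-7^"),
      base_allele = c("IGHV1-18*01", "IGHV3-7*01"),
      position = c(168L, 234L),
      alt_base = c("g", "t")
    )
  } else {
    tibble::tibble(
      group_id = c("TRBV12-5^", "TRBV10-1^"),
      base_allele = c("TRBV12-5*01", "TRBV10-1*02"),
      position = c(27L, 234L),
      alt_base = c("g", "t")
    )
  }
}

# per-group allele frequency matrices (regions x alleles); one group gets an
# Africa-private *02, groups with planted novels allocate 10% to the novel
default_allele_freqs <- function(two_copy_groups, db, novel_registry,
                                 regions = SGDP_REGIONS) {
  private_group <- grep("(IGHV4-34|TRBV9)\\^", two_copy_groups, value = TRUE)
  has_africa <- "Africa" %in% regions
  ovr <- function(x) if (has_africa) list(Africa = x) else list()
  out <- list()
  for (g in two_copy_groups) {
    alleles <- sort(group_alleles(db, g)$full_name)
    nov <- novel_registry$label[novel_registry$group_id == g]
    pad <- rep(0, length(alleles) - 2L)
    if (g %in% private_group && has_africa) {
      freq <- stats::setNames(c(1, rep(0, length(alleles) - 1L)), alleles)
      out[[g]] <- make_freq_matrix(freq, regions,
                                   overrides = ovr(c(0.7, 0.3, pad)))
    } else if (length(nov) > 0L) {
      freq <- stats::setNames(c(0.65, 0.25, 0.10), c(alleles[1:2], nov[1]))
      out[[g]] <- make_freq_matrix(freq, regions,
                                   overrides = ovr(c(0.55, 0.30, 0.15)))
    } else {
      freq <- stats::setNames(c(0.7, 0.3, pad), alleles)
      out[[g]] <- make_freq_matrix(freq, regions,
                                   overrides = ovr(c(0.55, 0.45, pad)))
    }
  }
  out
}

#' Configure a synthetic SGDP-like cohort simulation
#'
#' Assembles and validates the full ground-truth configuration: regional
#' sample sizes and DNA sources, CNV polymorphisms with per-region haploid
#' variant frequencies, two-copy groups with per-region allele frequencies
#' (including planted novel and region-private alleles), and coverage noise.
#' Defaults reproduce the study conditions (see the package vignette);
#' any component can be overridden.
#'
#' @param locus `"IGHV"` or `"TRBV"`.
#' @param db Germline database; default [synthetic_allele_db()] for the
#'   locus, grouped at 95% identity.
#' @param n_per_region,blood_saliva_per_region Named integer vectors over
#'   regions.
#' @param polymorphisms List of [cnv_polymorphism()] objects.
#' @param variant_freqs Named list (per polymorphism) of regions x variants
#'   frequency matrices (rows sum to 1).
#' @param novel_alleles Planted-novel table (`group_id`, `base_allele`,
#'   `position`, `alt_base`).
#' @param allele_freqs Named list (per two-copy group) of regions x alleles
#'   frequency matrices; allele columns are database full names or planted
#'   novel labels.
#' @param two_copy_groups Character vector of allele-bearing two-copy group
#'   ids (default: the database's functional groups other than the CNV
#'   polymorphism groups).
#' @param n_groups_total Total number of operational groups to emulate;
#'   groups beyond the CNV and two-copy sets are two-copy filler with
#'   coverage but no allele model (default 50).
#' @param genome_coverage_mean,genome_coverage_sd Genome-wide coverage
#'   distribution across individuals (reads per base; default 42 +/- 4).
#' @param coverage_noise_cv Coefficient of variation of multiplicative
#'   per-group coverage noise (default 0.05).
#' @param read_length,kmer_size Sequencing read and assembly k-mer lengths
#'   (default 100 bp / 21 bp).
#' @param seed Root seed.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(locus = c("IGHV", "TRBV"),
                              db = NULL,
                              n_per_region = SGDP_N_PER_REGION,
                              blood_saliva_per_region = SGDP_BLOOD_SALIVA_PER_REGION,
                              polymorphisms = NULL,
                              variant_freqs = NULL,
                              novel_alleles = NULL,
                              allele_freqs = NULL,
                              two_copy_groups = NULL,
                              n_groups_total = 50L,
                              genome_coverage_mean = 42,
                              genome_coverage_sd = 4,
                              coverage_noise_cv = 0.05,
                              read_length = 100L,
                              kmer_size = 21L,
                              seed = 1L) {
  locus <- match.arg(locus)
  if (is.null(db)) {
    db <- synthetic_allele_db(locus, seed = derive_seed(seed, 77L))
    db <- group_operational_segments(db, 0.95)
  }
  if (is.null(db$groups)) db <- group_operational_segments(db, 0.95)
  polymorphisms <- polymorphisms %||% default_polymorphisms(locus)
  variant_freqs <- variant_freqs %||% default_variant_freqs(locus)
  novel_alleles <- novel_alleles %||% default_novel_alleles(locus)
  cnv_groups <- unique(unlist(lapply(polymorphisms, `[[`, "group_ids")))
  if (is.null(two_copy_groups)) {
    two_copy_groups <- setdiff(
      db$groups$group_id[db$groups$functional], cnv_groups)
  }
  registry <- novel_allele_registry(
    novel_alleles[novel_alleles$group_id %in% two_copy_groups, , drop = FALSE],
    db)
  allele_freqs <- allele_freqs %||%
    default_allele_freqs(two_copy_groups, db, registry,
                         regions = names(n_per_region))
  n_filler <- max(0L, n_groups_total - length(cnv_groups) -
                    length(two_copy_groups))
  filler_groups <- if (n_filler > 0L) {
    sprintf("%sfill%02d^", locus, seq_len(n_filler))
  } else character(0)

  cfg <- structure(list(
    locus = locus, db = db,
    regions = names(n_per_region),
    n_per_region = n_per_region,
    blood_saliva_per_region = blood_saliva_per_region,
    polymorphisms = polymorphisms,
    variant_freqs = variant_freqs,
    novel_alleles = novel_alleles,
    novel_registry = registry,
    allele_freqs = allele_freqs,
    two_copy_groups = two_copy_groups,
    filler_groups = filler_groups,
    genome_coverage_mean = genome_coverage_mean,
    genome_coverage_sd = genome_coverage_sd,
    coverage_noise_cv = coverage_noise_cv,
    read_length = as.integer(read_length),
    kmer_size = as.integer(kmer_size),
    seed = as.integer(seed)
  ), class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (any(cfg$n_per_region < 0) || any(cfg$blood_saliva_per_region < 0)) {
    stop("regional counts must be non-negative")
  }
  if (any(cfg$blood_saliva_per_region > cfg$n_per_region)) {
    stop("blood/saliva counts cannot exceed regional sample sizes")
  }
  if (cfg$read_length <= cfg$kmer_size || cfg$kmer_size < 1L) {
    stop("need read_length > kmer_size >= 1")
  }
  if (cfg$coverage_noise_cv < 0) stop("coverage_noise_cv must be >= 0")
  poly_ids <- vapply(cfg$polymorphisms, `[[`, character(1), "polymorphism_id")
  for (p in cfg$polymorphisms) {
    fm <- cfg$variant_freqs[[p$polymorphism_id]]
    if (is.null(fm)) stop("missing variant frequencies for ", p$polymorphism_id)
    if (!setequal(colnames(fm), names(p$haploid_variants))) {
      stop("variant frequency columns disagree with variants of ",
           p$polymorphism_id)
    }
    if (!all(cfg$regions %in% rownames(fm))) {
      stop("variant frequencies for ", p$polymorphism_id,
           " do not cover all regions")
    }
    for (r in rownames(fm)) assert_frequency_vector(fm[r, ], p$polymorphism_id)
  }
  for (g in names(cfg$allele_freqs)) {
    fm <- cfg$allele_freqs[[g]]
    if (!all(cfg$regions %in% rownames(fm))) {
      stop("allele frequencies for ", g, " do not cover all regions")
    }
    for (r in rownames(fm)) assert_frequency_vector(fm[r, ], g)
  }
  if (anyDuplicated(poly_ids)) stop("duplicate polymorphism ids")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config> ", x$locus, ": ", sum(x$n_per_region),
      " individuals in ", length(x$regions), " regions (",
      sum(x$blood_saliva_per_region), " blood/saliva); ",
      length(x$polymorphisms), " CNV polymorphisms, ",
      length(x$two_copy_groups), " two-copy allele groups, ",
      length(x$filler_groups), " filler groups; cv = ",
      x$coverage_noise_cv, "\n", sep = "")
  invisible(x)
}

#' Simulate a cohort with known ground truth
#'
#' Draws, per individual: a geographic region and DNA source (regional
#' blood/saliva counts are fixed, assignment within region is random); two
#' haploid CNV variants per polymorphism, independently from the regional
#' variant frequencies (diploid copy number is their sum); two alleles per
#' two-copy group from the regional allele frequencies; a genome-wide
#' coverage; and per-group observed coverage
#' `(CN / 2) * genome_coverage * (1 + Normal(0, cv))`, truncated at zero.
#'
#' @param config A [simulation_config()].
#' @param seed Seed (default: the config's).
#' @return Object of class `synthetic_cohort`: list with `metadata`
#'   (`individual_id`, `region`, `dna_source`), `variant_truth`
#'   (per individual x polymorphism haploid variant pair), `cn_truth` (long:
#'   `individual_id`, `group_id`, `true_cn`), `allele_truth` (per
#'   individual x two-copy group allele pair), `coverage` (long:
#'   `individual_id`, `group_id`, `coverage`, `genome_coverage`), plus the
#'   `config` echo and `seed`.
#' @export
simulate_population <- function(config, seed = config$seed) {
  validate_simulation_config(config)
  set.seed(seed)
  regions <- config$regions

  meta <- dplyr::bind_rows(lapply(regions, function(r) {
    n <- config$n_per_region[[r]]
    if (n == 0L) return(NULL)
    nb <- config$blood_saliva_per_region[[r]]
    src <- rep("cell_line", n)
    if (nb > 0L) {
      idx <- sample.int(n, nb)
      src[idx] <- sample(c("blood", "saliva"), nb, replace = TRUE)
    }
    tibble::tibble(individual_id = sprintf("%s_%03d", r, seq_len(n)),
                   region = r, dna_source = src)
  }))
  n_ind <- nrow(meta)

  all_groups <- c(unique(unlist(lapply(config$polymorphisms, `[[`, "group_ids"))),
                  config$two_copy_groups, config$filler_groups)
  cn <- matrix(2L, n_ind, length(all_groups),
               dimnames = list(meta$individual_id, all_groups))

  variant_rows <- list()
  for (p in config$polymorphisms) {
    fm <- config$variant_freqs[[p$polymorphism_id]]
    vs <- names(p$haploid_variants)
    hap1 <- hap2 <- character(n_ind)
    for (r in regions) {
      idx <- which(meta$region == r)
      if (length(idx) == 0L) next
      draws <- sample(vs, 2L * length(idx), replace = TRUE,
                      prob = fm[r, vs])
      hap1[idx] <- draws[seq_along(idx)]
      hap2[idx] <- draws[length(idx) + seq_along(idx)]
    }
    vmat <- do.call(rbind, p$haploid_variants)
    dip <- vmat[hap1, , drop = FALSE] + vmat[hap2, , drop = FALSE]
    cn[, p$group_ids] <- dip
    variant_rows[[p$polymorphism_id]] <- tibble::tibble(
      individual_id = meta$individual_id,
      polymorphism_id = p$polymorphism_id,
      hap1_variant = hap1, hap2_variant = hap2)
  }

  allele_rows <- list()
  for (g in names(config$allele_freqs)) {
    fm <- config$allele_freqs[[g]]
    alleles <- colnames(fm)
    hap1 <- hap2 <- character(n_ind)
    for (r in regions) {
      idx <- which(meta$region == r)
      if (length(idx) == 0L) next
      draws <- sample(alleles, 2L * length(idx), replace = TRUE,
                      prob = fm[r, ])
      hap1[idx] <- draws[seq_along(idx)]
      hap2[idx] <- draws[length(idx) + seq_along(idx)]
    }
    allele_rows[[g]] <- tibble::tibble(
      individual_id = meta$individual_id, group_id = g,
      hap1_allele = hap1, hap2_allele = hap2)
  }

  genome_cov <- pmax(stats::rnorm(n_ind, config$genome_coverage_mean,
                                  config$genome_coverage_sd), 1)
  noise <- matrix(stats::rnorm(n_ind * length(all_groups), 0,
                               config$coverage_noise_cv),
                  n_ind, length(all_groups))
  obs <- pmax((cn / 2) * genome_cov * (1 + noise), 0)

  coverage <- tibble::tibble(
    individual_id = rep(meta$individual_id, times = length(all_groups)),
    group_id = rep(all_groups, each = n_ind),
    coverage = as.vector(obs),
    genome_coverage = rep(genome_cov, times = length(all_groups))
  )
  cn_truth <- tibble::tibble(
    individual_id = rep(meta$individual_id, times = length(all_groups)),
    group_id = rep(all_groups, each = n_ind),
    true_cn = as.vector(cn)
  )
  structure(list(metadata = meta,
                 variant_truth = dplyr::bind_rows(variant_rows),
                 cn_truth = cn_truth,
                 allele_truth = dplyr::bind_rows(allele_rows),
                 coverage = coverage,
                 config = config,
                 seed = as.integer(seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$metadata), " individuals, ",
      length(unique(x$coverage$group_id)), " groups, locus ",
      x$config$locus, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' True copy numbers as a matrix
#'
#' @param cohort A `synthetic_cohort`.
#' @return Integer matrix individuals x groups.
#' @export
true_cn_matrix <- function(cohort) {
  ct <- cohort$cn_truth
  inds <- unique(ct$individual_id)
  grps <- unique(ct$group_id)
  m <- matrix(NA_integer_, length(inds), length(grps),
              dimnames = list(inds, grps))
  m[cbind(match(ct$individual_id, inds), match(ct$group_id, grps))] <-
    as.integer(ct$true_cn)
  m
}

#' Look up the nucleotide sequence behind an allele label
#'
#' Database full names resolve against the database; planted novel labels
#' against the cohort's novel registry.
#'
#' @param label Allele label (database full name or novel label).
#' @param db The `allele_database`.
#' @param registry Novel registry (e.g. `config$novel_registry`).
#' @return Nucleotide string.
#' @export
resolve_allele_seq <- function(label, db, registry) {
  i <- match(label, db$alleles$full_name)
  if (!is.na(i)) return(db$alleles$nt_seq[i])
  j <- match(label, registry$label)
  if (!is.na(j)) return(registry$seq[j])
  stop("unknown allele label: ", label)
}

#' Simulate shotgun reads from haploid segment copies
#'
#' Reads are drawn uniformly from each haploid copy: per copy the read count
#' is Poisson with mean `depth * len / read_length` (i.e. `depth` is the
#' expected per-base coverage contributed by one copy), start positions are
#' uniform, and base errors are i.i.d. substitutions at `error_rate`. A
#' segment with no copies yields zero reads. Reads longer than the segment
#' are truncated to its full length and flagged.
#'
#' @param hap_seqs Character vector of haploid copy sequences (possibly
#'   empty for a deleted segment); names identify the copies.
#' @param read_length Read length in bp.
#' @param depth Expected per-base coverage per copy (> 0).
#' @param error_rate Per-base substitution error probability.
#' @param seed Optional seed.
#' @return Tibble with `read_id`, `hap` (copy of origin), `start` (1-based)
#'   and `seq`; attribute `truncated` marks the degenerate short-segment
#'   case.
#' @export
simulate_segment_reads <- function(hap_seqs, read_length = 100L, depth = 30,
                                   error_rate = 0, seed = NULL) {
  if (depth <= 0) stop("depth must be > 0")
  if (!is.null(seed)) set.seed(seed)
  if (length(hap_seqs) == 0L) {
    out <- tibble::tibble(read_id = character(0), hap = character(0),
                          start = integer(0), seq = character(0))
    attr(out, "truncated") <- FALSE
    return(out)
  }
  if (is.null(names(hap_seqs))) {
    names(hap_seqs) <- paste0("hap", seq_along(hap_seqs))
  }
  truncated <- FALSE
  rows <- list()
  for (h in seq_along(hap_seqs)) {
    s <- hap_seqs[[h]]
    len <- nchar(s)
    rl <- read_length
    if (rl > len) {
      rl <- len
      truncated <- TRUE
    }
    n_reads <- stats::rpois(1, depth * len / rl)
    if (n_reads == 0L) next
    starts <- sample.int(len - rl + 1L, n_reads, replace = TRUE)
    seqs <- substring(s, starts, starts + rl - 1L)
    if (error_rate > 0) {
      chars <- strsplit(seqs, "", fixed = TRUE)
      chars <- lapply(chars, function(x) {
        hit <- which(stats::runif(length(x)) < error_rate)
        for (i in hit) x[i] <- sample(setdiff(DNA_BASES, x[i]), 1)
        x
      })
      seqs <- vapply(chars, paste, character(1), collapse = "")
    }
    rows[[h]] <- tibble::tibble(
      read_id = sprintf("%s_r%04d", names(hap_seqs)[h], seq_len(n_reads)),
      hap = names(hap_seqs)[h],
      start = as.integer(starts),
      seq = seqs)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(read_id = character(0), hap = character(0),
                          start = integer(0), seq = character(0))
  }
  attr(out, "truncated") <- truncated
  out
}

#' Restrict a cohort to the DNA sources usable for a locus
#'
#' IGHV analyses must exclude cell-line DNA (immortalised B cells carry
#' VDJ-recombined, truncated IGHV loci), keeping blood and saliva samples
#' only; TRBV analyses use all individuals.
#'
#' @param metadata Tibble with `individual_id`, `region`, `dna_source`
#'   (values in `blood`, `saliva`, `cell_line`).
#' @param locus `"IGHV"` or `"TRBV"`.
#' @return The filtered metadata tibble.
#' @export
select_cohort <- function(metadata, locus = c("IGHV", "TRBV")) {
  locus <- match.arg(locus)
  known <- c("blood", "saliva", "cell_line")
  bad <- setdiff(unique(metadata$dna_source), known)
  if (length(bad) > 0L) {
    stop("unknown dna_source value(s): ", paste(bad, collapse = ", "))
  }
  if (locus == "IGHV") {
    metadata[metadata$dna_source %in% c("blood", "saliva"), , drop = FALSE]
  } else {
    metadata
  }
}

#' Write cohort tables to TSV files
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_cohort_tsv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(metadata = file.path(dir, "metadata.tsv"),
             coverage = file.path(dir, "coverage.tsv"),
             cn_truth = file.path(dir, "cn_truth.tsv"),
             allele_truth = file.path(dir, "allele_truth.tsv"))
  utils::write.table(cohort$metadata, paths["metadata"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$coverage, paths["coverage"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$cn_truth, paths["cn_truth"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$allele_truth, paths["allele_truth"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}
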