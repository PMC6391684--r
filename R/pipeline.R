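#' Configure an end-to-end pipeline run
#'
#' Bundles the inputs and thresholds for [run_pipeline()]. By default every
#' input is synthesised (database and cohort from [simulation_config()]);
#' file-based inputs can be supplied instead: an allele FASTA, a metadata
#' TSV and a coverage TSV with the column layouts written by
#' [write_cohort_tsv()], and a polymorphism JSON as written by
#' [write_polymorphisms_json()].
#'
#' @param locus `"IGHV"` or `"TRBV"`.
#' @param seed Root seed; all stage seeds derive from it.
#' @param sim_config Optional [simulation_config()] (default: locus default
#'   with this seed).
#' @param allele_fasta,metadata_tsv,coverage_tsv,polymorphisms_json Optional
#'   file inputs overriding the synthetic ones.
#' @param grouping_identity Identity threshold for operational grouping.
#' @param min_individuals Allele/SNV calling threshold (default 2).
#' @param alpha Regional chi-squared flagging level (default 0.01).
#' @param phase_depth Per-copy read depth for the phasing stage.
#' @param phase_error_rate Per-base read error rate for the phasing stage.
#' @param cn_blocklist Group ids excluded from CNV calling (e.g. groups with
#'   anomalous coverage profiles).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(locus = c("IGHV", "TRBV"), seed = 1L,
                            sim_config = NULL,
                            allele_fasta = NULL, metadata_tsv = NULL,
                            coverage_tsv = NULL, polymorphisms_json = NULL,
                            grouping_identity = 0.95,
                            min_individuals = 2L, alpha = 0.01,
                            phase_depth = 25, phase_error_rate = 0.002,
                            cn_blocklist = character(0)) {
  locus <- match.arg(locus)
  for (p in c(allele_fasta, metadata_tsv, coverage_tsv, polymorphisms_json)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  structure(list(locus = locus, seed = as.integer(seed),
                 sim_config = sim_config,
                 allele_fasta = allele_fasta, metadata_tsv = metadata_tsv,
                 coverage_tsv = coverage_tsv,
                 polymorphisms_json = polymorphisms_json,
                 grouping_identity = grouping_identity,
                 min_individuals = as.integer(min_individuals),
                 alpha = alpha, phase_depth = phase_depth,
                 phase_error_rate = phase_error_rate,
                 cn_blocklist = cn_blocklist),
            class = "pipeline_config")
}

#' Run the full germline-variation pipeline
#'
#' Executes the stages in order -- cohort selection, copy-number estimation,
#' CNV haplotype calling (with relative abundances, regional heterogeneity
#' tests, pairwise R-squared, haplotype-count estimate and the segment-set
#' difference probability), read simulation + phasing + allele/SNV calling
#' on the two-copy groups, population summary statistics (pairwise bp
#' difference, SNPs per segment, novel fraction, private variants, FST), and
#' metric MDS of allele content -- and returns every stage output in one
#' bundle stamped with the seed and a config hash. Reruns with the same
#' config are identical.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with elements `log`, `db`,
#'   `cohort`, `metadata_used`, `cn`, `cnv`, `alleles`, `stats`, `mds`,
#'   `seed`, `config`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  sim_cfg <- config$sim_config %||%
    simulation_config(config$locus, seed = config$seed)
  db <- if (!is.null(config$allele_fasta)) {
    group_operational_segments(
      load_allele_fasta(config$allele_fasta, config$locus),
      config$grouping_identity)
  } else sim_cfg$db
  note("stage 1 reference: ", nrow(db$alleles), " alleles in ",
       nrow(db$groups), " operational groups")

  cohort <- simulate_population(sim_cfg, seed = derive_seed(config$seed, 1L))
  metadata <- if (!is.null(config$metadata_tsv)) {
    tibble::as_tibble(utils::read.delim(config$metadata_tsv))
  } else cohort$metadata
  meta_used <- select_cohort(metadata, config$locus)
  note("stage 2 cohort: ", nrow(meta_used), " of ", nrow(metadata),
       " individuals usable for ", config$locus)

  coverage <- if (!is.null(config$coverage_tsv)) {
    tibble::as_tibble(utils::read.delim(config$coverage_tsv))
  } else cohort$coverage
  coverage <- coverage[coverage$individual_id %in% meta_used$individual_id, ,
                       drop = FALSE]
  cn <- estimate_copy_number(coverage)
  est <- cn_matrix(cn)
  note("stage 3 copy number: ", nrow(cn), " estimates over ",
       ncol(est), " groups")

  polymorphisms <- if (!is.null(config$polymorphisms_json)) {
    read_polymorphisms_json(config$polymorphisms_json)
  } else sim_cfg$polymorphisms
  polymorphisms <- Filter(function(p) {
    !any(p$group_ids %in% config$cn_blocklist)
  }, polymorphisms)
  callsets <- lapply(polymorphisms, function(p) {
    cluster_copy_numbers(est, p)
  })
  names(callsets) <- vapply(polymorphisms, `[[`, character(1),
                            "polymorphism_id")
  ra <- lapply(callsets, variant_relative_abundance)
  regional <- suppressWarnings(
    lapply(callsets, regional_distribution_test, metadata = meta_used,
           alpha = config$alpha))
  poly_groups <- unique(unlist(lapply(polymorphisms, `[[`, "group_ids")))
  r2 <- pairwise_r_squared(est[, poly_groups, drop = FALSE])
  off_block <- mean_off_block_r2(r2, polymorphisms)
  variant_counts <- vapply(seq_along(callsets), function(i) {
    rab <- ra[[i]]
    if (rab$level[1] == "haploid") {
      sum(rab$count > 0)
    } else {
      min_max_haploid(max(as.integer(rab$variant)))
    }
  }, integer(1))
  hap_count <- haplotype_count_estimate(variant_counts)
  # called integer CN per individual per group (two-copy groups fixed at 2)
  called_cn <- matrix(2L, nrow(est), ncol(est), dimnames = dimnames(est))
  for (cs in callsets) {
    gids <- cs$polymorphism$group_ids
    m <- as.matrix(cs$calls[, paste0("cn_", gids), drop = FALSE])
    called_cn[cs$calls$individual_id, gids] <- m
  }
  setdiff_prob <- segment_set_difference_probability(
    called_cn > 0, metadata = meta_used, stratify_by_region = TRUE)
  note("stage 4 CNV: ", length(callsets), " polymorphisms called; ",
       "mean off-block R^2 = ", signif(off_block, 3),
       "; haplotype product = ", hap_count)

  # stage 5: reads -> phasing -> alleles, on the two-copy allele groups
  two_copy <- intersect(sim_cfg$two_copy_groups, colnames(est))
  truth <- cohort$allele_truth
  truth <- truth[truth$individual_id %in% meta_used$individual_id &
                   truth$group_id %in% two_copy, , drop = FALSE]
  refs <- stats::setNames(
    db$groups$representative_seq[match(two_copy, db$groups$group_id)],
    two_copy)
  phased_rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    labs <- c(truth$hap1_allele[i], truth$hap2_allele[i])
    haps <- vapply(labs, resolve_allele_seq, character(1),
                   db = db, registry = sim_cfg$novel_registry)
    reads <- simulate_segment_reads(
      haps, read_length = sim_cfg$read_length,
      depth = config$phase_depth, error_rate = config$phase_error_rate,
      seed = derive_seed(config$seed, 100L + i))
    ph <- phase_segment_reads(reads, refs[[truth$group_id[i]]])
    phased_rows[[i]] <- tibble::tibble(
      individual_id = truth$individual_id[i],
      group_id = truth$group_id[i],
      hap1_seq = ph$hap1, hap2_seq = ph$hap2)
  }
  phased <- dplyr::bind_rows(phased_rows)
  alleles <- call_alleles_cohort(phased, db,
                                 min_individuals = config$min_individuals,
                                 metadata = meta_used)
  snps <- identify_snps(alleles, min_individuals = config$min_individuals)
  note("stage 5 alleles: ", nrow(alleles$table), " alleles called over ",
       length(two_copy), " two-copy groups; ",
       nrow(unique(snps[, c("group_id", "position")])), " SNPs")

  # stage 6: summary statistics
  called_calls <- alleles$calls[alleles$calls$called, , drop = FALSE]
  seq_tab <- unique(tibble::tibble(group_id = called_calls$group_id,
                                   allele_name = called_calls$allele_name,
                                   seq = called_calls$hap_seq))
  seq_tab <- seq_tab[!duplicated(paste(seq_tab$group_id, seq_tab$allele_name)), ]
  bp_diff <- suppressWarnings(avg_pairwise_bp_difference(seq_tab))
  snps_seg <- snps_per_segment(snps, two_copy)
  novel <- novel_fraction(alleles)
  priv <- dplyr::bind_rows(
    private_variants(allele_carriers(alleles), meta_used),
    private_variants(snv_carriers(snps, alleles), meta_used))
  fst <- fst_weir_cockerham(allele_counts_by_region(alleles, meta_used))
  allele_counts <- as.integer(table(alleles$table$group_id)[two_copy])
  allele_counts[is.na(allele_counts)] <- 0L
  note("stage 6 statistics: avg bp diff = ", signif(bp_diff, 3),
       "%; SNPs/segment = ", signif(snps_seg, 3), "; novel fraction = ",
       novel$novel, "/", novel$total, "; overall FST = ",
       signif(fst$overall, 3))

  # stage 7: population structure
  acm <- allele_copy_matrix(alleles)
  emb <- mds_embed(acm, dims = 2L, seed = derive_seed(config$seed, 7L))
  reg <- meta_used$region[match(rownames(emb$coords),
                                meta_used$individual_id)]
  sil <- suppressWarnings(region_separation_score(emb, reg))
  note("stage 7 MDS: stress-1 = ", signif(emb$stress, 3),
       "; regional silhouette = ", signif(sil, 3))

  structure(list(
    log = log, db = db, cohort = cohort, metadata_used = meta_used,
    cn = cn,
    cnv = list(callsets = callsets, relative_abundance = ra,
               regional_tests = regional, r_squared = r2,
               mean_off_block_r2 = off_block,
               variant_counts = variant_counts,
               haplotype_count = hap_count,
               called_cn = called_cn,
               setdiff_probability = setdiff_prob),
    alleles = list(callset = alleles, snps = snps, phased = phased,
                   allele_counts_per_segment = allele_counts),
    stats = list(avg_pairwise_bp_difference = bp_diff,
                 snps_per_segment = snps_seg,
                 novel_fraction = novel,
                 private_variants = priv,
                 fst = fst),
    mds = list(embedding = emb, regions = reg, silhouette = sil),
    seed = config$seed,
    config = config,
    config_hash = rlang::hash(config)
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> seed ", x$seed, ", config ",
      substr(x$config_hash, 1, 8), "\n", sep = "")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Write / read CNV polymorphism definitions as JSON
#'
#' @param polymorphisms List of [cnv_polymorphism()] objects.
#' @param path JSON file path.
#' @return `path` (write) or the polymorphism list (read).
#' @export
write_polymorphisms_json <- function(polymorphisms, path) {
  payload <- lapply(polymorphisms, function(p) {
    list(polymorphism_id = p$polymorphism_id,
         group_ids = p$group_ids,
         haploid_variants = p$haploid_variants)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polymorphisms_json
#' @export
read_polymorphisms_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(payload, function(p) {
    cnv_polymorphism(p$polymorphism_id,
                     unlist(p$group_ids),
                     lapply(p$haploid_variants, as.integer))
  })
}
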