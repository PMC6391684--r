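#' Phase a two-copy segment from indel-free reads
#'
#' A simplified diploid phaser for the synthetic regime in which reads align
#' to the segment reference without indels. A pileup over reference positions
#' is built from the reads' start coordinates; a position is heterozygous
#' when exactly two base states each carry at least `het_frac` of the
#' covering reads (default 20%). Heterozygous sites are phased greedily by
#' read linkage: for each site, reads that also cover an earlier phased site
#' vote on which haplotype carries which state. Sites with no linking reads
#' (or tied votes) are flagged `unlinked` and given a deterministic
#' (alphabetical) phase.
#'
#' @param reads Data frame with columns `seq` (read string) and `start`
#'   (1-based start position on the reference).
#' @param reference Reference nucleotide string for the segment group.
#' @param het_frac Minimum fraction of covering reads for a base state to be
#'   considered (default 0.2).
#' @return An object of class `phased_segment`: list with `hap1`, `hap2`
#'   (nucleotide strings; identical when homozygous), `het_positions`
#'   (1-based), `unlinked` (logical), and `mean_depth`.
#' @export
phase_segment_reads <- function(reads, reference, het_frac = 0.2) {
  if (is.null(reads) || nrow(reads) == 0L) stop("no reads to phase")
  L <- nchar(reference)
  rl <- nchar(reads$seq)
  pos <- unlist(Map(function(s, l) seq.int(s, s + l - 1L), reads$start, rl))
  base <- unlist(strsplit(reads$seq, "", fixed = TRUE))
  read_of <- rep.int(seq_len(nrow(reads)), rl)
  ok <- pos >= 1L & pos <= L
  pos <- pos[ok]; base <- base[ok]; read_of <- read_of[ok]
  bidx <- match(base, DNA_BASES)
  known <- !is.na(bidx)
  cnt <- matrix(
    tabulate((pos[known] - 1L) * 4L + bidx[known], nbins = 4L * L),
    nrow = 4L
  )
  depth <- colSums(cnt)
  if (all(depth == 0)) stop("reads do not cover the reference")

  top <- apply(cnt, 2, which.max)
  consensus <- DNA_BASES[top]
  consensus[depth == 0] <- strsplit(reference, "")[[1]][depth == 0]

  frac <- sweep(cnt, 2, pmax(depth, 1L), "/")
  n_states <- colSums(frac >= het_frac & cnt > 0)
  if (any(n_states > 2L)) {
    stop("ambiguous pileup: >2 base states above threshold at position(s) ",
         paste(utils::head(which(n_states > 2L), 5L), collapse = ", "))
  }
  het <- which(n_states == 2L)

  hap1 <- hap2 <- consensus
  unlinked <- FALSE
  if (length(het) > 0L) {
    # the two states at each het site, alphabetical
    states <- lapply(het, function(p) {
      DNA_BASES[which(frac[, p] >= het_frac & cnt[, p] > 0)]
    })
    # read base at each het site (NA when not covered)
    K <- length(het)
    rb <- matrix(NA_character_, nrow(reads), K)
    at_het <- pos %in% het
    if (any(at_het)) {
      hp <- match(pos[at_het], het)
      rb[cbind(read_of[at_het], hp)] <- base[at_het]
    }
    # assign[k] = TRUE means hap1 carries states[[k]][1]
    assign1 <- rep(TRUE, K)
    if (K > 1L) {
      for (k in 2L:K) {
        votes <- 0L; n_votes <- 0L
        for (j in seq_len(k - 1L)) {
          h1j <- states[[j]][if (assign1[j]) 1L else 2L]
          h2j <- states[[j]][if (assign1[j]) 2L else 1L]
          cov_both <- !is.na(rb[, j]) & !is.na(rb[, k])
          if (!any(cov_both)) next
          bj <- rb[cov_both, j]; bk <- rb[cov_both, k]
          same <- sum((bj == h1j & bk == states[[k]][1]) |
                        (bj == h2j & bk == states[[k]][2]))
          diff <- sum((bj == h1j & bk == states[[k]][2]) |
                        (bj == h2j & bk == states[[k]][1]))
          votes <- votes + same - diff
          n_votes <- n_votes + same + diff
        }
        if (n_votes == 0L || votes == 0L) {
          unlinked <- TRUE
          assign1[k] <- TRUE
        } else {
          assign1[k] <- votes > 0L
        }
      }
    }
    for (k in seq_len(K)) {
      hap1[het[k]] <- states[[k]][if (assign1[k]) 1L else 2L]
      hap2[het[k]] <- states[[k]][if (assign1[k]) 2L else 1L]
    }
  }
  structure(list(hap1 = paste(hap1, collapse = ""),
                 hap2 = paste(hap2, collapse = ""),
                 het_positions = het,
                 unlinked = unlinked,
                 mean_depth = mean(depth)),
            class = "phased_segment")
}

#' @export
print.phased_segment <- function(x, ...) {
  cat("<phased_segment> ", nchar(x$hap1), " bp, ",
      length(x$het_positions), " het site(s)",
      if (x$unlinked) " [unlinked]", ", mean depth ",
      round(x$mean_depth, 1), "\n", sep = "")
  invisible(x)
}

# mutation record(s) for substitutions of ref at 0-based positions pos0.
# The amino-acid pair reflects each substitution applied alone to the
# reference codon, matching the printed nomenclature.
mutation_records <- function(ref_seq, pos0, alt_bases) {
  if (length(pos0) == 0L) {
    return(tibble::tibble(position = integer(0), ref_base = character(0),
                          alt_base = character(0), ref_aa = character(0),
                          alt_aa = character(0)))
  }
  o <- order(pos0)
  pos0 <- pos0[o]; alt_bases <- alt_bases[o]
  cs <- pos0 - pos0 %% 3L
  ref_codon <- substring(ref_seq, cs + 1L, cs + 3L)
  aa_of <- function(codon) {
    if (nchar(codon) < 3L) return("X")
    translate_allele(codon)
  }
  ref_aa <- vapply(ref_codon, aa_of, character(1), USE.NAMES = FALSE)
  alt_codon <- ref_codon
  off <- pos0 - cs + 1L
  for (i in seq_along(alt_codon)) {
    if (nchar(alt_codon[i]) >= off[i]) {
      substr(alt_codon[i], off[i], off[i]) <- toupper(alt_bases[i])
    }
  }
  alt_aa <- vapply(alt_codon, aa_of, character(1), USE.NAMES = FALSE)
  tibble::tibble(
    position = as.integer(pos0),
    ref_base = tolower(substring(ref_seq, pos0 + 1L, pos0 + 1L)),
    alt_base = tolower(alt_bases),
    ref_aa = ref_aa,
    alt_aa = alt_aa
  )
}

#' Match a haplotype sequence to the closest database allele
#'
#' Finds the minimum-substitution database allele of the group over the
#' aligned prefix (substitutions only; this pipeline reports indel-bearing
#' reconstructions as truncated rather than naming them). Ties are broken
#' toward the lexicographically smallest allele name and recorded.
#'
#' @param hap_seq Haplotype nucleotide string.
#' @param db A grouped `allele_database`.
#' @param group_id Operational group to search.
#' @return List with `allele` (closest full name), `mutations` (tibble with
#'   0-based `position`, `ref_base`, `alt_base`, `ref_aa`, `alt_aa`, sorted
#'   by position), `truncated` (haplotype shorter than the reference allele)
#'   and `tie`.
#' @export
match_allele <- function(hap_seq, db, group_id) {
  if (!nzchar(hap_seq)) stop("empty haplotype sequence")
  cands <- group_alleles(db, group_id)
  if (nrow(cands) == 0L) stop("no functional alleles for group: ", group_id)
  hap <- toupper(hap_seq)
  mism <- lapply(cands$nt_seq, prefix_mismatch_positions, a = hap)
  n_mism <- lengths(mism)
  best <- which(n_mism == min(n_mism))
  tie <- length(best) > 1L
  best <- best[order(cands$full_name[best])][1]
  ref <- cands$nt_seq[best]
  pos1 <- mism[[best]]             # 1-based mismatch positions on prefix
  muts <- mutation_records(ref, pos1 - 1L,
                           substring(hap, pos1, pos1))
  list(allele = cands$full_name[best],
       mutations = muts,
       truncated = nchar(hap) < nchar(ref),
       tie = tie)
}

#' Name a (possibly novel) allele by its closest database match
#'
#' Novel alleles are named by the closest matching database allele followed
#' by one suffix per substitution, separated by `"_"`. Each suffix is
#' `{ref base}{alt base}{position}{ref amino acid}{alt amino acid}` with
#' lowercase bases, a 0-based position in the reading frame starting at the
#' first database base, and `"_"` for a stop codon -- e.g.
#' `IGHV1-18*01_ag168ND`. When any substitution creates a stop, `"(P)"` is
#' appended; when the reconstruction was truncated, `"(T)"` is appended.
#'
#' @param base_allele_name Closest database allele name.
#' @param mutations Mutation tibble as produced by [match_allele()], sorted
#'   by ascending position (enforced).
#' @param truncated Whether the haplotype was truncated.
#' @return The allele name string; equal to `base_allele_name` when there are
#'   no mutations and no truncation.
#' @examples
#' m <- tibble::tibble(position = 168L, ref_base = "a", alt_base = "g",
#'                     ref_aa = "N", alt_aa = "D")
#' name_novel_allele("IGHV1-18*01", m)  # "IGHV1-18*01_ag168ND"
#' @export
name_novel_allele <- function(base_allele_name, mutations, truncated = FALSE) {
  if (nrow(mutations) > 0L && is.unsorted(mutations$position, strictly = FALSE)) {
    stop("mutations must be sorted by ascending position")
  }
  name <- base_allele_name
  if (nrow(mutations) > 0L) {
    suffix <- paste0("_", mutations$ref_base, mutations$alt_base,
                     mutations$position, mutations$ref_aa, mutations$alt_aa)
    name <- paste0(name, paste(suffix, collapse = ""))
    if (any(mutations$alt_aa == "_")) name <- paste0(name, "(P)")
  }
  if (truncated) name <- paste0(name, "(T)")
  name
}

#' Parse an allele name back into base allele and mutations
#'
#' Inverse of [name_novel_allele()] (modulo amino-acid annotations, which are
#' recomputed from sequence when applying). Handles the collision between the
#' `"_"` mutation separator and `"_"` as the stop-codon amino acid.
#'
#' @param name Allele name string.
#' @return List with `base` name, `mutations` tibble (`position`, `ref_base`,
#'   `alt_base`, `ref_aa`, `alt_aa`), `premature_stop` and `truncated` flags.
#' @export
parse_allele_name <- function(name) {
  premature_stop <- grepl("(P)", name, fixed = TRUE)
  truncated <- grepl("(T)", name, fixed = TRUE)
  core <- gsub("\\((P|T)\\)", "", name)
  us <- regexpr("_", core, fixed = TRUE)
  if (us < 0L) {
    return(list(base = core,
                mutations = mutation_records("", integer(0), character(0)),
                premature_stop = premature_stop, truncated = truncated))
  }
  base <- substr(core, 1L, us - 1L)
  mut_str <- substr(core, us + 1L, nchar(core))
  m <- gregexpr("[acgt]{2}[0-9]+[A-Z_X][A-Z_X]", mut_str)[[1]]
  toks <- regmatches(mut_str, gregexpr("[acgt]{2}[0-9]+[A-Z_X][A-Z_X]", mut_str))[[1]]
  if (length(toks) == 0L || m[1] < 0L) {
    stop("cannot parse mutation suffixes in allele name: ", name)
  }
  muts <- lapply(toks, function(t) {
    tibble::tibble(
      position = as.integer(sub("^[acgt]{2}([0-9]+).*$", "\\1", t)),
      ref_base = substr(t, 1L, 1L),
      alt_base = substr(t, 2L, 2L),
      ref_aa = substr(t, nchar(t) - 1L, nchar(t) - 1L),
      alt_aa = substr(t, nchar(t), nchar(t))
    )
  })
  list(base = base, mutations = dplyr::bind_rows(muts),
       premature_stop = premature_stop, truncated = truncated)
}

#' Apply substitution mutations to a reference sequence
#'
#' @param ref_seq Reference nucleotide string.
#' @param mutations Mutation tibble with 0-based `position` and `alt_base`.
#' @return Mutated sequence (uppercase alt bases).
#' @export
apply_mutations <- function(ref_seq, mutations) {
  if (nrow(mutations) == 0L) return(ref_seq)
  if (any(mutations$position >= nchar(ref_seq))) {
    stop("mutation position beyond reference length")
  }
  substitute_bases(ref_seq, mutations$position + 1L,
                   toupper(mutations$alt_base))
}

#' Call alleles across a cohort with the two-individual rule
#'
#' Matches and names every phased haplotype, then drops alleles observed in
#' fewer than `min_individuals` distinct individuals (their haplotypes are
#' reassigned to `"uncalled"`). A homozygous observation contributes two
#' haplotype counts but one individual toward the threshold. Truncation does
#' not change an allele's identity; the frequency table records whether any
#' contributing reconstruction was truncated and exposes a `display_name`
#' with the `"(T)"` suffix.
#'
#' @param phased Tibble with columns `individual_id`, `group_id`, `hap1_seq`,
#'   `hap2_seq`, covering only designated two-copy groups.
#' @param db A grouped `allele_database`.
#' @param min_individuals Minimum distinct individuals for a call
#'   (default 2).
#' @param metadata Optional tibble (`individual_id`, `region`) to annotate
#'   regions observed per allele.
#' @return An object of class `allele_callset`: list with `calls` (one row
#'   per haplotype: `individual_id`, `group_id`, `haplotype`, `allele_name`,
#'   `novel`, `truncated`, `called`, `hap_seq`) and `table` (per
#'   group x allele: `n_haplotypes`, `n_individuals`, `frequency`,
#'   `novel`, `truncated_in_any`, `display_name`, optional `regions`).
#' @export
call_alleles_cohort <- function(phased, db, min_individuals = 2L,
                                metadata = NULL) {
  req <- c("individual_id", "group_id", "hap1_seq", "hap2_seq")
  if (!all(req %in% names(phased))) {
    stop("phased table needs columns: ", paste(req, collapse = ", "))
  }
  long <- dplyr::bind_rows(
    tibble::tibble(individual_id = phased$individual_id,
                   group_id = phased$group_id, haplotype = 1L,
                   hap_seq = phased$hap1_seq),
    tibble::tibble(individual_id = phased$individual_id,
                   group_id = phased$group_id, haplotype = 2L,
                   hap_seq = phased$hap2_seq)
  )
  # cache matches: cohorts contain few distinct sequences per group
  cache <- new.env(parent = emptyenv())
  match_cached <- function(seq, gid) {
    key <- paste0(gid, "\r", seq)
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- match_allele(seq, db, gid)
    res$name <- name_novel_allele(res$allele, res$mutations,
                                  truncated = FALSE)
    cache[[key]] <- res
    res
  }
  matched <- Map(match_cached, long$hap_seq, long$group_id)
  long$allele_name <- vapply(matched, `[[`, character(1), "name")
  long$novel <- vapply(matched, function(m) nrow(m$mutations) > 0L, logical(1))
  long$truncated <- vapply(matched, `[[`, logical(1), "truncated")

  tab <- long |>
    dplyr::group_by(.data$group_id, .data$allele_name) |>
    dplyr::summarise(
      n_haplotypes = dplyr::n(),
      n_individuals = dplyr::n_distinct(.data$individual_id),
      novel = .data$novel[1],
      truncated_in_any = any(.data$truncated),
      .groups = "drop"
    )
  tab$called <- tab$n_individuals >= min_individuals
  key <- paste(long$group_id, long$allele_name)
  called_key <- paste(tab$group_id, tab$allele_name)[tab$called]
  long$called <- key %in% called_key
  long$allele_name[!long$called] <- "uncalled"

  tab <- tab[tab$called, , drop = FALSE]
  tab <- tab |>
    dplyr::group_by(.data$group_id) |>
    dplyr::mutate(frequency = .data$n_haplotypes / sum(.data$n_haplotypes)) |>
    dplyr::ungroup()
  tab$display_name <- ifelse(tab$truncated_in_any,
                             paste0(tab$allele_name, "(T)"),
                             tab$allele_name)
  if (!is.null(metadata)) {
    reg <- metadata$region[match(long$individual_id, metadata$individual_id)]
    reg_by <- tapply(reg[long$called],
                     paste(long$group_id, long$allele_name)[long$called],
                     function(r) paste(sort(unique(r)), collapse = ","))
    tab$regions <- unname(reg_by[paste(tab$group_id, tab$allele_name)])
  }
  tab$called <- NULL
  structure(list(calls = long, table = tab,
                 min_individuals = min_individuals),
            class = "allele_callset")
}

#' @export
print.allele_callset <- function(x, ...) {
  cat("<allele_callset> ", nrow(x$calls), " haplotype observations, ",
      nrow(x$table), " called alleles across ",
      length(unique(x$table$group_id)), " group(s) (>= ",
      x$min_individuals, " individuals)\n", sep = "")
  invisible(x)
}

#' Identify SNPs across called haplotypes
#'
#' A position is a SNP when at least two base states are each carried by at
#' least `min_individuals` distinct individuals (the same conservative rule
#' used for alleles); states below the threshold are excluded.
#'
#' @param callset An `allele_callset` (its `calls` retain haplotype
#'   sequences).
#' @param min_individuals State support threshold (default 2).
#' @return Tibble with one row per qualifying (group, position, base):
#'   0-based `position`, `base`, `n_haplotypes`, `n_individuals` and a
#'   `carriers` list column of individual ids. SNP positions are the
#'   distinct (group_id, position) pairs.
#' @export
identify_snps <- function(callset, min_individuals = 2L) {
  stopifnot(inherits(callset, "allele_callset"))
  calls <- callset$calls
  out <- list()
  for (g in unique(calls$group_id)) {
    sub <- calls[calls$group_id == g, , drop = FALSE]
    if (dplyr::n_distinct(sub$individual_id) < 2L) next
    L <- min(nchar(sub$hap_seq))
    chars <- do.call(rbind, strsplit(substr(sub$hap_seq, 1L, L), "", fixed = TRUE))
    for (p in seq_len(L)) {
      col <- chars[, p]
      if (length(unique(col)) < 2L) next
      st <- split(sub$individual_id, col)
      n_ind <- vapply(st, function(x) length(unique(x)), integer(1))
      qual <- names(st)[n_ind >= min_individuals]
      if (length(qual) < 2L) next
      for (b in qual) {
        out[[length(out) + 1L]] <- tibble::tibble(
          group_id = g, position = p - 1L, base = b,
          n_haplotypes = sum(col == b),
          n_individuals = length(unique(st[[b]])),
          carriers = list(unique(st[[b]]))
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(group_id = character(0), position = integer(0),
                          base = character(0), n_haplotypes = integer(0),
                          n_individuals = integer(0), carriers = list()))
  }
  dplyr::bind_rows(out)
}
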