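#' Construct a synthetic germline allele database
#'
#' Builds a fully synthetic allele database shaped like an IMGT germline set:
#' each segment gets a random V-exon-length base sequence (allele `*01`) and
#' a second allele `*02` carrying substitutions at fixed positions (0-based
#' 150 and 210, within one read length of the planted novel-mutation sites
#' so that heterozygous sites are phasable by read linkage). Three codons are
#' pinned on every base sequence so that planted novel alleles produce the
#' canonical mutation-name forms: `AAC` at 0-based 168 (`a>g` gives `N>D`),
#' `GAA` at 234 (`g>t` gives `E>stop`) and `CAC` at 27 (`c>g` gives `H>D`).
#' Optionally a near-identical segment pair (e.g. `IGHV3-23` / `IGHV3-23D`)
#' exercises operational grouping, and a pseudogene record exercises the
#' functionality flag.
#'
#' Sequences are random and carry no information about real germline
#' alleles; the database exists to give the simulator and tests known ground
#' truth.
#'
#' @param locus `"IGHV"` or `"TRBV"`.
#' @param segments Character vector of segment names to create (defaults to
#'   a locus-appropriate set of 11-12 two-copy-style names).
#' @param duplicate_pair Optional length-2 character vector naming a segment
#'   and its near-identical duplicate (identical `*01` sequences).
#' @param include_pseudogene Add one `P`-flagged record.
#' @param seq_length Allele length in bp (default 294, a typical V exon).
#' @param seed Seed for sequence generation.
#' @return An ungrouped `allele_database`.
#' @export
synthetic_allele_db <- function(locus = c("IGHV", "TRBV"),
                                segments = NULL,
                                duplicate_pair = NULL,
                                include_pseudogene = TRUE,
                                seq_length = 294L,
                                seed = 101L) {
  locus <- match.arg(locus)
  if (is.null(segments)) {
    segments <- if (locus == "IGHV") {
      c("IGHV1-18", "IGHV1-2", "IGHV1-46", "IGHV3-7", "IGHV3-15", "IGHV3-21",
        "IGHV3-49", "IGHV4-34", "IGHV5-51", "IGHV6-1", "IGHV3-74")
    } else {
      c("TRBV2", "TRBV5-1", "TRBV6-1", "TRBV7-2", "TRBV9", "TRBV10-1",
        "TRBV12-5", "TRBV18", "TRBV19", "TRBV20-1", "TRBV28", "TRBV30")
    }
  }
  if (is.null(duplicate_pair)) {
    duplicate_pair <- if (locus == "IGHV") c("IGHV3-23", "IGHV3-23D") else
      c("TRBV12-3", "TRBV12-4")
  }
  stopifnot(seq_length >= 240L)
  set.seed(seed)
  pin_codons <- function(s) {
    s <- substitute_bases(s, c(28L, 29L, 30L), c("C", "A", "C"))
    s <- substitute_bases(s, c(169L, 170L, 171L), c("A", "A", "C"))
    substitute_bases(s, c(235L, 236L, 237L), c("G", "A", "A"))
  }
  other_base <- function(b) sample(setdiff(DNA_BASES, b), 1)
  rows <- list()
  add_allele <- function(seg, id, seq, functional = TRUE) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      segment_name = seg, allele_id = id,
      full_name = paste0(seg, "*", id),
      nt_seq = seq, aa_seq = translate_allele(seq), functional = functional)
  }
  for (seg in segments) {
    base <- pin_codons(random_dna(1, seq_length))
    add_allele(seg, "01", base)
    a2 <- base
    for (p in c(151L, 211L)) {
      a2 <- substitute_bases(a2, p, other_base(substr(a2, p, p)))
    }
    add_allele(seg, "02", a2)
  }
  if (!is.null(duplicate_pair)) {
    dup_base <- pin_codons(random_dna(1, seq_length))
    add_allele(duplicate_pair[1], "01", dup_base)
    add_allele(duplicate_pair[2], "01", dup_base)
  }
  if (include_pseudogene) {
    add_allele(paste0(locus, "-PS1"), "01", random_dna(1, seq_length),
               functional = FALSE)
  }
  new_allele_database(dplyr::bind_rows(rows), locus)
}

#' Registry of planted novel alleles
#'
#' Resolves a table of planted mutations (group, base allele, 0-based
#' position, alternative base) against a database into full sequences and
#' the exact names the calling pipeline is expected to produce.
#'
#' @param novel_alleles Tibble with `group_id`, `base_allele`, `position`,
#'   `alt_base`.
#' @param db A grouped `allele_database`.
#' @return Tibble adding `label` (the expected allele name, used as the
#'   allele identifier in frequency configurations) and `seq`.
#' @export
novel_allele_registry <- function(novel_alleles, db) {
  if (is.null(novel_alleles) || nrow(novel_alleles) == 0L) {
    return(tibble::tibble(group_id = character(0), base_allele = character(0),
                          position = integer(0), alt_base = character(0),
                          label = character(0), seq = character(0)))
  }
  rows <- lapply(seq_len(nrow(novel_alleles)), function(i) {
    base <- novel_alleles$base_allele[i]
    ref <- db$alleles$nt_seq[match(base, db$alleles$full_name)]
    if (is.na(ref)) stop("unknown base allele: ", base)
    mut <- mutation_records(ref, novel_alleles$position[i],
                            novel_alleles$alt_base[i])
    tibble::tibble(
      group_id = novel_alleles$group_id[i],
      base_allele = base,
      position = as.integer(novel_alleles$position[i]),
      alt_base = novel_alleles$alt_base[i],
      label = name_novel_allele(base, mut),
      seq = apply_mutations(ref, mut)
    )
  })
  dplyr::bind_rows(rows)
}
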