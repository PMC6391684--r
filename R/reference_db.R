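#' Load a germline allele database from an IMGT-dialect FASTA
#'
#' Reads a FASTA of germline V-segment alleles. Headers are either plain
#' (`>IGHV1-18*01`) or `|`-separated IMGT-style fields, in which case the
#' field containing a `SEGMENT*NN` token is taken as the allele name and an
#' optional field equal to `F`, `ORF` or `P` (possibly parenthesised) is the
#' IMGT functionality annotation. Records without a functionality field are
#' assumed functional. Pseudogene (`P`) and `ORF` records are retained but
#' flagged non-functional; downstream statistics ignore them.
#'
#' @param path Path to the FASTA file.
#' @param locus Gene family the database describes, `"IGHV"` or `"TRBV"`.
#' @return An object of class `allele_database`: a list with
#'   `alleles` (tibble with columns `segment_name`, `allele_id`, `full_name`,
#'   `nt_seq`, `aa_seq`, `functional`), `groups` (filled by
#'   [group_operational_segments()], initially `NULL`) and `locus`.
#' @seealso [group_operational_segments()], [translate_allele()]
#' @examples
#' fa <- system.file("extdata", "synthetic_ighv_alleles.fasta",
#'                   package = "vgenevar")
#' db <- load_allele_fasta(fa, "IGHV")
#' db
#' @export
load_allele_fasta <- function(path, locus = c("IGHV", "TRBV")) {
  locus <- match.arg(locus)
  if (!file.exists(path)) stop("allele FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  parsed <- lapply(names(seqs), parse_imgt_header)
  nt <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", nt)
  if (any(bad)) {
    stop("non-nucleotide characters in record ",
         vapply(parsed[bad], `[[`, character(1), "full_name")[1])
  }
  full_names <- vapply(parsed, `[[`, character(1), "full_name")
  if (anyDuplicated(full_names)) {
    stop("duplicate allele name(s): ",
         paste(unique(full_names[duplicated(full_names)]), collapse = ", "))
  }
  alleles <- tibble::tibble(
    segment_name = vapply(parsed, `[[`, character(1), "segment_name"),
    allele_id    = vapply(parsed, `[[`, character(1), "allele_id"),
    full_name    = full_names,
    nt_seq       = unname(nt),
    aa_seq       = vapply(unname(nt), translate_allele, character(1)),
    functional   = vapply(parsed, `[[`, logical(1), "functional")
  )
  new_allele_database(alleles, locus)
}

new_allele_database <- function(alleles, locus, groups = NULL) {
  structure(list(alleles = alleles, groups = groups, locus = locus),
            class = "allele_database")
}

#' @export
print.allele_database <- function(x, ...) {
  cat("<allele_database> ", x$locus, ": ", nrow(x$alleles), " alleles, ",
      length(unique(x$alleles$segment_name)), " segments (",
      sum(x$alleles$functional), " functional alleles)\n", sep = "")
  if (!is.null(x$groups)) {
    cat("  ", nrow(x$groups), " operational groups\n", sep = "")
  }
  invisible(x)
}

# Parse one FASTA header into name/functionality fields.
parse_imgt_header <- function(header) {
  fields <- trimws(strsplit(header, "|", fixed = TRUE)[[1]])
  name_re <- "^[A-Za-z][A-Za-z0-9()./-]*\\*[0-9A-Za-z]+$"
  is_name <- grepl(name_re, fields)
  if (!any(is_name)) {
    stop("malformed FASTA header (no 'SEGMENT*NN' allele token): '",
         header, "'", call. = FALSE)
  }
  full_name <- fields[which(is_name)[1]]
  func_re <- "^\\(?(F|ORF|P)\\)?$"
  func_fields <- fields[grepl(func_re, fields) & !is_name]
  functional <- if (length(func_fields) == 0L) TRUE else {
    sub(func_re, "\\1", func_fields[1]) == "F"
  }
  list(
    segment_name = sub("\\*.*$", "", full_name),
    allele_id    = sub("^.*\\*", "", full_name),
    full_name    = full_name,
    functional   = functional
  )
}

#' Write an allele database to FASTA
#'
#' Inverse of [load_allele_fasta()]; headers are `NAME*NN|F` or `NAME*NN|P`.
#'
#' @param db An `allele_database`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allele_fasta <- function(db, path) {
  hdr <- paste0(db$alleles$full_name, "|",
                ifelse(db$alleles$functional, "F", "P"))
  writeLines(paste0(">", hdr, "\n", db$alleles$nt_seq), path)
  invisible(path)
}

#' Translate a nucleotide sequence with the standard genetic code
#'
#' Stop codons are rendered as `"_"` (the convention used in novel-allele
#' names, where a mutation to a stop appears as e.g. `gt234E_`), codons
#' containing ambiguous bases as `"X"`, and a trailing partial codon is
#' dropped.
#'
#' @param nt_seq A single nucleotide string.
#' @param frame_offset Reading-frame offset in `0:2`; V-exon databases start
#'   in frame at the first base, so the default is 0.
#' @return The amino-acid string (possibly empty).
#' @examples
#' translate_allele("ATGGAT")  # "MD"
#' translate_allele("TAA")     # "_"
#' @export
translate_allele <- function(nt_seq, frame_offset = 0L) {
  stopifnot(is.character(nt_seq), length(nt_seq) == 1L)
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  s <- substr(toupper(nt_seq), frame_offset + 1L, nchar(nt_seq))
  n_codons <- nchar(s) %/% 3L
  if (n_codons == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n_codons)
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  aa[aa == "*"] <- "_"
  paste(aa, collapse = "")
}

#' Global alignment identity between two nucleotide sequences
#'
#' Identity is matches divided by alignment length (gaps included, end gaps
#' penalized), computed from a Needleman-Wunsch alignment via
#' `Biostrings::pairwiseAlignment`.
#'
#' @param a,b Nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend Scoring for the alignment used
#'   to define identity (defaults: 1/-1, gap open 4, extend 1).
#' @return Identity fraction in \[0, 1\].
#' @export
global_alignment_identity <- function(a, b, match = 1, mismatch = -1,
                                      gap_open = 4, gap_extend = 1) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = sm,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(p == s & p != "-") / length(p)
}

#' Group segments into operationally distinguishable units
#'
#' Short-read data cannot genotype near-identical segments separately (for
#' example the pair IGHV3-23 / IGHV3-23D), so segments are merged by
#' single-linkage: two segments join one group when any allele pair across
#' them reaches `identity_threshold` global-alignment identity. Single
#' linkage reproduces chained sets such as the four-member
#' IGHV3-30 / IGHV3-30-3 / IGHV3-30-5 / IGHV3-33 group. Only functional
#' segments are aligned; non-functional segments become flagged singleton
#' groups so that every allele still maps to exactly one group.
#'
#' Group ids are deterministic: the lexicographically smallest member name
#' followed by `"^"`.
#'
#' @param db An `allele_database`.
#' @param identity_threshold Identity fraction in (0, 1\] above which two
#'   segments are operationally indistinguishable (default 0.95).
#' @param ... Scoring arguments passed to [global_alignment_identity()].
#' @return The `allele_database` with `groups` filled: a tibble with
#'   `group_id`, `segments` (list column), `representative_seq`, `functional`.
#' @export
group_operational_segments <- function(db, identity_threshold = 0.95, ...) {
  stopifnot(inherits(db, "allele_database"))
  if (identity_threshold <= 0 || identity_threshold > 1) {
    stop("identity_threshold must be in (0, 1]")
  }
  if (nrow(db$alleles) == 0L) stop("empty allele database")
  fun <- db$alleles[db$alleles$functional, , drop = FALSE]
  segs <- sort(unique(fun$segment_name))
  n <- length(segs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  seqs_by_seg <- split(fun$nt_seq, fun$segment_name)[segs]
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (find(i) == find(j)) next
        if (segment_pair_linked(seqs_by_seg[[i]], seqs_by_seg[[j]],
                                identity_threshold, ...)) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  members <- split(segs, comp)
  make_group <- function(m, functional) {
    m <- sort(m)
    al <- db$alleles[db$alleles$segment_name %in% m, , drop = FALSE]
    rep_seq <- al$nt_seq[order(al$full_name)][1]
    tibble::tibble(group_id = paste0(m[1], "^"),
                   segments = list(m),
                   representative_seq = rep_seq,
                   functional = functional)
  }
  groups <- dplyr::bind_rows(lapply(members, make_group, functional = TRUE))
  nonfun_segs <- setdiff(unique(db$alleles$segment_name), segs)
  if (length(nonfun_segs) > 0L) {
    groups <- dplyr::bind_rows(
      groups,
      dplyr::bind_rows(lapply(nonfun_segs, function(s) make_group(s, FALSE)))
    )
  }
  groups <- groups[order(groups$group_id), , drop = FALSE]
  db$groups <- groups
  db
}

# TRUE when any allele pair across two segments reaches the threshold.
# Two screens avoid needless alignments: a length-ratio bound (identity
# cannot exceed lmin/lmax), and for equal-length pairs the ungapped identity
# decides directly when it is far from the threshold; borderline pairs fall
# through to the full global alignment.
segment_pair_linked <- function(seqs_a, seqs_b, threshold, ...) {
  for (a in seqs_a) {
    for (b in seqs_b) {
      lmin <- min(nchar(a), nchar(b))
      lmax <- max(nchar(a), nchar(b))
      if (lmin / lmax < threshold) next  # identity <= lmin/lmax
      if (lmin == lmax) {
        u <- 1 - length(prefix_mismatch_positions(a, b)) / lmin
        if (u >= threshold) return(TRUE)
        if (u < threshold - 0.2) next
      }
      if (global_alignment_identity(a, b, ...) >= threshold) return(TRUE)
    }
  }
  FALSE
}

#' Segment membership of operational groups
#'
#' @param db A grouped `allele_database`.
#' @return Named character vector mapping segment name to group id.
#' @export
segment_to_group <- function(db) {
  if (is.null(db$groups)) stop("database has no groups; run group_operational_segments()")
  out <- character(0)
  for (i in seq_len(nrow(db$groups))) {
    m <- db$groups$segments[[i]]
    out[m] <- db$groups$group_id[i]
  }
  out
}

# alleles (rows of db$alleles) belonging to one group id
group_alleles <- function(db, group_id) {
  if (is.null(db$groups)) stop("database has no groups; run group_operational_segments()")
  idx <- match(group_id, db$groups$group_id)
  if (is.na(idx)) stop("group not in database: ", group_id)
  members <- db$groups$segments[[idx]]
  db$alleles[db$alleles$segment_name %in% members & db$alleles$functional, ,
             drop = FALSE]
}
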