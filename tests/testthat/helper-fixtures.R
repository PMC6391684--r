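# shared fixtures, built in code

# write records to a temp FASTA and load it as an allele database
make_db <- function(names, seqs, functional = NULL, locus = "IGHV",
                    grouped = FALSE, identity = 0.95) {
  hdr <- names
  if (!is.null(functional)) {
    hdr <- paste0(names, "|", ifelse(functional, "F", "P"))
  }
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(paste0(">", hdr, "\n", seqs), path)
  db <- load_allele_fasta(path, locus)
  if (grouped) db <- group_operational_segments(db, identity)
  db
}

# deterministic random DNA for fixtures
rand_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate a sequence at given 1-based positions to a different fixed base
mutate_at <- function(seq, positions) {
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  for (p in positions) {
    substr(seq, p, p) <- rot[[substr(seq, p, p)]]
  }
  seq
}

# small simulation config: one 2-variant insertion polymorphism over two
# groups, a handful of two-copy groups, configurable noise
small_sim_config <- function(n_per_region = c(North = 50L, South = 50L),
                             cv = 0, ins_freq = c(North = 0.5, South = 0.5),
                             seed = 1L, db = NULL) {
  db <- db %||% shared_test_db()
  poly <- cnv_polymorphism("ins_block", c("gIns1^", "gIns2^"),
                           list(ins = c(1L, 1L), del = c(0L, 1L)))
  vf <- matrix(c(ins_freq, 1 - ins_freq), ncol = 2,
               dimnames = list(names(n_per_region), c("ins", "del")))
  simulation_config(
    locus = "IGHV", db = db,
    n_per_region = n_per_region,
    blood_saliva_per_region = n_per_region,
    polymorphisms = list(poly),
    variant_freqs = list(ins_block = vf),
    novel_alleles = tibble::tibble(group_id = character(0),
                                   base_allele = character(0),
                                   position = integer(0),
                                   alt_base = character(0)),
    allele_freqs = list(),
    two_copy_groups = character(0),
    n_groups_total = 0L,
    coverage_noise_cv = cv,
    seed = seed
  )
}

# one grouped default db per session (grouping is the slow step)
shared_test_db <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$db)) {
      db <- synthetic_allele_db("IGHV", seed = 101L)
      cache$db <- group_operational_segments(db, 0.95)
    }
    cache$db
  }
})

`%||%` <- function(x, y) if (is.null(x)) y else x
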