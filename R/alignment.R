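#' Alignment scoring schemes
#'
#' Substitution matrix plus affine gap penalties. A gap of length `L` costs
#' `gap_open + gap_extend * L` (the first gapped position pays both the
#' opening and one extension). `protein_scoring()` defaults to BLOSUM62 with
#' gap open 11 / extend 1; `dna_scoring()` to match 2 / mismatch -2 with gap
#' open 3 / extend 1.
#'
#' @param matrix Named square substitution matrix (protein), or built from
#'   `match`/`mismatch` (DNA).
#' @param gap_open,gap_extend Positive gap penalties.
#' @param match,mismatch DNA match/mismatch scores.
#' @return A list of class `alignment_scoring`.
#' @name alignment_scoring
NULL

#' @rdname alignment_scoring
#' @export
protein_scoring <- function(matrix = NULL, gap_open = 11, gap_extend = 1) {
  if (is.null(matrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    matrix <- e$BLOSUM62
  }
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, alphabet = "AA"),
            class = "alignment_scoring")
}

#' @rdname alignment_scoring
#' @export
dna_scoring <- function(match = 2, mismatch = -2, gap_open = 3,
                        gap_extend = 1) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  structure(list(matrix = m, gap_open = gap_open, gap_extend = gap_extend,
                 alphabet = "DNA"),
            class = "alignment_scoring")
}

# shared affine-gap dynamic programming with traceback.
# type "local": Smith-Waterman (scores floored at 0, best cell anywhere);
# type "global": Needleman-Wunsch with end gaps penalized.
align_dp <- function(a, b, scoring, type) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  sm <- scoring$matrix
  missing_l <- setdiff(unique(c(av, bv)), rownames(sm))
  if (length(missing_l) > 0L) {
    stop("letters absent from substitution matrix: ",
         paste(missing_l, collapse = ", "))
  }
  S <- sm[av, bv, drop = FALSE]
  n <- length(av); m <- length(bv)
  go <- scoring$gap_open; ge <- scoring$gap_extend
  NEG <- -1e18

  H <- matrix(0, n + 1L, m + 1L)   # best score ending at (i, j)
  E <- matrix(NEG, n + 1L, m + 1L) # gap in a (move along b)
  Fm <- matrix(NEG, n + 1L, m + 1L) # gap in b (move along a)
  ptr <- matrix(0L, n + 1L, m + 1L) # 1 diag, 2 left(E), 3 up(F), 0 stop
  if (type == "global") {
    H[1, ] <- c(0, -(go + ge * seq_len(m)))
    H[, 1] <- c(0, -(go + ge * seq_len(n)))
    E[1, 2:(m + 1L)] <- H[1, 2:(m + 1L)]
    Fm[2:(n + 1L), 1] <- H[2:(n + 1L), 1]
    ptr[1, 2:(m + 1L)] <- 2L
    ptr[2:(n + 1L), 1] <- 3L
  }
  for (i in 2:(n + 1L)) {
    Hi1 <- H[i - 1L, ]
    for (j in 2:(m + 1L)) {
      e <- max(H[i, j - 1L] - go - ge, E[i, j - 1L] - ge)
      f <- max(Hi1[j] - go - ge, Fm[i - 1L, j] - ge)
      d <- Hi1[j - 1L] + S[i - 1L, j - 1L]
      best <- max(d, e, f)
      p <- if (best == d) 1L else if (best == e) 2L else 3L
      if (type == "local" && best <= 0) {
        best <- 0
        p <- 0L
      }
      H[i, j] <- best
      E[i, j] <- e
      Fm[i, j] <- f
      ptr[i, j] <- p
    }
  }
  if (type == "local") {
    idx <- which(H == max(H), arr.ind = TRUE)
    # deterministic: smallest i then j
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    score <- H[i, j]
    if (score <= 0) {
      return(new_alignment_result(0, 0, 0L, "", ""))
    }
  } else {
    i <- n + 1L; j <- m + 1L
    score <- H[i, j]
  }
  # traceback
  pa <- character(0); pb <- character(0)
  while (i > 1L || j > 1L) {
    p <- ptr[i, j]
    if (type == "local" && (p == 0L || H[i, j] == 0)) break
    if (p == 1L) {
      pa <- c(av[i - 1L], pa); pb <- c(bv[j - 1L], pb)
      i <- i - 1L; j <- j - 1L
    } else if (p == 2L) {
      # gap in a: consume b until the gap opened
      repeat {
        pa <- c("-", pa); pb <- c(bv[j - 1L], pb)
        opened <- abs(E[i, j] - (H[i, j - 1L] - go - ge)) < 1e-9
        j <- j - 1L
        if (opened || j == 1L) break
      }
    } else if (p == 3L) {
      repeat {
        pa <- c(av[i - 1L], pa); pb <- c("-", pb)
        opened <- abs(Fm[i, j] - (H[i - 1L, j] - go - ge)) < 1e-9
        i <- i - 1L
        if (opened || i == 1L) break
      }
    } else {
      break
    }
  }
  matches <- sum(pa == pb & pa != "-")
  len <- length(pa)
  new_alignment_result(score,
                       if (len > 0) matches / len else 0,
                       len,
                       paste(pa, collapse = ""),
                       paste(pb, collapse = ""))
}

new_alignment_result <- function(score, identity, aligned_length,
                                 aligned_a, aligned_b) {
  structure(list(score = score, identity = identity,
                 aligned_length = as.integer(aligned_length),
                 aligned_a = aligned_a, aligned_b = aligned_b),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment_result> score ", format(x$score), ", identity ",
      format(round(x$identity, 3)), " over ", x$aligned_length,
      " columns\n", sep = "")
  invisible(x)
}

#' Smith-Waterman local alignment (affine gaps)
#'
#' Optimal local alignment by dynamic programming with affine gap penalties.
#' The score is never negative; sequences with no positive-scoring residue
#' pair align empty with score 0. Symmetric in its arguments for symmetric
#' substitution matrices.
#'
#' @param a,b Sequences (strings).
#' @param scoring An [alignment_scoring] scheme (default [protein_scoring()]).
#' @return An `alignment_result`: `score`, `identity` (matches over aligned
#'   columns), `aligned_length`, and the aligned strings.
#' @export
smith_waterman <- function(a, b, scoring = protein_scoring()) {
  align_dp(a, b, scoring, type = "local")
}

#' Needleman-Wunsch global alignment (affine gaps, end gaps penalized)
#'
#' @inheritParams smith_waterman
#' @return An `alignment_result`.
#' @export
needleman_wunsch <- function(a, b, scoring = protein_scoring()) {
  align_dp(a, b, scoring, type = "global")
}
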