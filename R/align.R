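#' @keywords internal
#' Substitution matrix by name. Only BLOSUM62 (from Biostrings' published
#' copy) is shipped; stop codons are rescored to -4 against everything so a
#' translated-frame alignment can never profit from a stop.
get_submatrix <- function(name = "BLOSUM62") {
  if (!identical(name, "BLOSUM62")) {
    abort(paste0("unknown substitution matrix: ", name))
  }
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62
  m["*", ] <- -4L
  m[, "*"] <- -4L
  storage.mode(m) <- "integer"
  m
}

#' Optimal local alignment (affine gaps)
#'
#' Smith-Waterman with affine gap costs: a gap of length L costs
#' `gap_open + L * gap_extend`. The score is the true optimum; traceback is
#' deterministic (ties prefer substitution over a gap in the query over a
#' gap in the subject; the best cell with the smallest subject end, then
#' query end, wins).
#'
#' @param query,subject non-empty protein strings. Stop characters (`*`) in
#'   the subject split it into segments that are aligned separately — an
#'   alignment never crosses a stop.
#' @param matrix substitution matrix name.
#' @param gap_open,gap_extend positive gap costs.
#' @return one-row tibble: `score`, `qstart`, `qend`, `sstart`, `send`
#'   (1-based inclusive; 0s for an empty alignment), `qaln`, `saln`.
#' @export
local_align <- function(query, subject, matrix = "BLOSUM62",
                        gap_open = 11L, gap_extend = 1L) {
  if (nchar(query) == 0 || nchar(subject) == 0) {
    abort("alignment requires non-empty sequences")
  }
  smat <- get_submatrix(matrix)
  segs <- subject_segments(subject)
  best <- NULL
  for (k in seq_len(nrow(segs))) {
    r <- .align_pair_cpp(query, segs$seq[k], smat, rownames(smat),
                         as.integer(gap_open), as.integer(gap_extend),
                         local = TRUE, traceback = TRUE)
    r$sstart <- if (r$sstart > 0) r$sstart + segs$offset[k] else 0L
    r$send <- if (r$send > 0) r$send + segs$offset[k] else 0L
    if (is.null(best) || r$score > best$score) best <- r
  }
  tibble(score = best$score, qstart = best$qstart, qend = best$qend,
         sstart = best$sstart, send = best$send,
         qaln = best$qaln, saln = best$saln)
}

# Split a translated frame at stop codons; returns non-empty segments with
# their 0-based offsets on the original string.
subject_segments <- function(subject) {
  parts <- strsplit(subject, "*", fixed = TRUE)[[1]]
  if (length(parts) == 0) parts <- ""
  offs <- cumsum(c(0L, nchar(parts) + 1L))[seq_along(parts)]
  keep <- nchar(parts) > 0
  if (!any(keep)) return(tibble(seq = character(), offset = integer()))
  tibble(seq = parts[keep], offset = as.integer(offs[keep]))
}

#' Optimal global alignment (affine gaps)
#'
#' Needleman-Wunsch counterpart of [local_align()], used for mature-peptide
#' family comparisons. Same gap model and deterministic tie-breaking.
#'
#' @inheritParams local_align
#' @param a,b non-empty peptide strings.
#' @return one-row tibble: `score`, `aln_a`, `aln_b`.
#' @export
pairwise_align_global <- function(a, b, matrix = "BLOSUM62",
                                  gap_open = 11L, gap_extend = 1L) {
  if (nchar(a) == 0 || nchar(b) == 0) {
    abort("alignment requires non-empty sequences")
  }
  smat <- get_submatrix(matrix)
  r <- .align_pair_cpp(a, b, smat, rownames(smat),
                       as.integer(gap_open), as.integer(gap_extend),
                       local = FALSE, traceback = TRUE)
  tibble(score = r$score, aln_a = r$qaln, aln_b = r$saln)
}

#' Karlin-Altschul E-value and bit score
#'
#' E = K * m * n * exp(-lambda * S) for raw score S, query length m and
#' database length n (in residues). Defaults are the published gapped
#' BLOSUM62 constants. These statistics are self-consistent within the
#' package; they are not calibrated to reproduce NCBI BLAST output.
#'
#' @param raw_score integer local-alignment score.
#' @param query_len,db_len_aa positive lengths in residues.
#' @param lambda,K statistical parameters.
#' @return numeric E-value (`evalue()`) or bit score (`bit_score()`).
#' @export
evalue <- function(raw_score, query_len, db_len_aa,
                   lambda = 0.267, K = 0.041) {
  if (any(query_len <= 0) || any(db_len_aa <= 0)) {
    abort("`query_len` and `db_len_aa` must be positive")
  }
  K * query_len * db_len_aa * exp(-lambda * raw_score)
}

#' @rdname evalue
#' @export
bit_score <- function(raw_score, lambda = 0.267, K = 0.041) {
  (lambda * raw_score - log(K)) / log(2)
}
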