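#' Six-frame translation of a transcript
#'
#' Translates a nucleotide sequence in all six reading frames under the
#' standard genetic code, the search space for translated homology mining.
#' Stops are rendered `*`; any codon containing `N` translates to `X`.
#' Frames −1..−3 translate the reverse complement. Frames too short to hold
#' a codon yield an empty peptide.
#'
#' @param sequence nucleotide string (ACGTN) or a tibble row with
#'   `id`/`sequence` columns.
#' @param id transcript id used in the output (ignored when `sequence` is a
#'   tibble).
#' @return tibble with columns `transcript_id`, `frame` (+1,+2,+3,-1,-2,-3)
#'   and `peptide`.
#' @export
six_frame_translate <- function(sequence, id = "transcript") {
  if (is.data.frame(sequence)) {
    ids <- sequence$id
    sequence <- sequence$sequence
  } else {
    ids <- rep(id, length.out = length(sequence))
  }
  sequence <- str_to_upper(sequence)
  bad <- which(!grepl(alphabet_regex("nucleotide"), sequence))
  if (length(bad)) {
    abort(paste0("transcript '", ids[bad[1]],
                 "' is not a valid nucleotide sequence"))
  }
  fwd <- Biostrings::DNAStringSet(sequence)
  rev <- Biostrings::reverseComplement(fwd)
  batch <- function(ss, off) {
    L <- Biostrings::width(ss)
    w <- pmax((L - off) - (L - off) %% 3L, 0L)
    sub <- Biostrings::subseq(ss, start = pmin(off + 1L, L + 1L), width = w)
    as.character(Biostrings::translate(sub, if.fuzzy.codon = "X",
                                       no.init.codon = TRUE))
  }
  peps <- c(lapply(0:2, function(o) batch(fwd, o)),
            lapply(0:2, function(o) batch(rev, o)))
  out <- tibble(
    transcript_id = rep(ids, 6L),
    frame = rep(c(1L, 2L, 3L, -1L, -2L, -3L), each = length(ids)),
    peptide = unname(unlist(peps))
  )
  # transcript-major order, frames +1,+2,+3,-1,-2,-3 within each transcript
  out[order(rep(seq_along(ids), 6L), rep(seq_len(6L), each = length(ids))), ]
}

#' Map translated-frame coordinates back to the transcript
#'
#' For residue `i` of the frame translation, gives the 1-based
#' forward-strand nucleotide span of its codon.
#'
#' @param frame frame index in +1..+3, -1..-3.
#' @param nt_len transcript length in nucleotides.
#' @param i residue position(s), 1-based.
#' @return tibble with `nt_start`, `nt_end` (forward-strand, start <= end).
#' @export
frame_to_nt <- function(frame, nt_len, i) {
  off <- abs(frame)
  s_local <- off + 3L * (i - 1L)       # codon start on the read strand
  e_local <- s_local + 2L
  if (frame > 0) {
    tibble(nt_start = s_local, nt_end = e_local)
  } else {
    tibble(nt_start = nt_len - e_local + 1L, nt_end = nt_len - s_local + 1L)
  }
}
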