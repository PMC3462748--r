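#' Mine a transcriptome for neuropeptide precursor candidates
#'
#' Translated homology search: each reference peptide is aligned (affine-gap
#' Smith-Waterman) against all six frame translations of every transcript,
#' frame segments being split at stop codons. Per query, the best alignment
#' per transcript is scored with the Karlin-Altschul E-value and the top
#' `cfg$top_k` hits under `cfg$e_threshold` are returned, sorted by
#' ascending E-value. Ties are broken by raw score (descending), earlier
#' subject start, earlier query start, then frame index.
#'
#' @param queries tibble of reference peptides (`id`, `sequence`, optionally
#'   `family`).
#' @param transcripts tibble of transcripts (`id`, `sequence`, nucleotide).
#' @param cfg a [pipeline_config()].
#' @return tibble of hits: `query_id`, `family`, `transcript_id`, `frame`,
#'   `raw_score`, `bit_score`, `e_value`, `qstart`, `qend`, `sstart`, `send`
#'   (1-based on the frame translation), `qaln`, `saln`.
#' @export
mine_transcriptome <- function(queries, transcripts, cfg = pipeline_config()) {
  if (nrow(queries) == 0 || nrow(transcripts) == 0) {
    abort("`queries` and `transcripts` must be non-empty")
  }
  smat <- get_submatrix(cfg$matrix)
  frames <- six_frame_translate(transcripts)
  frames <- frames[nchar(frames$peptide) > 0, , drop = FALSE]
  # search space: stop-free segments of every frame translation
  seg_tbl <- list_rbind(map(seq_len(nrow(frames)), function(i) {
    s <- subject_segments(frames$peptide[i])
    if (nrow(s) == 0) return(NULL)
    s$transcript_id <- frames$transcript_id[i]
    s$frame <- frames$frame[i]
    s
  }))
  if (is.null(seg_tbl) || nrow(seg_tbl) == 0) {
    return(empty_hits())
  }
  db_len_aa <- sum(nchar(frames$peptide))
  fam <- queries$family %||% rep("unknown", nrow(queries))

  out <- list_rbind(map(seq_len(nrow(queries)), function(qi) {
    q <- queries$sequence[qi]
    scores <- .sw_scores_cpp(q, seg_tbl$seq, smat, rownames(smat),
                             cfg$gap_open, cfg$gap_extend)$score
    ev <- evalue(scores, nchar(q), db_len_aa, cfg$lambda, cfg$K)
    cand <- which(ev < cfg$e_threshold & scores > 0)
    if (length(cand) == 0) return(NULL)
    # best segment per transcript, then traceback for survivors only
    per <- tibble(idx = cand, transcript_id = seg_tbl$transcript_id[cand],
                  raw_score = scores[cand]) |>
      group_by(.data$transcript_id) |>
      arrange(desc(.data$raw_score), .data$idx, .by_group = TRUE) |>
      slice_head(n = 1L) |>
      ungroup()
    rows <- map(per$idx, function(k) {
      al <- .align_pair_cpp(q, seg_tbl$seq[k], smat, rownames(smat),
                            cfg$gap_open, cfg$gap_extend,
                            local = TRUE, traceback = TRUE)
      tibble(
        query_id = queries$id[qi], family = fam[qi],
        transcript_id = seg_tbl$transcript_id[k], frame = seg_tbl$frame[k],
        raw_score = al$score,
        bit_score = bit_score(al$score, cfg$lambda, cfg$K),
        e_value = evalue(al$score, nchar(q), db_len_aa, cfg$lambda, cfg$K),
        qstart = al$qstart, qend = al$qend,
        sstart = al$sstart + seg_tbl$offset[k],
        send = al$send + seg_tbl$offset[k],
        qaln = al$qaln, saln = al$saln
      )
    }) |> list_rbind()
    rows |>
      arrange(.data$e_value, desc(.data$raw_score), .data$sstart,
              .data$qstart, .data$frame) |>
      slice_head(n = cfg$top_k)
  }))
  if (is.null(out) || nrow(out) == 0) empty_hits() else out
}

empty_hits <- function() {
  tibble(query_id = character(), family = character(),
         transcript_id = character(), frame = integer(),
         raw_score = integer(), bit_score = numeric(), e_value = numeric(),
         qstart = integer(), qend = integer(), sstart = integer(),
         send = integer(), qaln = character(), saln = character())
}

#' Write hits as a BLAST-style tab-separated table
#'
#' Columns follow the familiar tabular-report order (qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore).
#' Subject coordinates are on the frame translation; the frame is appended
#' as an extra final column.
#'
#' @param hits tibble from [mine_transcriptome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_table <- function(hits, path) {
  split_cols <- function(qa, sa) {
    qs <- strsplit(qa, "")[[1]]; ss <- strsplit(sa, "")[[1]]
    ng <- qs != "-" & ss != "-"
    tibble(length = length(qs),
           mismatch = sum(ng & qs != ss),
           gapopen = sum(diff(c(FALSE, qs == "-")) == 1) +
             sum(diff(c(FALSE, ss == "-")) == 1),
           pident = round(100 * sum(ng & qs == ss) / length(qs), 2))
  }
  stats <- list_rbind(map2(hits$qaln, hits$saln, split_cols))
  out <- tibble(
    qseqid = hits$query_id, sseqid = hits$transcript_id,
    pident = stats$pident, length = stats$length,
    mismatch = stats$mismatch, gapopen = stats$gapopen,
    qstart = hits$qstart, qend = hits$qend,
    sstart = hits$sstart, send = hits$send,
    evalue = signif(hits$e_value, 3), bitscore = round(hits$bit_score, 1),
    frame = hits$frame
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
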