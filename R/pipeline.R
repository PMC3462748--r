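#' Run the full discovery pipeline
#'
#' mine -> ORF extraction -> signal peptide -> cleavage sites -> three-
#' criteria screen -> excision -> PTMs -> family motifs. One candidate is
#' annotated per mined transcript (its best hit); peptide families come
#' from motif matches, falling back to the homology family of the
#' supporting query. By default only screen-passing precursors are
#' reported.
#'
#' @param transcripts tibble (`id`, `sequence`, nucleotide).
#' @param references reference tibble (see [reference_peptides()]).
#' @param cfg a [pipeline_config()].
#' @param motifs motif tibble (see [default_motifs()]).
#' @return list of class `pepmine_run`: `annotations` (screen-passing, or
#'   all when `cfg$keep_failures`), `hits`, `peptides` (tidy table over
#'   reported annotations), `manifest`.
#' @export
run_discovery <- function(transcripts, references,
                          cfg = pipeline_config(),
                          motifs = default_motifs()) {
  hits <- if (nrow(transcripts) == 0) empty_hits() else {
    mine_transcriptome(references, transcripts, cfg)
  }
  # best hit per transcript decides the homology family of its candidate
  best <- if (nrow(hits) == 0) hits else {
    hits |>
      arrange(.data$e_value, desc(.data$raw_score), .data$transcript_id) |>
      distinct(.data$transcript_id, .keep_all = TRUE)
  }
  annotations <- map(seq_len(nrow(best)), function(i) {
    h <- best[i, ]
    tr <- transcripts[transcripts$id == h$transcript_id, ]
    cand <- tryCatch(find_orf(h, tr), error = function(e) {
      abort(paste0("stage find_orf failed for record '", h$transcript_id,
                   "': ", conditionMessage(e)))
    })
    ann <- annotate_precursor(cand$protein, precursor_id = h$transcript_id,
                              cfg = cfg, motifs = motifs,
                              homology_family = h$family)
    ann$candidate <- cand
    ann
  })
  passed <- keep(annotations, function(a) isTRUE(a$screen$passed))
  reported <- if (isTRUE(cfg$keep_failures)) annotations else passed
  manifest <- run_manifest(transcripts, references, cfg, counts = c(
    transcripts = nrow(transcripts), references = nrow(references),
    hits = nrow(hits), candidates = length(annotations),
    passed = length(passed),
    peptides = sum(map_int(reported, function(a) nrow(a$peptides)))
  ))
  structure(list(annotations = reported, hits = hits,
                 peptides = peptide_table(reported), manifest = manifest),
            class = "pepmine_run")
}

#' @export
print.pepmine_run <- function(x, ...) {
  cts <- x$manifest$counts
  cat("pepmine discovery run\n")
  cat(sprintf("  %d transcripts x %d references -> %d hits, %d candidates, %d passed, %d peptides\n",
              cts[["transcripts"]], cts[["references"]], cts[["hits"]],
              cts[["candidates"]], cts[["passed"]], cts[["peptides"]]))
  invisible(x)
}

#' @export
tidy.pepmine_run <- function(x, ...) x$peptides

#' @export
glance.pepmine_run <- function(x, ...) {
  as_tibble(as.list(x$manifest$counts))
}

# Reproducibility manifest: config snapshot, input digests, stage counts.
run_manifest <- function(transcripts, references, cfg, counts) {
  digest_tbl <- function(tbl) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    readr::write_tsv(tbl, tmp)
    unname(tools::md5sum(tmp))
  }
  list(
    version = as.character(utils::packageVersion("pepmine")),
    config = unclass(cfg),
    inputs = list(
      transcripts = list(n = nrow(transcripts), md5 = digest_tbl(transcripts)),
      references = list(n = nrow(references), md5 = digest_tbl(references))
    ),
    seed = cfg$seed,
    counts = as.list(counts)
  )
}

#' Write a run manifest as JSON
#'
#' @param run a `pepmine_run`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(run, path) {
  jsonlite::write_json(run$manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
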