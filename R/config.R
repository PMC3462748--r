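#' Pipeline configuration
#'
#' Central knob set for the discovery pipeline. Defaults follow the classical
#' transcriptome-mining protocol: hits kept at E < 0.01, top three hits per
#' query, precursors shorter than 300 residues, BLOSUM62 with BLAST-style
#' affine gap costs (a gap of length L costs `gap_open + L * gap_extend`),
#' and gapped Karlin-Altschul constants lambda = 0.267, K = 0.041.
#'
#' @param e_threshold numeric > 0; E-value cutoff for mined hits.
#' @param top_k integer >= 1; hits kept per query.
#' @param max_precursor_len integer >= 1; precursors must be strictly shorter.
#' @param matrix substitution matrix name; only "BLOSUM62" ships.
#' @param gap_open,gap_extend integer gap penalties (positive costs).
#' @param lambda,K Karlin-Altschul statistical parameters.
#' @param accept_RK,accept_KK accept the less canonical dibasic sites.
#' @param pyroglu_E treat N-terminal Glu (not just Gln) as cyclizable.
#' @param sulfation_window half-width of the acidic-context window around Tyr.
#' @param sulfation_acidic_min minimum D/E count in the window to call
#'   a sulfated Tyr.
#' @param dedupe_peptides if TRUE, identical mature sequences on one precursor
#'   are counted once; default counts every excised copy.
#' @param keep_failures keep precursors that fail screening in reports.
#' @param seed integer seed used by pipeline stages that draw random numbers.
#' @return A list of class `pepmine_config`.
#' @export
pipeline_config <- function(e_threshold = 0.01,
                            top_k = 3L,
                            max_precursor_len = 300L,
                            matrix = "BLOSUM62",
                            gap_open = 11L,
                            gap_extend = 1L,
                            lambda = 0.267,
                            K = 0.041,
                            accept_RK = FALSE,
                            accept_KK = FALSE,
                            pyroglu_E = FALSE,
                            sulfation_window = 5L,
                            sulfation_acidic_min = 2L,
                            dedupe_peptides = FALSE,
                            keep_failures = FALSE,
                            seed = 1L) {
  if (!is.numeric(e_threshold) || e_threshold <= 0) {
    abort("`e_threshold` must be > 0")
  }
  if (top_k < 1) abort("`top_k` must be >= 1")
  if (max_precursor_len < 1) abort("`max_precursor_len` must be >= 1")
  cfg <- list(
    e_threshold = e_threshold, top_k = as.integer(top_k),
    max_precursor_len = as.integer(max_precursor_len),
    matrix = matrix, gap_open = as.integer(gap_open),
    gap_extend = as.integer(gap_extend), lambda = lambda, K = K,
    accept_RK = accept_RK, accept_KK = accept_KK, pyroglu_E = pyroglu_E,
    sulfation_window = as.integer(sulfation_window),
    sulfation_acidic_min = as.integer(sulfation_acidic_min),
    dedupe_peptides = dedupe_peptides, keep_failures = keep_failures,
    seed = as.integer(seed)
  )
  structure(cfg, class = "pepmine_config")
}

#' Read / write a pipeline configuration as flat YAML
#'
#' @param path file path.
#' @return `read_config()` returns a `pepmine_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param cfg a `pepmine_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
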