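#' Collect mature peptides from annotations
#'
#' Binds the per-precursor peptide tables of a list of annotations into one
#' tidy table, one row per mature peptide.
#'
#' @param annotations list of `pepmine_annotation` objects.
#' @return tibble with the report columns (precursor_id, peptide_index,
#'   start, end, sequence, amidated, pyroglu, sulfated_positions, family)
#'   plus `display`.
#' @export
peptide_table <- function(annotations) {
  if (length(annotations) == 0) return(empty_peptides())
  list_rbind(map(annotations, function(a) a$peptides))
}

#' Write the pipeline report
#'
#' TSV: one row per mature peptide with fixed column order (precursor_id,
#' peptide_index, start, end, sequence, amidated, pyroglu,
#' sulfated_positions, family); sulfated positions are comma-joined.
#' JSON: a lossless mirror of the full annotation graph (protein, signal,
#' sites, screen, peptides per precursor).
#'
#' @param annotations list of `pepmine_annotation` objects.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(annotations, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- peptide_table(annotations)
    out <- tibble(
      precursor_id = tab$precursor_id, peptide_index = tab$peptide_index,
      start = tab$start, end = tab$end, sequence = tab$sequence,
      amidated = tab$amidated, pyroglu = tab$pyroglu,
      sulfated_positions = map_chr(tab$sulfated_positions,
                                   function(x) paste(x, collapse = ",")),
      family = tab$family
    )
    readr::write_tsv(out, path)
  } else {
    graph <- map(annotations, function(a) {
      peps <- a$peptides
      list(precursor_id = a$precursor_id, protein = a$protein,
           signal = as.list(a$signal),
           sites = as.list(a$sites),
           screen = as.list(a$screen),
           peptides = list(
             precursor_id = peps$precursor_id,
             peptide_index = peps$peptide_index,
             start = peps$start, end = peps$end, sequence = peps$sequence,
             amidated = peps$amidated, pyroglu = peps$pyroglu,
             sulfated_positions = peps$sulfated_positions,
             family = peps$family, display = peps$display
           ))
    })
    jsonlite::write_json(graph, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read back a JSON report
#'
#' Restores the annotation list written by `write_report(..., "json")`;
#' `write_report()` then `read_report_json()` is lossless.
#'
#' @param path JSON report path.
#' @return list of `pepmine_annotation` objects.
#' @export
read_report_json <- function(path) {
  graph <- jsonlite::read_json(path, simplifyVector = FALSE)
  map(graph, function(a) {
    p <- a$peptides
    k <- length(p$precursor_id)
    peps <- if (k == 0) empty_peptides() else tibble(
      precursor_id = as.character(unlist(p$precursor_id)),
      peptide_index = as.integer(unlist(p$peptide_index)),
      start = as.integer(unlist(p$start)),
      end = as.integer(unlist(p$end)),
      sequence = as.character(unlist(p$sequence)),
      amidated = as.logical(unlist(p$amidated)),
      pyroglu = as.logical(unlist(p$pyroglu)),
      sulfated_positions = map(p$sulfated_positions,
                               function(x) as.integer(unlist(x))),
      family = as.character(unlist(p$family)),
      display = as.character(unlist(p$display))
    )
    sites <- a$sites
    sites_tbl <- if (length(sites$position) == 0) {
      tibble(position = integer(), length = integer(),
             site_type = character(), rule = character())
    } else {
      tibble(position = as.integer(unlist(sites$position)),
             length = as.integer(unlist(sites$length)),
             site_type = as.character(unlist(sites$site_type)),
             rule = as.character(unlist(sites$rule)))
    }
    structure(list(
      precursor_id = a$precursor_id, protein = a$protein,
      signal = tibble(present = as.logical(a$signal$present),
                      cleavage_after = as.integer(a$signal$cleavage_after),
                      score = as.numeric(a$signal$score)),
      sites = sites_tbl,
      screen = tibble(has_signal = as.logical(a$screen$has_signal),
                      under_length = as.logical(a$screen$under_length),
                      has_processing_site =
                        as.logical(a$screen$has_processing_site),
                      passed = as.logical(a$screen$passed)),
      peptides = peps
    ), class = "pepmine_annotation")
  })
}

#' Precursor feature track
#'
#' BED-like, precursor-relative (1-based inclusive) feature table of the
#' signal peptide, cleavage sites and mature peptides of one annotation.
#'
#' @param annotation a `pepmine_annotation`.
#' @return tibble: `feature`, `start`, `end`, `label`.
#' @export
feature_track <- function(annotation) {
  rows <- list()
  if (isTRUE(annotation$signal$present)) {
    rows$signal <- tibble(feature = "signal", start = 1L,
                          end = annotation$signal$cleavage_after,
                          label = "signal")
  }
  if (nrow(annotation$sites) > 0) {
    rows$sites <- tibble(
      feature = "cleavage_site",
      start = annotation$sites$position - annotation$sites$length + 1L,
      end = annotation$sites$position,
      label = annotation$sites$site_type
    )
  }
  if (nrow(annotation$peptides) > 0) {
    rows$peps <- tibble(feature = "peptide",
                        start = annotation$peptides$start,
                        end = annotation$peptides$end,
                        label = annotation$peptides$display)
  }
  if (length(rows) == 0) {
    return(tibble(feature = character(), start = integer(),
                  end = integer(), label = character()))
  }
  list_rbind(rows) |> arrange(.data$start)
}
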