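#' Read a FASTA file into a tibble
#'
#' Thin tidy wrapper around Biostrings' FASTA reader with strict alphabet
#' validation. Sequences are uppercased on read; any line wrapping is
#' accepted. Protein records may use the 20 standard residues plus `X`;
#' nucleotide records `ACGT` plus `N`.
#'
#' @param path FASTA file path.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param strict if TRUE (default) an out-of-alphabet character is an error;
#'   otherwise offending records are dropped with a warning.
#' @return A tibble with columns `id`, `description` (full header line) and
#'   `sequence`, in file order.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide"),
                       strict = TRUE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  check_fasta_structure(path)
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  seqs <- str_to_upper(as.character(ss))
  ids <- sub("\\s.*$", "", headers)
  bad <- which(!grepl(alphabet_regex(alphabet), seqs))
  if (length(bad) > 0) {
    msg <- paste0("record '", ids[bad[1]], "' contains characters outside the ",
                  alphabet, " alphabet")
    if (strict) abort(msg) else {
      warning(paste0(msg, "; dropped"), call. = FALSE)
      keep <- setdiff(seq_along(seqs), bad)
      ids <- ids[keep]; headers <- headers[keep]; seqs <- seqs[keep]
    }
  }
  tibble(id = ids, description = headers, sequence = unname(seqs))
}

alphabet_regex <- function(alphabet) {
  if (alphabet == "protein") "^[ACDEFGHIKLMNPQRSTVWYX]+$" else "^[ACGTN]+$"
}

# Structural pre-check so parse errors can name a line number, which the
# block reader cannot.
check_fasta_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0) abort("empty FASTA file")
  if (!startsWith(lines[nonblank[1]], ">")) {
    abort(paste0("malformed FASTA: line ", nonblank[1],
                 " is not a header line"))
  }
  is_hdr <- startsWith(lines, ">")
  for (i in which(is_hdr)) {
    if (trimws(sub("^>", "", lines[i])) == "") {
      abort(paste0("malformed FASTA: empty header at line ", i))
    }
    nxt <- lines[-seq_len(i)]
    nxt_nonblank <- which(trimws(nxt) != "")
    if (length(nxt_nonblank) == 0 || startsWith(nxt[nxt_nonblank[1]], ">")) {
      abort(paste0("malformed FASTA: record at line ", i,
                   " has an empty sequence"))
    }
  }
  invisible(TRUE)
}

#' Write a tibble of sequences as FASTA
#'
#' Lines are wrapped at 60 columns. The `description` column (if present)
#' is used as the header, otherwise `id`.
#'
#' @param records tibble with `id`, `sequence` and optionally `description`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  ss <- Biostrings::BStringSet(records$sequence)
  names(ss) <- if ("description" %in% names(records)) {
    records$description
  } else {
    records$id
  }
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Keyword-filter a curated reference set
#'
#' Emulates the keyword harvest used to assemble a local neuropeptide
#' database: records whose description matches at least one include keyword
#' and no exclude keyword are kept (case-insensitive substring match).
#' Defaults exclude receptors and membrane proteins.
#'
#' @param records tibble with a `description` column.
#' @param include character vector of keywords; must be non-empty.
#' @param exclude character vector of disqualifying keywords.
#' @return The kept rows, order preserved.
#' @export
filter_reference <- function(records,
                             include = c("neuropeptide", "hormone", "peptide"),
                             exclude = c("receptor", "signal anchor",
                                         "transmembrane")) {
  if (length(include) == 0) abort("`include` must contain at least one keyword")
  stopifnot("description" %in% names(records))
  desc <- tolower(records$description)
  hit_any <- function(kw) {
    if (length(kw) == 0) return(rep(FALSE, length(desc)))
    Reduce(`|`, lapply(tolower(kw), function(k) grepl(k, desc, fixed = TRUE)))
  }
  records[hit_any(include) & !hit_any(exclude), , drop = FALSE]
}

#' Assemble a reference peptide table
#'
#' The reference "database" is a protein tibble plus family/taxon metadata:
#' the query set for transcriptome mining.
#'
#' @param id,sequence,family,taxon,description parallel vectors; `family`
#'   defaults to `"unknown"`.
#' @return tibble with columns id, taxon, family, sequence, description.
#' @export
reference_peptides <- function(id, sequence, family = "unknown",
                               taxon = "", description = id) {
  sequence <- str_to_upper(sequence)
  if (any(nchar(sequence) == 0)) abort("reference sequences must be non-empty")
  if (any(!grepl(alphabet_regex("protein"), sequence))) {
    abort("reference sequences must use the protein alphabet (20 letters + X)")
  }
  tibble(id = id, taxon = taxon, family = family,
         sequence = sequence, description = description)
}
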