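#' Parse a family motif pattern
#'
#' Pattern language for terminal peptide signatures: literal residues;
#' `X` = any residue; `[AB]` = alternatives; `X(n)` = exactly n arbitrary
#' residues; a trailing lowercase `a` requires the peptide to be amidated.
#' Anchoring is `C` (C-terminal), `N` (N-terminal) or `any`.
#'
#' @param pattern pattern string.
#' @param anchor one of `"C"`, `"N"`, `"any"`.
#' @return list: `regex`, `requires_amidation`, `anchor`.
#' @export
parse_motif <- function(pattern, anchor = c("C", "N", "any")) {
  anchor <- match.arg(anchor)
  requires_amidation <- grepl("a$", pattern)
  body <- sub("a$", "", pattern)
  rx <- character()
  i <- 1L
  n <- nchar(body)
  while (i <= n) {
    ch <- substr(body, i, i)
    if (ch == "[") {
      close <- regexpr("]", substr(body, i, n), fixed = TRUE)
      if (close < 0) abort(paste0("unclosed [ in motif pattern: ", pattern))
      alt <- substr(body, i + 1L, i + close - 2L)
      if (nchar(alt) == 0 || !grepl("^[A-Z]+$", alt)) {
        abort(paste0("bad alternative set in motif pattern: ", pattern))
      }
      rx <- c(rx, paste0("[", alt, "]"))
      i <- i + close
    } else if (ch == "X") {
      if (substr(body, i + 1L, i + 1L) == "(") {
        close <- regexpr(")", substr(body, i, n), fixed = TRUE)
        cnt <- substr(body, i + 2L, i + close - 2L)
        if (close < 0 || !grepl("^[0-9]+$", cnt)) {
          abort(paste0("bad repeat in motif pattern: ", pattern))
        }
        rx <- c(rx, paste0(".{", cnt, "}"))
        i <- i + close
      } else {
        rx <- c(rx, ".")
        i <- i + 1L
      }
    } else if (grepl("^[A-WYZ]$", ch)) {
      rx <- c(rx, ch)
      i <- i + 1L
    } else {
      abort(paste0("unparseable character '", ch, "' in motif pattern: ",
                   pattern))
    }
  }
  regex <- paste0(rx, collapse = "")
  if (anchor == "C") regex <- paste0(regex, "$")
  if (anchor == "N") regex <- paste0("^", regex)
  list(regex = regex, requires_amidation = requires_amidation,
       anchor = anchor)
}

#' Default family motif set
#'
#' Terminal signatures of the arthropod families with clean sequence
#' motifs: FGL-amide A-type allatostatins, W(X6)W-amide B-type
#' allatostatins, the C-type allatostatin core with a variable residue at
#' the usually conserved Ala position, sulfakinins generalized to admit
#' Lys8 and Met6/Phe6 variants, SIFamide, FXGXR-amide tachykinin-related
#' peptides, and the N-terminal NFDEIDR orcokinin signature. Patterns are
#' data: edit or extend the tibble, or load one from a TSV file.
#'
#' @return tibble: `family`, `pattern`, `anchor`; row order is match
#'   priority.
#' @export
default_motifs <- function() {
  tibble(
    family = c("ASTC", "ASTB", "SK", "TRP", "SIF", "ASTA", "Orco"),
    pattern = c("SXWKQCXFNAVSCFa", "WX(6)Wa", "[YF]G[HMF][MLF][RK]Fa",
                "FXGXRa", "SIFa", "[YF]XFG[LI]a", "NFDEIDR"),
    anchor = c("C", "C", "C", "C", "C", "C", "N")
  )
}

#' Read / write a motif pattern file
#'
#' One pattern per line: `family TAB pattern TAB anchor`.
#'
#' @param path TSV path.
#' @return motif tibble (see [default_motifs()]).
#' @export
read_motifs <- function(path) {
  m <- readr::read_tsv(path, col_names = c("family", "pattern", "anchor"),
                       col_types = "ccc")
  # validate all patterns up front: a bad pattern is a config error at load
  purrr::walk2(m$pattern, m$anchor, parse_motif)
  m
}

#' @rdname read_motifs
#' @param motifs motif tibble.
#' @export
write_motifs <- function(motifs, path) {
  readr::write_tsv(motifs[, c("family", "pattern", "anchor")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Assign a peptide to a family by motif match
#'
#' Patterns are tried in priority (row) order; the first match wins.
#' Patterns carrying the amidation flag only match amidated peptides.
#'
#' @param sequence mature peptide sequence.
#' @param amidated logical amidation state of the peptide.
#' @param motifs motif tibble (see [default_motifs()]).
#' @return NULL when nothing matches, else list: `family`, `start`, `end`
#'   (matched span within the peptide).
#' @export
match_motif <- function(sequence, amidated, motifs = default_motifs()) {
  for (k in seq_len(nrow(motifs))) {
    p <- parse_motif(motifs$pattern[k], motifs$anchor[k])
    if (p$requires_amidation && !isTRUE(amidated)) next
    m <- regexpr(p$regex, sequence)
    if (m > 0) {
      return(list(family = motifs$family[k], start = as.integer(m),
                  end = as.integer(m + attr(m, "match.length") - 1L)))
    }
  }
  NULL
}

#' Count family isoforms on a precursor
#'
#' Number of mature peptides on an annotated precursor assigned to the
#' family — instances by default; identical copies collapse when the
#' config's dedupe flag was set during annotation.
#'
#' @param annotation a `pepmine_annotation` (see [annotate_precursor()]).
#' @param family family label.
#' @return integer count.
#' @export
count_isoforms <- function(annotation, family) {
  sum(annotation$peptides$family == family)
}

#' Star-topology progressive multiple alignment
#'
#' Aligns every sequence globally to the centroid (the sequence with the
#' maximal summed pairwise alignment score; ties to the earlier input) and
#' merges the pairwise alignments column-wise, inserting shared gaps. Not a
#' guide-tree method: deterministic and adequate for short mature-peptide
#' families. Removing the gap characters of any row recovers its input.
#'
#' @param sequences character vector, length >= 2.
#' @inheritParams local_align
#' @return character matrix (one row per sequence, rownames from names or
#'   index) of single characters, `-` for gaps.
#' @export
progressive_msa <- function(sequences, matrix = "BLOSUM62",
                            gap_open = 11L, gap_extend = 1L) {
  n <- length(sequences)
  if (n < 2) abort("progressive_msa needs at least 2 sequences")
  ids <- names(sequences) %||% as.character(seq_len(n))
  scores <- base::matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- pairwise_align_global(sequences[i], sequences[j], matrix,
                               gap_open, gap_extend)$score
    scores[i, j] <- s; scores[j, i] <- s
  }
  centroid <- which.max(rowSums(scores))
  center <- sequences[[centroid]]
  L <- nchar(center)
  others <- setdiff(seq_len(n), centroid)
  alns <- lapply(others, function(k) {
    al <- pairwise_align_global(center, sequences[[k]], matrix,
                                gap_open, gap_extend)
    list(ca = strsplit(al$aln_a, "")[[1]], sa = strsplit(al$aln_b, "")[[1]])
  })
  # gaps_k[i + 1] = residues of sequence k inserted after center position i
  # (i = 0 means before the first center residue)
  gap_counts <- lapply(alns, function(al) {
    g <- integer(L + 1L)
    pos <- 0L
    for (c in seq_along(al$ca)) {
      if (al$ca[c] == "-") g[pos + 1L] <- g[pos + 1L] + 1L else pos <- pos + 1L
    }
    g
  })
  G <- if (length(gap_counts)) Reduce(pmax, gap_counts) else integer(L + 1L)
  # lay a pairwise alignment onto the merged column set; insertions are
  # left-aligned within their slot
  lay <- function(ca, sa) {
    out <- character()
    pos <- 0L
    slot <- character()
    flush <- function(slot, i) c(slot, rep("-", G[i + 1L] - length(slot)))
    for (c in seq_along(ca)) {
      if (ca[c] == "-") {
        slot <- c(slot, sa[c])
      } else {
        out <- c(out, flush(slot, pos), sa[c])
        slot <- character()
        pos <- pos + 1L
      }
    }
    c(out, flush(slot, pos))
  }
  center_chars <- strsplit(center, "")[[1]]
  rows <- vector("list", n)
  rows[[centroid]] <- lay(center_chars, center_chars)
  for (t in seq_along(others)) {
    rows[[others[t]]] <- lay(alns[[t]]$ca, alns[[t]]$sa)
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- ids
  mat
}

#' Write a multiple alignment
#'
#' Emits the matrix from [progressive_msa()] as aligned FASTA or
#' CLUSTAL-style text.
#'
#' @param msa character matrix from [progressive_msa()].
#' @param path output path.
#' @param format `"fasta"` or `"clustal"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  ids <- rownames(msa)
  seqs <- apply(msa, 1, paste0, collapse = "")
  if (format == "fasta") {
    write_fasta(tibble(id = ids, sequence = seqs), path)
  } else {
    wid <- max(nchar(ids)) + 3L
    lines <- c("CLUSTAL-style alignment (pepmine)", "",
               paste0(formatC(ids, width = -wid), seqs))
    writeLines(lines, path)
  }
  invisible(path)
}
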