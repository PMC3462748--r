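#' Extract the precursor ORF supporting a hit
#'
#' Takes the maximal stop-to-stop segment of the hit's reading frame that
#' contains the hit span, trims it to start at the first Met upstream of the
#' hit (if any), and returns the candidate protein. When the segment holds
#' no Met upstream of the hit the segment start is used and the candidate is
#' flagged `no_start`.
#'
#' @param hit one-row tibble from [mine_transcriptome()].
#' @param transcript matching transcript row (`id`, `sequence`).
#' @return list of class `pepmine_candidate`: `transcript_id`, `frame`,
#'   `protein`, `prot_start` (1-based residue offset of the protein on the
#'   frame translation), `no_start`, `supporting_hits`,
#'   `rare_confirmed` (RACE-style confirmation metadata, never computed).
#' @export
find_orf <- function(hit, transcript) {
  stopifnot(hit$transcript_id == transcript$id)
  tr <- six_frame_translate(transcript$sequence, transcript$id)
  pep <- tr$peptide[tr$frame == hit$frame]
  stops <- c(0L, which(strsplit(pep, "")[[1]] == "*"), nchar(pep) + 1L)
  seg_start <- max(stops[stops < hit$sstart]) + 1L
  seg_end <- min(stops[stops > hit$send]) - 1L
  if (seg_start > hit$sstart || seg_end < hit$send) {
    abort("hit span crosses a stop codon; aligner contract violated")
  }
  seg <- substr(pep, seg_start, seg_end)
  mets <- which(strsplit(seg, "")[[1]] == "M")
  mets <- mets[mets <= (hit$sstart - seg_start + 1L)]
  no_start <- length(mets) == 0
  start <- if (no_start) seg_start else seg_start + min(mets) - 1L
  structure(list(
    transcript_id = transcript$id, frame = hit$frame,
    protein = substr(pep, start, seg_end),
    prot_start = start, no_start = no_start,
    supporting_hits = hit$query_id, rare_confirmed = NA
  ), class = "pepmine_candidate")
}

HYDROPHOBIC <- c("A", "I", "L", "M", "F", "V", "W", "C")
SMALL_CLEAV <- c("A", "G", "S", "C", "T", "V")

#' Heuristic signal peptide prediction
#'
#' A transparent von-Heijne-style stand-in for neural-network predictors:
#' a signal peptide is called when (i) some 8-residue window within
#' positions 2-30 holds at least 6 hydrophobic residues (A I L M F V W C),
#' and (ii) a cleavage position c in 10-40 satisfies the (-3,-1) small-
#' residue rule, i.e. residues c and c-2 are both in {A G S C T V}. The
#' cleavage point is the smallest such c at or after the end of the best
#' hydrophobic window; the score is that window's hydrophobic fraction.
#'
#' @param protein amino-acid string, length >= 15 for a meaningful call.
#' @return tibble: `present`, `cleavage_after` (0 when absent), `score`.
#' @export
predict_signal_peptide <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  none <- tibble(present = FALSE, cleavage_after = 0L, score = 0)
  if (n < 15) return(none)
  hyd <- aa %in% HYDROPHOBIC
  win_starts <- 2:min(23L, n - 7L)       # window fits within positions 2-30
  if (length(win_starts) == 0 || win_starts[1] > n - 7L) return(none)
  counts <- vapply(win_starts, function(s) sum(hyd[s:(s + 7L)]), integer(1))
  if (max(counts) < 6L) return(none)
  core_start <- win_starts[which.max(counts)]
  core_end <- core_start + 7L
  c_lo <- max(10L, core_end)
  c_hi <- min(40L, n - 1L)
  if (c_lo > c_hi) return(none)
  small <- aa %in% SMALL_CLEAV
  ok <- which(small[c_lo:c_hi] & small[(c_lo:c_hi) - 2L])
  if (length(ok) == 0) return(none)
  tibble(present = TRUE, cleavage_after = as.integer(c_lo + ok[1] - 1L),
         score = max(counts) / 8)
}

#' Predict prohormone convertase cleavage sites
#'
#' Operational reading of the classical dibasic/monobasic processing rules,
#' scanned C-terminal of the signal peptide:
#' (a) dibasic KR and RR always accepted; (b) RK / KK only when toggled on;
#' (c) a single R accepted when another K/R sits at relative position -4,
#' -6 or -8; (d) runs of 3+ consecutive K/R accepted as one multibasic site
#' at the run's last residue; (e) any site immediately followed by Pro is
#' rejected. Overlaps resolve in favour of the longer site. Each toggle is
#' independently switchable via the config.
#'
#' @param protein amino-acid string.
#' @param signal_end last residue of the signal peptide (0 for none);
#'   must be < nchar(protein).
#' @param cfg a [pipeline_config()].
#' @return tibble of accepted sites, sorted by position: `position` (last
#'   residue of the site, 1-based), `length` (residues spanned),
#'   `site_type` (KR, RR, RK, KK, mono_R, multibasic), `rule`.
#' @export
find_cleavage_sites <- function(protein, signal_end = 0L,
                                cfg = pipeline_config()) {
  n <- nchar(protein)
  if (signal_end >= n) abort("`signal_end` must be < protein length")
  aa <- strsplit(protein, "")[[1]]
  basic <- aa %in% c("K", "R")
  out <- list()
  i <- signal_end + 1L
  while (i <= n) {
    if (!basic[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && basic[j + 1L]) j <- j + 1L
    run_len <- j - i + 1L
    followed_by_P <- (j < n) && aa[j + 1L] == "P"
    site <- NULL
    if (run_len >= 3L) {
      site <- list(position = j, length = run_len,
                   site_type = "multibasic", rule = "run>=3")
    } else if (run_len == 2L) {
      type <- paste0(aa[i], aa[j])
      ok <- type %in% c("KR", "RR") ||
        (type == "RK" && isTRUE(cfg$accept_RK)) ||
        (type == "KK" && isTRUE(cfg$accept_KK))
      if (ok) site <- list(position = j, length = 2L,
                           site_type = type, rule = "dibasic")
    } else if (aa[i] == "R") {
      up <- i - c(4L, 6L, 8L)
      up <- up[up >= 1L]
      if (any(basic[up])) {
        site <- list(position = i, length = 1L,
                     site_type = "mono_R", rule = "mono_R[-4/-6/-8]")
      }
    }
    if (!is.null(site) && !followed_by_P) out[[length(out) + 1L]] <- site
    i <- j + 1L
  }
  if (length(out) == 0) {
    return(tibble(position = integer(), length = integer(),
                  site_type = character(), rule = character()))
  }
  list_rbind(map(out, as_tibble)) |>
    mutate(position = as.integer(.data$position),
           length = as.integer(.data$length)) |>
    arrange(.data$position)
}

#' Screen a candidate by the three classical precursor criteria
#'
#' A candidate passes when it has a predicted signal peptide, at least one
#' accepted processing site after the signal, and is strictly shorter than
#' `cfg$max_precursor_len` residues.
#'
#' @param protein amino-acid string.
#' @param signal tibble from [predict_signal_peptide()].
#' @param sites tibble from [find_cleavage_sites()].
#' @param cfg a [pipeline_config()].
#' @return one-row tibble: `has_signal`, `under_length`,
#'   `has_processing_site`, `passed`.
#' @export
screen_precursor <- function(protein, signal, sites,
                             cfg = pipeline_config()) {
  has_signal <- isTRUE(signal$present)
  under_length <- nchar(protein) < cfg$max_precursor_len
  has_site <- nrow(sites) > 0 &&
    any(sites$position > (signal$cleavage_after %||% 0L))
  tibble(has_signal = has_signal, under_length = under_length,
         has_processing_site = has_site,
         passed = has_signal && under_length && has_site)
}

#' Excise raw peptide segments between processing sites
#'
#' Segments are the maximal stretches strictly between the signal peptide
#' end, the accepted site residues, and the precursor end; site residues
#' are excluded and empty segments dropped. Concatenating signal, sites and
#' segments in order reconstructs the precursor exactly.
#'
#' @inheritParams screen_precursor
#' @param signal_end last residue of the signal peptide (0 for none).
#' @return tibble: `start`, `end` (1-based inclusive on the precursor),
#'   `sequence`.
#' @export
excise_peptides <- function(protein, signal_end = 0L, sites = NULL) {
  n <- nchar(protein)
  if (is.null(sites) || nrow(sites) == 0) {
    bounds <- tibble(position = integer(), length = integer())
  } else {
    bounds <- sites
  }
  cut_start <- c(signal_end + 1L, bounds$position + 1L)
  cut_end <- c(bounds$position - bounds$length, n)
  segs <- tibble(start = as.integer(cut_start), end = as.integer(cut_end)) |>
    filter(.data$end >= .data$start) |>
    mutate(sequence = str_sub(protein, .data$start, .data$end))
  segs
}

#' C-terminal amidation by the glycine-donor rule
#'
#' A segment ending in Gly is matured by removing that Gly; the preceding
#' residue carries the amide. Idempotent: at most one residue is removed.
#'
#' @param sequence raw excised segment.
#' @return one-row tibble: `sequence` (matured), `amidated`.
#' @export
apply_amidation <- function(sequence) {
  if (nchar(sequence) > 1 && endsWith(sequence, "G")) {
    tibble(sequence = substr(sequence, 1L, nchar(sequence) - 1L),
           amidated = TRUE)
  } else {
    tibble(sequence = sequence, amidated = FALSE)
  }
}

#' N-terminal pyroglutamate flag
#'
#' Flags peptides whose N-terminal residue can cyclize: Gln always, Glu when
#' `cfg$pyroglu_E` is on. The stored sequence is never altered.
#'
#' @param sequence mature peptide sequence.
#' @param cfg a [pipeline_config()].
#' @return logical flag.
#' @export
apply_pyroglu <- function(sequence, cfg = pipeline_config()) {
  first <- substr(sequence, 1L, 1L)
  first == "Q" || (isTRUE(cfg$pyroglu_E) && first == "E")
}

#' Acidic-context tyrosine sulfation prediction
#'
#' A Tyr is flagged as sulfated when at least `cfg$sulfation_acidic_min`
#' acidic residues (D/E) occur within +/- `cfg$sulfation_window` positions
#' (window clipped at the peptide ends).
#'
#' @param sequence mature peptide sequence.
#' @param cfg a [pipeline_config()].
#' @return integer vector of 1-based Tyr positions flagged as sulfated.
#' @export
predict_sulfation <- function(sequence, cfg = pipeline_config()) {
  aa <- strsplit(sequence, "")[[1]]
  ys <- which(aa == "Y")
  if (length(ys) == 0) return(integer())
  w <- cfg$sulfation_window
  keep <- vapply(ys, function(i) {
    lo <- max(1L, i - w); hi <- min(length(aa), i + w)
    sum(aa[lo:hi] %in% c("D", "E")) >= cfg$sulfation_acidic_min
  }, logical(1))
  as.integer(ys[keep])
}

#' Full annotation of one precursor protein
#'
#' Composes the annotation chain: signal peptide, cleavage sites, screening
#' verdict, excision, and per-peptide PTMs plus family-motif assignment.
#'
#' @param protein amino-acid string.
#' @param precursor_id identifier used in the peptide table.
#' @param cfg a [pipeline_config()].
#' @param motifs motif pattern tibble (see [default_motifs()]); NULL skips
#'   family assignment.
#' @param homology_family fallback family label applied to peptides with no
#'   motif match (the by-homology route used when mining supplied a family).
#' @return list of class `pepmine_annotation`: `precursor_id`, `protein`,
#'   `signal`, `sites`, `screen`, `peptides` (tibble with precursor_id,
#'   peptide_index, start, end, sequence, amidated, pyroglu,
#'   sulfated_positions (list), family, display).
#' @export
annotate_precursor <- function(protein, precursor_id = "precursor",
                               cfg = pipeline_config(),
                               motifs = default_motifs(),
                               homology_family = "unknown") {
  signal <- predict_signal_peptide(protein)
  se <- if (signal$present) signal$cleavage_after else 0L
  sites <- find_cleavage_sites(protein, se, cfg)
  screen <- screen_precursor(protein, signal, sites, cfg)
  segs <- excise_peptides(protein, se, sites)
  peptides <- annotate_segments(segs, precursor_id, cfg, motifs,
                                homology_family)
  structure(list(precursor_id = precursor_id, protein = protein,
                 signal = signal, sites = sites, screen = screen,
                 peptides = peptides),
            class = "pepmine_annotation")
}

annotate_segments <- function(segs, precursor_id, cfg, motifs,
                              homology_family) {
  if (nrow(segs) == 0) return(empty_peptides())
  rows <- map(seq_len(nrow(segs)), function(k) {
    am <- apply_amidation(segs$sequence[k])
    pg <- apply_pyroglu(am$sequence, cfg)
    su <- predict_sulfation(am$sequence, cfg)
    fam <- if (is.null(motifs)) NA_character_ else {
      m <- match_motif(am$sequence, am$amidated, motifs)
      if (is.null(m)) NA_character_ else m$family
    }
    if (is.na(fam)) fam <- homology_family
    end <- segs$start[k] + nchar(am$sequence) - 1L
    disp <- paste0(if (pg) "pQ" else "", am$sequence,
                   if (am$amidated) "-NH2" else "")
    tibble(precursor_id = precursor_id, peptide_index = k,
           start = segs$start[k], end = as.integer(end),
           sequence = am$sequence, amidated = am$amidated, pyroglu = pg,
           sulfated_positions = list(su), family = fam, display = disp)
  }) |> list_rbind()
  if (isTRUE(cfg$dedupe_peptides)) {
    rows <- rows |> distinct(.data$sequence, .keep_all = TRUE) |>
      mutate(peptide_index = row_number())
  }
  rows
}

empty_peptides <- function() {
  tibble(precursor_id = character(), peptide_index = integer(),
         start = integer(), end = integer(), sequence = character(),
         amidated = logical(), pyroglu = logical(),
         sulfated_positions = list(), family = character(),
         display = character())
}
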