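test_that("six-frame translation follows the standard code", {
  tr <- six_frame_translate("ATGAAACGT", "t")
  expect_equal(tr$peptide[tr$frame == 1], "MKR")
  expect_equal(nrow(tr), 6)
  expect_setequal(tr$frame, c(1:3, -1:-3))

  # a coding sequence planted on the reverse strand shows up in frame -1
  cds <- "ATGGATTTCGAAATC"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  tr2 <- six_frame_translate(rc, "t2")
  expect_equal(tr2$peptide[tr2$frame == -1], "MDFEI")

  # degenerate inputs yield empty translations, not errors
  tiny <- six_frame_translate("AT", "t3")
  expect_equal(nrow(tiny), 6)
  expect_true(all(tiny$peptide == ""))

  # N-containing codons translate to X
  trn <- six_frame_translate("ATGANACGT", "t4")
  expect_equal(trn$peptide[trn$frame == 1], "MXR")
})

test_that("all six frames agree with an independent translation oracle", {
  set.seed(11)
  for (rep in 1:5) {
    nt <- random_nt_str(300)
    tr <- six_frame_translate(nt, "r")
    fwd <- seqinr::s2c(nt)
    rev <- seqinr::s2c(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(nt))))
    for (f in 0:2) {
      exp_f <- paste0(seqinr::translate(fwd, frame = f), collapse = "")
      exp_r <- paste0(seqinr::translate(rev, frame = f), collapse = "")
      expect_equal(tr$peptide[tr$frame == f + 1], exp_f)
      expect_equal(tr$peptide[tr$frame == -(f + 1)], exp_r)
    }
  }
})

test_that("frame coordinates map back to the transcript", {
  nt <- "AAATGGATTTCGA"   # 13 nt
  tr <- six_frame_translate(nt, "t")
  # frame +2 residue 2: codon at nt 5-7
  span <- frame_to_nt(2L, nchar(nt), 2L)
  codon <- substr(nt, span$nt_start, span$nt_end)
  expect_equal(as.character(Biostrings::translate(
    Biostrings::DNAString(codon))), substr(tr$peptide[tr$frame == 2], 2, 2))
  # reverse frame -1 residue 1: last three forward-strand bases
  span2 <- frame_to_nt(-1L, nchar(nt), 1L)
  expect_equal(c(span2$nt_start, span2$nt_end), c(11L, 13L))
})

test_that("local alignment scores published-matrix identities and floors", {
  # KRNSE vs itself: sum of BLOSUM62 diagonal entries 5+5+6+4+5
  r <- local_align("KRNSE", "KRNSE")
  expect_equal(r$score, 25L)
  expect_equal(r$qaln, "KRNSE")
  expect_equal(r$saln, "KRNSE")
  expect_equal(c(r$qstart, r$qend, r$sstart, r$send), c(1L, 5L, 1L, 5L))

  # no positive substitution pairs -> empty alignment at score 0
  r0 <- local_align("WWWW", "PPPP")
  expect_equal(r0$score, 0L)
  expect_equal(r0$qaln, "")

  expect_error(local_align("", "AAA"), "non-empty")
  expect_error(local_align("AAA", "AAA", matrix = "PAM30"), "unknown")
})

test_that("local and global optima equal the brute-force DP oracle", {
  set.seed(42)
  for (case in 1:120) {
    q <- random_protein(sample(1:20, 1))
    s <- random_protein(sample(1:20, 1))
    expect_equal(local_align(q, s)$score,
                 oracle_align_score(q, s, type = "local"),
                 info = paste(q, s))
    expect_equal(pairwise_align_global(q, s)$score,
                 oracle_align_score(q, s, type = "global"),
                 info = paste(q, s))
  }
})

test_that("alignment scores agree with Biostrings' implementation", {
  set.seed(43)
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  for (case in 1:40) {
    q <- random_protein(sample(5:25, 1))
    s <- random_protein(sample(5:25, 1))
    ours <- local_align(q, s)$score
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(q), Biostrings::AAString(s),
      substitutionMatrix = env$BLOSUM62, gapOpening = 11, gapExtension = 1,
      type = "local", scoreOnly = TRUE)
    expect_equal(ours, as.integer(max(ref, 0)), info = paste(q, s))
  }
})

test_that("alignments never cross a stop codon", {
  # planted matches on both sides of a stop: best side wins, coordinates
  # stay on the full frame translation
  q <- "MKWVNDE"
  subj <- paste0("AAA", "MKWVND", "*", "MKWVNDE", "AAA")
  r <- local_align(q, subj)
  expect_equal(r$score, local_align(q, "MKWVNDE")$score)
  expect_equal(r$sstart, 11L)  # after the stop at position 10
  expect_equal(r$send, 17L)
  expect_false(grepl("\\*", r$saln))
})

test_that("Karlin-Altschul statistics behave as the closed form requires", {
  expect_error(evalue(10, 0, 100), "positive")
  # linear in database size
  expect_equal(evalue(50, 10, 2e5), 2 * evalue(50, 10, 1e5))
  # strictly decreasing in score, approaching zero
  scores <- seq(10, 300, by = 10)
  es <- evalue(scores, 20, 1e6)
  expect_true(all(diff(es) < 0))
  expect_lt(es[length(es)], 1e-20)
  # closed-form grid at the published gapped BLOSUM62 constants
  for (s in c(20, 57, 113)) {
    expect_equal(evalue(s, 15, 3e5),
                 0.041 * 15 * 3e5 * exp(-0.267 * s))
  }
  expect_equal(bit_score(100), (0.267 * 100 - log(0.041)) / log(2))
})

test_that("mining recovers a planted coding sequence as the top hit", {
  spec <- precursor_spec("PDH",
    tibble::tibble(sequence = "NSELINSLLGLPKIMNEA", amidate = TRUE),
    spacer_len = 8L)
  tx <- generate_transcriptome(list(spec), n_decoys = 20, seed = 5)
  q <- reference_peptides("q_pdh", tx$proteins$protein[1], family = "PDH")
  hits <- mine_transcriptome(q, tx$transcripts)
  expect_gt(nrow(hits), 0)
  expect_equal(hits$transcript_id[1], "prec_PDH")
  expect_lt(hits$e_value[1], 0.01)
  expect_true(all(diff(hits$e_value) >= 0))
})

test_that("decoy-only searches return nothing at the E threshold", {
  tx <- generate_transcriptome(list(), n_decoys = 500, seed = 9)
  pdh_prec <- catalog_precursors()$protein[13]
  q <- reference_peptides("ref_PDH", pdh_prec, family = "PDH")
  hits <- mine_transcriptome(q, tx$transcripts)
  expect_equal(nrow(hits), 0)
})

test_that("top-k truncation and shuffle invariance hold", {
  spec <- precursor_spec("TRP",
    tibble::tibble(sequence = "APSGFLGMR", amidate = TRUE), spacer_len = 8L)
  one <- generate_transcriptome(list(spec), n_decoys = 0, seed = 3)
  # five transcripts all containing the query's coding sequence
  tx <- tibble::tibble(id = paste0("t", 1:5),
                       sequence = one$transcripts$sequence[1])
  q <- reference_peptides("q", one$proteins$protein[1], family = "TRP")
  hits <- mine_transcriptome(q, tx)
  expect_equal(nrow(hits), 3)  # default top_k
  hits5 <- mine_transcriptome(q, tx, pipeline_config(top_k = 10))
  expect_equal(nrow(hits5), 5)

  # shuffling transcript order leaves the hit set unchanged
  set.seed(1)
  shuf <- tx[sample(nrow(tx)), ]
  h2 <- mine_transcriptome(q, shuf)
  expect_setequal(paste(h2$transcript_id, h2$raw_score),
                  paste(hits$transcript_id, hits$raw_score))
})

test_that("hits sorted by score are sorted by E-value, and the outfmt table writes", {
  tx <- generate_transcriptome(catalog_specs()[c("PDH", "SIF", "TRP")],
                               n_decoys = 0, seed = 2)
  refs <- catalog_references()[13:16, ]
  hits <- mine_transcriptome(refs, tx$transcripts)
  by_q <- split(hits, hits$query_id)
  for (h in by_q) {
    expect_true(all(diff(h$e_value) >= 0))
    expect_true(all(diff(h$raw_score) <= 0))
  }
  out <- tempfile(fileext = ".tsv")
  write_hits_table(hits, out)
  tab <- readr::read_tsv(out, col_names = FALSE, show_col_types = FALSE)
  expect_equal(nrow(tab), nrow(hits))
  expect_equal(ncol(tab), 13)
})
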