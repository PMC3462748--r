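test_that("ORF extraction starts at the first Met and respects stops", {
  # hand-built transcript: UTR + in-frame stop + ATG...CDS...stop + UTR
  prot <- "MKWNDELFS"
  cds <- "ATGAAATGGAACGACGAACTGTTCTCC"
  nt <- paste0("AAAC", "TAA", cds, "TGA", "CCCC")
  tx <- tibble::tibble(id = "t1", sequence = nt)
  q <- reference_peptides("q1", prot)
  hits <- mine_transcriptome(q, tx, pipeline_config(e_threshold = 100))
  cand <- find_orf(hits[1, ], tx)
  expect_equal(cand$protein, prot)
  expect_false(cand$no_start)

  # no Met upstream: candidate starts at the segment boundary, flagged
  prot2 <- "WNDELFSWNDELFS"
  cds2 <- paste0("TGGAACGACGAACTGTTCTCC", "TGGAACGACGAACTGTTCTCC")
  nt2 <- paste0("AAAC", "TAA", cds2, "TGA", "CCCC")
  tx2 <- tibble::tibble(id = "t2", sequence = nt2)
  hits2 <- mine_transcriptome(reference_peptides("q2", prot2), tx2,
                              pipeline_config(e_threshold = 100))
  cand2 <- find_orf(hits2[1, ], tx2)
  expect_equal(cand2$protein, prot2)
  expect_true(cand2$no_start)
})

test_that("planted ORFs are recovered exactly across random transcripts", {
  for (i in 1:10) {
    spec <- random_spec()
    tx <- generate_transcriptome(list(spec), n_decoys = 0, seed = 100 + i)
    q <- reference_peptides("q", tx$proteins$protein[1])
    hits <- mine_transcriptome(q, tx$transcripts)
    cand <- find_orf(hits[1, ], tx$transcripts[1, ])
    expect_equal(cand$protein, tx$proteins$protein[1], info = i)
  }
})

test_that("signal peptide heuristic needs a hydrophobic core and small (-3,-1)", {
  # charged N-terminus: no core, no signal
  sig0 <- predict_signal_peptide(
    paste0("MDDDDEEEEDDDDEEEEDDDDEEEE", "SSSS"))
  expect_false(sig0$present)

  # constructed signal: core then Ala-Leu-Ala; rule recovers the exact end
  p <- paste0("MK", strrep("L", 12), "ALA", "QFDDSTNEEDAAA")
  sig <- predict_signal_peptide(p)
  expect_true(sig$present)
  expect_equal(sig$cleavage_after, 17L)
  expect_gte(sig$score, 6 / 8)
  # the called end satisfies the small-residue rule
  small <- c("A", "G", "S", "C", "T", "V")
  aa <- strsplit(p, "")[[1]]
  expect_true(aa[sig$cleavage_after] %in% small)
  expect_true(aa[sig$cleavage_after - 2] %in% small)

  # too short for a call
  expect_false(predict_signal_peptide("MKLLLVLA")$present)
})

test_that("generator-planted signals are recovered at their exact ends", {
  hits <- 0L
  for (i in 1:200) {
    gp <- generate_precursor(random_spec(), seed = 1000 + i)
    sig <- predict_signal_peptide(gp$protein)
    if (isTRUE(sig$present) &&
        abs(sig$cleavage_after - gp$truth$signal_end) <= 2) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / 200, 0.95)
})

test_that("cleavage rules fire exactly as specified", {
  cfg <- pipeline_config()
  # (a) dibasic KR after a signal
  p1 <- paste0(strrep("A", 19), "KR", "SSSS")
  s1 <- find_cleavage_sites(p1, 16L, cfg)
  expect_equal(s1$position, 21L)
  expect_equal(s1$site_type, "KR")

  # (b) RK/KK off by default, on by toggle
  p2 <- paste0(strrep("A", 19), "RK", "SSSS", "KK", "SSSS")
  expect_equal(nrow(find_cleavage_sites(p2, 16L, cfg)), 0)
  s2 <- find_cleavage_sites(p2, 16L,
                            pipeline_config(accept_RK = TRUE,
                                            accept_KK = TRUE))
  expect_equal(s2$site_type, c("RK", "KK"))

  # (c) mono R needs K/R at -4, -6 or -8
  p3 <- paste0(strrep("A", 16), "KAAAR", "NNNN")        # K at -4
  s3 <- find_cleavage_sites(p3, 16L, cfg)
  expect_equal(s3$site_type, "mono_R")
  expect_equal(s3$position, 21L)
  p4 <- paste0(strrep("A", 16), "AAAAR", "NNNN")        # no upstream basic
  expect_equal(nrow(find_cleavage_sites(p4, 16L, cfg)), 0)
  # exhaustive over offsets: only -4/-6/-8 license the site
  for (off in 2:9) {
    pp <- paste0(strrep("A", 16), "K", strrep("A", off - 1L), "R", "NNNN")
    got <- find_cleavage_sites(pp, 16L, cfg)
    if (off %in% c(4, 6, 8)) {
      expect_equal(got$site_type, "mono_R", info = off)
    } else {
      expect_equal(nrow(got), 0, info = off)
    }
  }

  # (d) runs of >= 3 basics collapse into one multibasic site
  p5 <- paste0(strrep("A", 16), "KRR", "SSSS")
  s5 <- find_cleavage_sites(p5, 16L, cfg)
  expect_equal(s5$site_type, "multibasic")
  expect_equal(s5$position, 19L)
  expect_equal(s5$length, 3L)

  # (e) Pro immediately after kills any site
  p6 <- paste0(strrep("A", 16), "KR", "PSSS")
  expect_equal(nrow(find_cleavage_sites(p6, 16L, cfg)), 0)
  p7 <- paste0(strrep("A", 16), "KAAAR", "PNNN")
  expect_equal(nrow(find_cleavage_sites(p7, 16L, cfg)), 0)

  expect_error(find_cleavage_sites("AAAA", 4L), "signal_end")
})

test_that("three-criteria screen enforces the strict length boundary", {
  cfg <- pipeline_config()
  sig <- tibble::tibble(present = TRUE, cleavage_after = 16L, score = 1)
  sites <- tibble::tibble(position = 30L, length = 2L,
                          site_type = "KR", rule = "dibasic")
  p299 <- random_protein(299)
  p300 <- random_protein(300)
  expect_true(screen_precursor(p299, sig, sites, cfg)$passed)
  r300 <- screen_precursor(p300, sig, sites, cfg)
  expect_false(r300$passed)
  expect_false(r300$under_length)
  expect_true(r300$has_signal)

  # no accepted sites: conjunction fails
  empty <- find_cleavage_sites(strrep("A", 40), 16L, cfg)
  expect_false(screen_precursor(p299, sig, empty, cfg)$passed)
  # removing the signal can only flip passed to false (monotonicity)
  nosig <- tibble::tibble(present = FALSE, cleavage_after = 0L, score = 0)
  expect_false(screen_precursor(p299, nosig, sites, cfg)$passed)
})

test_that("excision tiles the precursor and conserves every residue", {
  # two segments of length 4 around one dibasic site
  p <- paste0(strrep("M", 16), "DDDD", "KR", "NNNN")
  sites <- tibble::tibble(position = 22L, length = 2L, site_type = "KR",
                          rule = "dibasic")
  segs <- excise_peptides(p, 16L, sites)
  expect_equal(segs$sequence, c("DDDD", "NNNN"))
  expect_equal(segs$start, c(17L, 23L))

  # no sites: one segment, everything after the signal
  segs2 <- excise_peptides(p, 16L, NULL)
  expect_equal(segs2$sequence, substr(p, 17, nchar(p)))

  # conservation property over random precursors
  for (i in 1:60) {
    gp <- generate_precursor(random_spec(), seed = 3000 + i)
    prot <- gp$protein
    sites_i <- find_cleavage_sites(prot, gp$truth$signal_end)
    segs_i <- excise_peptides(prot, gp$truth$signal_end, sites_i)
    rebuilt <- character(nchar(prot))
    rebuilt[seq_len(gp$truth$signal_end)] <-
      strsplit(substr(prot, 1, gp$truth$signal_end), "")[[1]]
    for (k in seq_len(nrow(sites_i))) {
      span <- (sites_i$position[k] - sites_i$length[k] + 1L):sites_i$position[k]
      rebuilt[span] <- strsplit(substr(prot, span[1],
                                       sites_i$position[k]), "")[[1]]
    }
    for (k in seq_len(nrow(segs_i))) {
      span <- segs_i$start[k]:segs_i$end[k]
      rebuilt[span] <- strsplit(segs_i$sequence[k], "")[[1]]
    }
    expect_equal(paste0(rebuilt, collapse = ""), prot, info = i)
  }
})

test_that("amidation strips one Gly, once", {
  r <- apply_amidation("NSELINSLLGLPKIMNEAG")
  expect_equal(r$sequence, "NSELINSLLGLPKIMNEA")
  expect_true(r$amidated)
  r2 <- apply_amidation("ADEF")
  expect_equal(r2$sequence, "ADEF")
  expect_false(r2$amidated)
  # idempotent: a second application removes nothing more
  r3 <- apply_amidation(r$sequence)
  expect_false(r3$amidated)
  expect_equal(r3$sequence, r$sequence)
  # double Gly donates only the last
  expect_equal(apply_amidation("ADEFGG")$sequence, "ADEFG")
})

test_that("pyroglutamate flag follows the N-terminal residue and toggle", {
  expect_true(apply_pyroglu("QVRF"))
  expect_false(apply_pyroglu("AVRF"))
  expect_false(apply_pyroglu("EVRF"))
  expect_true(apply_pyroglu("EVRF", pipeline_config(pyroglu_E = TRUE)))
})

test_that("sulfation needs two acidic residues around the Tyr", {
  cfg <- pipeline_config()
  # hand count: Y at 9 of GGDDQFDDYGHMRF has D at 7, 8 (and 3, 4 outside +-5)
  expect_equal(predict_sulfation("GGDDQFDDYGHMRF", cfg), 9L)
  expect_equal(predict_sulfation("AAAYAAA", cfg), integer())
  expect_equal(predict_sulfation("GGMMQFMM", cfg), integer())
  # window clipping at the peptide edge still counts correctly
  expect_equal(predict_sulfation("YDE", cfg), 1L)
  # threshold is configurable
  expect_equal(predict_sulfation("AADYAAA",
                                 pipeline_config(sulfation_acidic_min = 1)),
               4L)
})

test_that("end-to-end annotation reproduces planted PTM triples", {
  for (i in 1:25) {
    gp <- generate_precursor(random_spec(), seed = 5000 + i)
    ann <- annotate_precursor(gp$protein, "p", motifs = NULL)
    expect_equal(ann$signal$cleavage_after, gp$truth$signal_end, info = i)
    got <- ann$peptides[, c("sequence", "amidated", "pyroglu")]
    want <- gp$truth$peptides[, c("sequence", "amidated", "pyroglu")]
    expect_equal(as.data.frame(got), as.data.frame(want), info = i)
  }
})
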