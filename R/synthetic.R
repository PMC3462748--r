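#' Run code under a temporary RNG seed
#'
#' All generators are pure functions of (spec, seed): they set the seed
#' locally and restore the caller's RNG state afterwards.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 7919) %% 2147483629)
}

#' Build a precursor specification
#'
#' Describes the architecture of one synthetic preprohormone: an N-terminal
#' signal peptide, an optional acidic propeptide spacer, and ordered peptide
#' payloads joined by basic processing sites. Amidated payloads get the
#' C-terminal Gly donor appended at assembly.
#'
#' @param family family label.
#' @param payloads tibble with `sequence` and `amidate` columns (or a
#'   character vector, taken as non-amidated).
#' @param sites site types between consecutive payloads, recycled
#'   (`"KR"`, `"RR"`); also used after the spacer.
#' @param signal_len signal peptide length (residues) or NULL to sample
#'   16-25 at generation.
#' @param spacer_len length of the acidic spacer between signal and first
#'   payload; 0 for none. A spacer is followed by its own site.
#' @param utr5,utr3 untranslated flank lengths (nt) used at transcript
#'   assembly.
#' @return list of class `pepmine_spec`.
#' @export
precursor_spec <- function(family, payloads, sites = "KR",
                           signal_len = NULL, spacer_len = 0L,
                           utr5 = 30L, utr3 = 30L) {
  if (is.character(payloads)) {
    payloads <- tibble(sequence = payloads, amidate = FALSE)
  }
  stopifnot(nrow(payloads) >= 1,
            all(grepl(alphabet_regex("protein"), payloads$sequence)))
  structure(list(family = family, payloads = payloads, sites = sites,
                 signal_len = signal_len, spacer_len = as.integer(spacer_len),
                 utr5 = as.integer(utr5), utr3 = as.integer(utr3)),
            class = "pepmine_spec")
}

# Signal construction guarantees the heuristic predictor recovers its exact
# end: Met + Lys + a hydrophobic core drawn from {L,I,F,M,W} (none of which
# are small-cleavage residues) + Ala-Leu-Ala, so positions (c-2, c) first
# satisfy the (-3,-1) small-residue rule at the true end.
make_signal <- function(len) {
  stopifnot(len >= 16, len <= 30)
  core <- sample(c("L", "I", "F", "M", "W"), len - 5L, replace = TRUE)
  paste0("M", "K", paste0(core, collapse = ""), "ALA")
}

SPACER_ALPHABET <- c("D", "E", "N", "S", "A")

make_spacer <- function(len) {
  paste0(sample(SPACER_ALPHABET, len, replace = TRUE), collapse = "")
}

#' Generate one synthetic precursor with ground truth
#'
#' Assembles signal + (spacer + site) + payload1 + site + payload2 ... with
#' the Gly amidation donor appended to amidated payloads, then verifies
#' self-consistency: the annotation chain applied to the protein must
#' reproduce the planted signal end, sites, and mature peptide set.
#'
#' @param spec a [precursor_spec()].
#' @param seed integer seed (signal core and spacer are random).
#' @return list: `protein`, `truth` (list: family, signal_end, sites tibble,
#'   peptides tibble with sequence/amidated/pyroglu/sulfated_positions/
#'   is_spacer, spacer).
#' @export
generate_precursor <- function(spec, seed = 1L) {
  with_seed(seed, {
    slen <- spec$signal_len %||% sample(16:25, 1)
    signal <- make_signal(slen)
    np <- nrow(spec$payloads)
    n_sites <- (np - 1L) + (spec$spacer_len > 0L)
    site_types <- rep(spec$sites, length.out = max(n_sites, 1L))
    if (n_sites == 0L) site_types <- character()
    spacer <- if (spec$spacer_len > 0L) make_spacer(spec$spacer_len) else ""

    elements <- character()   # raw excisable segments in order
    if (nzchar(spacer)) elements <- c(elements, spacer)
    payload_raw <- ifelse(spec$payloads$amidate,
                          paste0(spec$payloads$sequence, "G"),
                          spec$payloads$sequence)
    elements <- c(elements, payload_raw)

    protein <- signal
    sites <- tibble(position = integer(), length = integer(),
                    site_type = character())
    for (k in seq_along(elements)) {
      protein <- paste0(protein, elements[k])
      if (k < length(elements)) {
        st <- site_types[k]
        protein <- paste0(protein, st)
        sites <- bind_rows(sites, tibble(
          position = nchar(protein), length = nchar(st), site_type = st))
      }
    }

    cfg <- pipeline_config()
    peptides <- list_rbind(map(seq_len(np), function(k) {
      am <- apply_amidation(payload_raw[k])
      tibble(sequence = am$sequence,
             amidated = am$amidated,
             pyroglu = apply_pyroglu(am$sequence, cfg),
             sulfated_positions = list(predict_sulfation(am$sequence, cfg)),
             is_spacer = FALSE)
    }))
    if (nzchar(spacer)) {
      peptides <- bind_rows(
        tibble(sequence = spacer, amidated = FALSE,
               pyroglu = apply_pyroglu(spacer, cfg),
               sulfated_positions = list(predict_sulfation(spacer, cfg)),
               is_spacer = TRUE),
        peptides)
    }
    truth <- list(family = spec$family, signal_end = nchar(signal),
                  sites = sites, peptides = peptides, spacer = spacer)
    validate_precursor(protein, truth)
    list(protein = protein, truth = truth)
  })
}

# Self-consistency: the annotation rules must reproduce the planted
# structure; a spec whose payloads collide with the cleavage rules
# (e.g. an internal accepted site) is an error at generation time.
validate_precursor <- function(protein, truth) {
  sig <- predict_signal_peptide(protein)
  if (!isTRUE(sig$present) || sig$cleavage_after != truth$signal_end) {
    abort(paste0("generated precursor is not self-consistent: planted ",
                 "signal end ", truth$signal_end, ", predicted ",
                 if (sig$present) sig$cleavage_after else "absent"))
  }
  sites <- find_cleavage_sites(protein, truth$signal_end)
  if (!identical(sites$position, truth$sites$position) ||
      !identical(sites$length, truth$sites$length)) {
    abort(paste0("generated precursor is not self-consistent: payloads ",
                 "collide with the cleavage rules (planted sites at ",
                 paste(truth$sites$position, collapse = ","),
                 ", found ", paste(sites$position, collapse = ","), ")"))
  }
  segs <- excise_peptides(protein, truth$signal_end, sites)
  mature <- map_chr(segs$sequence, function(s) apply_amidation(s)$sequence)
  if (!identical(mature, truth$peptides$sequence)) {
    abort("generated precursor is not self-consistent: peptide mismatch")
  }
  invisible(TRUE)
}

# codon table keyed by amino acid, from the standard genetic code
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

back_translate <- function(protein, codons) {
  aa <- strsplit(protein, "")[[1]]
  paste0(vapply(aa, function(a) {
    opts <- codons[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1)), collapse = "")
}

random_nt <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

#' Generate a synthetic transcriptome with ground truth
#'
#' Back-translates each precursor (uniform synonymous codon choice) and
#' embeds it between untranslated flanks, with an in-frame stop planted
#' immediately 5' of the start codon and the natural stop 3' of the coding
#' sequence, so ORF recovery is exact. Decoys are i.i.d. random nucleotide
#' sequences with the requested GC content and a length distribution
#' matched to the precursor transcripts.
#'
#' @param specs list of [precursor_spec()]s.
#' @param n_decoys number of decoy transcripts (>= 0).
#' @param gc decoy GC fraction.
#' @param seed integer seed.
#' @return list: `transcripts` (tibble id/sequence), `truth` (named list per
#'   precursor id: protein + planted structure), `proteins` (tibble
#'   id/family/protein).
#' @export
generate_transcriptome <- function(specs, n_decoys = 0L, gc = 0.5,
                                   seed = 1L) {
  stopifnot(n_decoys >= 0)
  codons <- codons_by_aa()
  recs <- map(seq_along(specs), function(i) {
    sp <- specs[[i]]
    gp <- generate_precursor(sp, derive_seed(seed, i))
    with_seed(derive_seed(seed, i) + 1L, {
      cds <- back_translate(gp$protein, codons)
      stopc <- sample(c("TAA", "TAG", "TGA"), 1)
      seqn <- paste0(random_nt(sp$utr5, gc), "TAA", cds, stopc,
                     random_nt(sp$utr3, gc))
      id <- paste0("prec_", sp$family)
      list(id = id, sequence = seqn, protein = gp$protein, truth = gp$truth)
    })
  })
  transcripts <- tibble(id = map_chr(recs, "id"),
                        sequence = map_chr(recs, "sequence"))
  lens <- nchar(transcripts$sequence)
  decoys <- with_seed(derive_seed(seed, 0L), {
    if (n_decoys > 0) {
      dl <- if (length(lens)) lens[sample.int(length(lens), n_decoys,
                                              replace = TRUE)]
            else rep(600L, n_decoys)
      tibble(id = sprintf("decoy_%04d", seq_len(n_decoys)),
             sequence = map_chr(dl, random_nt, gc = gc))
    } else {
      tibble(id = character(), sequence = character())
    }
  })
  truth <- setNames(map(recs, function(r) {
    c(list(protein = r$protein), r$truth)
  }), map_chr(recs, "id"))
  list(transcripts = bind_rows(transcripts, decoys),
       truth = truth,
       proteins = tibble(id = map_chr(recs, "id"),
                         family = map_chr(recs, function(r) r$truth$family),
                         protein = map_chr(recs, "protein")))
}

#' Write generator ground truth as JSON
#'
#' @param truth the `truth` element of [generate_transcriptome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Synthetic precursor catalog
# ---------------------------------------------------------------------------

#' Synthetic neuropeptide precursor catalog
#'
#' A fully synthetic reconstruction of a barnacle-style neuropeptidome:
#' 16 precursor specifications (one per family/subfamily) that together
#' carry 64 mature peptides, with the structural statistics reported for
#' the catalog planted by construction — 22 FGLamide A-type allatostatins,
#' 10 B-type allatostatin isoforms, 4 tachykinin-related peptide copies,
#' 4 sulfakinins (including the Lys8 and Met6/Phe6 variants), 11 orcokinins
#' of 14 residues, the printed pigment-dispersing-hormone and C-type
#' allatostatin mature sequences, and an insulin-related B-C-A chain
#' precursor. Sequences other than the printed mature peptides are
#' synthetic stand-ins, not database entries; the catalog's orcokinin
#' variants carry Pro8 so the dibasic/monobasic rule set leaves each
#' 14-mer intact.
#'
#' @return named list of [precursor_spec()]s.
#' @export
catalog_specs <- function() {
  pay <- function(seqs, amidate) tibble(sequence = seqs, amidate = amidate)
  asta_prefix <- c("AP", "GQ", "SD", "NQ", "AS", "GD", "SQ", "ND",
                   "AQ", "GS", "SN", "NA", "AD", "GN", "SA", "NS",
                   "AG", "DQ", "SG", "NG", "AN", "DS")
  asta_core <- rep(c("YAFGL", "YSFGL", "FDFGL", "YNFGI"), length.out = 22)
  specs <- list(
    ASTA = precursor_spec("ASTA",
      pay(paste0(asta_prefix, asta_core), TRUE)),
    ASTB = precursor_spec("ASTB",
      pay(c("AWSNLGQAW", "NWNQLGSAW", "GWQDLNSAW", "AWSSMGNAW",
            "DWTNLGGAW", "NWDQIGNAW", "SWGELNAAW", "AWNNLHGAW",
            "GWSDLHSAW", "AWGQMNDAW"), TRUE)),
    ASTC = precursor_spec("ASTC", pay("SYWKQCSFNAVSCF", TRUE),
                          spacer_len = 10L),
    BurA = precursor_spec("BurA",
      pay(paste0("SEGCETTDMTVHILSYPGCTETSVHINTCSGACFSQSIPTPVDIYGNELH",
                 "TSCASCAPSQVSSVTVQLDC"), FALSE), spacer_len = 10L),
    BurB = precursor_spec("BurB",
      pay(paste0("SDECQVTPVIHVLSYPGCVPTPIPSFACQGSCTSYVQVSGSDIWQMEHSC",
                 "MCCQESGEWEYVTLELDC"), FALSE), spacer_len = 10L),
    CalciA = precursor_spec("CalciA",
      pay("SGLDLGLSRGFSGSQAAQHLMGLAAANYAGGP", TRUE), spacer_len = 10L),
    CalciB = precursor_spec("CalciB",
      pay("SNLDLGMSRGAWNSQAAQHFMGLTSGNYSGGP", TRUE), spacer_len = 10L),
    EH = precursor_spec("EH",
      pay(paste0("SNLSVDGISTVCMNNCAQCMSMFGDYFQGELCAESCIMNQDFAICLDSIQ",
                 "HTDEF"), FALSE), spacer_len = 10L),
    IRP = precursor_spec("IRP",
      pay(c("ASNFCGDLSSTLHLVCDNFN",
            "SQDTPVDALSELFNADQLQTW",
            "GIVDECCNNACTFDELASYCS"), FALSE)),
    ITP = precursor_spec("ITP",
      pay(paste0("SFFDIQCTGVYDTSIFASLDQICDDCYNLYGDPTVHSLCTPDCFTSDYFT",
                 "GCLEALLLTDEMETIQNWI"), FALSE), spacer_len = 10L),
    NPF = precursor_spec("NPF",
      pay("SFDELMNPQMAEELMSNPELWTSYESAQVSRPRF", TRUE), spacer_len = 10L),
    Orco = precursor_spec("Orco",
      pay(paste0("NFDEIDRPGFGF",
                 c("AV", "SV", "AL", "TI", "NV", "AI", "SL", "TV",
                   "NL", "AM", "SI")), FALSE)),
    PDH = precursor_spec("PDH", pay("NSELINSLLGLPKIMNEA", TRUE),
                         spacer_len = 10L),
    SIF = precursor_spec("SIF", pay("GYRKPTFNGSIF", TRUE),
                         spacer_len = 10L),
    SK = precursor_spec("SK",
      pay(c("GGDDQFDDYGHMRF", "QFDDYGMMKF", "ADDYGFLKF", "SDEYGMFKF"),
          TRUE)),
    TRP = precursor_spec("TRP",
      pay(c("APSGFLGMR", "APEGFFGMR", "SPNGFLGVR", "TPSGFMGMR"), TRUE))
  )
  specs
}

#' Materialized catalog precursors
#'
#' Generates the [catalog_specs()] precursor proteins with their ground
#' truth at a fixed default seed.
#'
#' @param seed integer seed.
#' @return tibble: `id`, `family`, `protein`, `truth` (list column).
#' @export
catalog_precursors <- function(seed = 2012L) {
  specs <- catalog_specs()
  rows <- imap(specs, function(sp, fam) {
    gp <- generate_precursor(sp, derive_seed(seed, match(fam, names(specs))))
    tibble(id = paste0("prec_", fam), family = fam,
           protein = gp$protein, truth = list(gp$truth))
  })
  list_rbind(rows)
}

#' Synthetic reference query set
#'
#' One mining query per catalog family: the planted precursor protein with
#' random substitutions at the given rate, emulating an arthropod homolog
#' of each family. Descriptions carry the family and the word
#' "neuropeptide" so keyword filtering keeps them.
#'
#' @param seed integer seed.
#' @param mutation_rate per-residue substitution probability.
#' @return reference tibble (see [reference_peptides()]).
#' @export
catalog_references <- function(seed = 2012L, mutation_rate = 0.08) {
  prec <- catalog_precursors(seed)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  muts <- with_seed(derive_seed(seed, 777L), {
    map_chr(prec$protein, function(p) {
      aa <- strsplit(p, "")[[1]]
      hit <- runif(length(aa)) < mutation_rate
      aa[hit] <- sample(aa20, sum(hit), replace = TRUE)
      paste0(aa, collapse = "")
    })
  })
  reference_peptides(
    id = paste0("ref_", prec$family),
    sequence = muts,
    family = prec$family,
    taxon = "synthetic arthropod",
    description = paste0("ref_", prec$family, " synthetic arthropod ",
                         prec$family, " neuropeptide precursor")
  )
}

# ---------------------------------------------------------------------------
# qPCR and bioassay generators
# ---------------------------------------------------------------------------

#' Default developmental fold-change profile
#'
#' Study-condition defaults for the Ct generator: 14 neuropeptide genes
#' across four stages (NauVI, Cyp, Juv, Adu) with the juvenile stage as
#' calibrator. Up-regulated-in-larva genes (pdh 4-fold, sif 6-fold, astb
#' and calcia ~3-fold in NauVI/Cyp), trp high in NauVI and Adu, irp down
#' only in Juv, and the remaining genes flat across larval stages but
#' down-regulated in adults.
#'
#' @return tibble: `gene`, `stage`, `fold`.
#' @export
default_fold_profile <- function() {
  stages <- c("NauVI", "Cyp", "Juv", "Adu")
  prof <- function(gene, folds) tibble(gene = gene, stage = stages,
                                       fold = folds)
  bind_rows(
    prof("pdh",    c(2,   4,   1, 0.5)),
    prof("sif",    c(2,   6,   1, 0.5)),
    prof("astb",   c(3,   3,   1, 0.4)),
    prof("calcia", c(3,   3,   1, 0.5)),
    prof("trp",    c(3,   1,   1, 3)),
    prof("irp",    c(2,   2,   1, 2)),
    prof("npf",    c(1,   1,   1, 0.4)),
    prof("burb",   c(1,   1,   1, 0.4)),
    prof("calcib", c(1,   1,   1, 0.4)),
    prof("orco",   c(1,   1,   1, 0.4)),
    prof("sulf",   c(1,   1,   1, 0.4)),
    prof("eh",     c(1,   1,   1, 0.4)),
    prof("asta",   c(1,   1,   1, 0.4)),
    prof("astc",   c(1,   1,   1, 0.4))
  )
}

#' Generate a synthetic qPCR Ct table
#'
#' Reference-gene Ct is a batch-shifted constant plus Gaussian noise; each
#' target gene's Ct is the cell's true reference level plus a gene baseline
#' offset minus log2(fold) plus noise, so the 2^-ddCt method recovers the
#' planted folds.
#'
#' @param fold_profile tibble gene x stage -> fold (see
#'   [default_fold_profile()]).
#' @param reference_gene reference gene label added to the table.
#' @param ct_ref_mean mean reference Ct (cycles).
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param baseline_delta target-vs-reference baseline offset (cycles);
#'   recycled over genes.
#' @param batch_sd per-batch additive Ct shift (cycles), shared by all
#'   genes in a batch and cancelled by ddCt.
#' @param n_batches,n_reps design size.
#' @param seed integer seed.
#' @return tidy Ct tibble (gene, stage, batch, replicate, ct).
#' @export
generate_ct_table <- function(fold_profile = default_fold_profile(),
                              reference_gene = "cytb",
                              ct_ref_mean = 15, noise_sd = 0.2,
                              baseline_delta = 3, batch_sd = 0.5,
                              n_batches = 3L, n_reps = 3L, seed = 1L) {
  stopifnot(all(fold_profile$fold > 0))
  genes <- unique(fold_profile$gene)
  stages <- unique(fold_profile$stage)
  base <- setNames(rep(baseline_delta, length.out = length(genes)), genes)
  with_seed(seed, {
    batch_shift <- rnorm(n_batches, 0, batch_sd)
    grid <- tidyr::expand_grid(stage = stages, batch = seq_len(n_batches),
                               replicate = seq_len(n_reps))
    ref_true <- ct_ref_mean + batch_shift[grid$batch]
    ref <- grid |>
      mutate(gene = reference_gene,
             ct = ref_true + rnorm(n(), 0, noise_sd))
    tg <- list_rbind(map(genes, function(g) {
      f <- fold_profile |> filter(.data$gene == g)
      fold <- setNames(f$fold, f$stage)
      grid |>
        mutate(gene = g,
               ct = ref_true + base[[g]] - log2(fold[.data$stage]) +
                 rnorm(n(), 0, noise_sd))
    }))
    bind_rows(ref, tg) |>
      select("gene", "stage", "batch", "replicate", "ct")
  })
}

#' Default settlement-assay scenario
#'
#' Dose-response probabilities of cyprid metamorphosis emulating a
#' proprotein-convertase inhibition experiment: strong 24-h inhibition at
#' 10 and 100 umol/L, little effect at 1 umol/L, and full recovery by
#' 48 h in every group.
#'
#' @return tibble: `dose` (umol/L, 0 = control), `vehicle`, `p24`, `p48`.
#' @export
default_settlement_scenario <- function() {
  tibble(
    dose = c(0, 0, 1, 10, 100),
    vehicle = c("AFSW", "DMSO", "DMSO", "DMSO", "DMSO"),
    p24 = c(0.60, 0.60, 0.58, 0.15, 0.05),
    p48 = c(0.85, 0.85, 0.85, 0.85, 0.85)
  )
}

#' Generate synthetic settlement counts
#'
#' Per dose, timepoint, batch and well: around `n_per_well` cyprids (18-22)
#' with the metamorphosed count drawn Binomial(n_total, p) at the
#' scenario's probability for that dose and timepoint.
#'
#' @param scenario tibble like [default_settlement_scenario()].
#' @param n_wells wells (replicates) per batch and treatment.
#' @param n_batches larval batches.
#' @param n_per_well nominal cyprids per well.
#' @param seed integer seed.
#' @return tibble: dose, vehicle, timepoint, batch, well, n_meta, n_total.
#' @export
generate_settlement_counts <- function(scenario = default_settlement_scenario(),
                                       n_wells = 3L, n_batches = 3L,
                                       n_per_well = 20L, seed = 1L) {
  stopifnot(all(scenario$p24 >= 0 & scenario$p24 <= 1),
            all(scenario$p48 >= 0 & scenario$p48 <= 1))
  with_seed(seed, {
    long <- scenario |>
      tidyr::pivot_longer(c("p24", "p48"), names_to = "timepoint",
                          values_to = "p") |>
      mutate(timepoint = ifelse(.data$timepoint == "p24", 24, 48))
    grid <- tidyr::expand_grid(long,
                               batch = seq_len(n_batches),
                               well = seq_len(n_wells))
    grid |>
      mutate(n_total = sample((n_per_well - 2L):(n_per_well + 2L),
                              n(), replace = TRUE),
             n_meta = rbinom(n(), .data$n_total, .data$p)) |>
      select("dose", "vehicle", "timepoint", "batch", "well",
             "n_meta", "n_total")
  })
}
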