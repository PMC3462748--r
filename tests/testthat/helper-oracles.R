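# Independent oracles used across the suite. These deliberately do not share
# code with the package: the alignment oracle is a plain three-matrix R
# dynamic program, translation is cross-checked against seqinr, and ANOVA
# pieces are recomputed from sums of squares.

oracle_submat <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62
  m["*", ] <- -4
  m[, "*"] <- -4
  m
}

# Affine-gap optimum by straightforward dynamic programming over the three
# alignment states; a gap of length L costs open + L * ext. Returns the
# optimal score only.
oracle_align_score <- function(q, s, open = 11, ext = 1,
                               type = c("local", "global"),
                               smat = oracle_submat()) {
  type <- match.arg(type)
  qa <- strsplit(q, "")[[1]]
  sa <- strsplit(s, "")[[1]]
  m <- length(qa); n <- length(sa)
  NEGI <- -1e9
  M <- matrix(NEGI, m + 1, n + 1)
  E <- matrix(NEGI, m + 1, n + 1)   # gap in query
  F_ <- matrix(NEGI, m + 1, n + 1)  # gap in subject
  M[1, 1] <- 0
  if (type == "global") {
    for (j in 2:(n + 1)) E[1, j] <- -(open + (j - 1) * ext)
    for (i in 2:(m + 1)) F_[i, 1] <- -(open + (i - 1) * ext)
  } else {
    M[1, ] <- 0
    M[, 1] <- 0
  }
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      sub <- smat[qa[i - 1], sa[j - 1]]
      d <- max(M[i - 1, j - 1], E[i - 1, j - 1], F_[i - 1, j - 1])
      M[i, j] <- if (d <= NEGI / 2) NEGI else d + sub
      if (type == "local") {
        M[i, j] <- max(M[i, j], sub)
        if (M[i, j] < 0) M[i, j] <- NEGI
      }
      E[i, j] <- max(M[i, j - 1] - open - ext, E[i, j - 1] - ext,
                     F_[i, j - 1] - open - ext)
      F_[i, j] <- max(M[i - 1, j] - open - ext, F_[i - 1, j] - ext,
                      E[i - 1, j] - open - ext)
      if (type == "local" && M[i, j] > best) best <- M[i, j]
    }
  }
  if (type == "local") best else max(M[m + 1, n + 1], E[m + 1, n + 1],
                                     F_[m + 1, n + 1])
}

random_protein <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                    "")[[1]]) {
  paste0(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_nt_str <- function(len) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# A random but rule-safe precursor spec: payloads avoid K/R entirely and do
# not end in G, so planted sites are the only cleavage sites.
random_spec <- function(n_payloads = NULL, spacer = NULL) {
  alpha <- strsplit("ACDEFHILMNPQSTVWY", "")[[1]]  # no K, R, G
  np <- n_payloads %||% sample(1:5, 1)
  pls <- vapply(seq_len(np), function(i) {
    p <- paste0(sample(alpha, sample(6:18, 1), replace = TRUE), collapse = "")
    sub("^P", "S", p)  # a site followed by Pro would be rejected
  }, character(1))
  sp <- spacer %||% (if (np == 1) 8L else sample(c(0L, 8L), 1))
  precursor_spec("RAND",
                 tibble::tibble(sequence = pls,
                                amidate = sample(c(TRUE, FALSE), np,
                                                 replace = TRUE)),
                 sites = sample(c("KR", "RR"), 1),
                 spacer_len = sp)
}

tmp_fasta <- function(records, width = 60) {
  path <- tempfile(fileext = ".fasta")
  lines <- unlist(lapply(seq_len(nrow(records)), function(i) {
    seq <- records$sequence[i]
    chunks <- substring(seq, seq(1, nchar(seq), width),
                        pmin(seq(1, nchar(seq), width) + width - 1,
                             nchar(seq)))
    c(paste0(">", records$id[i]), chunks)
  }))
  writeLines(lines, path)
  path
}
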