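# Independent brute-force oracles used to check the package implementations.
# Each is written from first principles with its own tables and mechanisms,
# not by calling the code under test.

# explicit IUPAC expansion table (the oracle's own copy)
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), K = c("G", "T"), M = c("A", "C"),
  S = c("C", "G"), W = c("A", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)
ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 K = "M", M = "K", S = "S", W = "W", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

oracle_revcomp <- function(x) {
  paste(rev(ORACLE_COMP[strsplit(x, "")[[1]]]), collapse = "")
}

# position-by-position scanner on both strands
oracle_find_sites <- function(template, primer, max_mismatch = 0) {
  tch <- strsplit(template, "")[[1]]
  scan <- function(pat) {
    pch <- strsplit(pat, "")[[1]]
    k <- length(pch)
    hits <- integer(0)
    if (k > length(tch)) return(hits)
    for (i in seq_len(length(tch) - k + 1)) {
      mism <- 0
      for (j in seq_len(k)) {
        if (!tch[i + j - 1] %in% ORACLE_IUPAC[[pch[j]]]) mism <- mism + 1
      }
      if (mism <= max_mismatch) hits <- c(hits, i)
    }
    hits
  }
  data.frame(position = c(scan(primer), scan(oracle_revcomp(primer))),
             strand = rep(c("+", "-"),
                          c(length(scan(primer)),
                            length(scan(oracle_revcomp(primer))))))
}

# ends-free global alignment maximum score by dynamic programming
oracle_overlap_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac)
  m <- length(bc)
  S <- matrix(0, n + 1, m + 1) # free leading end gaps
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (ac[i] == bc[j]) match else mismatch
      S[i + 1, j + 1] <- max(S[i, j] + sub, S[i, j + 1] + gap,
                             S[i + 1, j] + gap)
    }
  }
  max(S[n + 1, ], S[, m + 1]) # free trailing end gaps
}

# regex-based tryptic fragmentation (different mechanism from the package)
oracle_tryptic_fragments <- function(protein) {
  strsplit(protein, "(?<=[KR])(?!P)", perl = TRUE)[[1]]
}

oracle_digest <- function(protein, missed = 0) {
  frags <- oracle_tryptic_fragments(protein)
  out <- frags
  if (missed > 0 && length(frags) > 1) {
    for (m in seq_len(min(missed, length(frags) - 1))) {
      for (i in seq_len(length(frags) - m)) {
        out <- c(out, paste(frags[i:(i + m)], collapse = ""))
      }
    }
  }
  out
}

# exhaustive substring membership of peptides in family members
oracle_membership <- function(peptide, family) {
  names(family)[vapply(family, function(s) grepl(peptide, s, fixed = TRUE),
                       logical(1))]
}

# boolean-mask coverage
oracle_coverage <- function(protein, peptides) {
  n <- nchar(protein)
  mask <- rep(FALSE, n)
  for (p in peptides) {
    k <- nchar(p)
    if (k == 0 || k > n) next
    for (i in seq_len(n - k + 1)) {
      if (substr(protein, i, i + k - 1) == p) mask[i:(i + k - 1)] <- TRUE
    }
  }
  trunc(100 * sum(mask) / n * 100 + 0.5) / 100
}

# binomial probit log-likelihood for the grid-search oracle
oracle_probit_ll <- function(a, b, dose, n, dead) {
  p <- pnorm(a + b * log10(dose))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(dead * log(p) + (n - dead) * log(1 - p))
}

# random genome with one concrete expansion of each primer of a pair
# planted at the pair's expected reference coordinates
plant_pair_sites <- function(pair, genome_length = 2500) {
  g <- random_dna(genome_length)
  span <- pair$expected_span
  fwd <- vapply(strsplit(pair$forward, "")[[1]],
                function(ch) ORACLE_IUPAC[[ch]][1], character(1))
  fwd <- paste(fwd, collapse = "")
  rev_rc <- oracle_revcomp(paste(vapply(strsplit(pair$reverse, "")[[1]],
                                        function(ch) ORACLE_IUPAC[[ch]][1],
                                        character(1)), collapse = ""))
  substr(g, span[1], span[1] + nchar(fwd) - 1) <- fwd
  substr(g, span[2] - nchar(rev_rc) + 1, span[2]) <- rev_rc
  g
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n, replace = TRUE),
        collapse = "")
}

# random stop-free ORF of len residues plus terminal stop
random_orf <- function(n_residues) {
  codons <- setdiff(names(Biostrings::GENETIC_CODE),
                    names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"])
  paste0("ATG", paste(sample(codons, n_residues - 1, replace = TRUE),
                      collapse = ""), "TAA")
}
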