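## In-silico PCR with degenerate IUPAC primers: site finding, amplicon
## prediction, collection screening, vip3 typing, contig merging and
## pairwise percent identity.

# IUPAC ambiguity codes -> expansion sets
IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), K = c("G", "T"), M = c("A", "C"),
  S = c("C", "G"), W = c("A", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# complement of every IUPAC code (degenerate codes map to the code whose
# expansion set is the complement of the original set)
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", K = "M", M = "K", S = "S", W = "W",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Match a degenerate IUPAC base against a template base
#'
#' @param pattern_base single IUPAC DNA character (A,C,G,T,R,Y,K,S,W,M,B,D,H,V,N).
#' @param template_base single concrete DNA character (A, C, G or T).
#' @return `TRUE` iff `template_base` belongs to the expansion set of
#'   `pattern_base` (e.g. R matches A or G; N matches anything).
#' @examples
#' iupac_match("R", "A") # TRUE
#' iupac_match("R", "C") # FALSE
#' @export
iupac_match <- function(pattern_base, template_base) {
  if (!pattern_base %in% names(IUPAC_DNA)) {
    stop_btchar("invalid IUPAC pattern character: '", pattern_base, "'",
                class = "btchar_invalid_base")
  }
  if (!template_base %in% c("A", "C", "G", "T")) {
    stop_btchar("invalid template base: '", template_base, "'",
                class = "btchar_invalid_base")
  }
  template_base %in% IUPAC_DNA[[pattern_base]]
}

#' Reverse complement of a (possibly degenerate) DNA string
#'
#' @param x DNA string, IUPAC codes allowed.
#' @return reverse complement as a character string.
#' @export
reverse_complement <- function(x) {
  chars <- strsplit(toupper(x), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_COMPLEMENT))
  if (length(bad)) {
    stop_btchar("invalid DNA character(s): ", paste(unique(bad), collapse = ", "),
                class = "btchar_invalid_base")
  }
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Construct a primer pair
#'
#' A forward/reverse degenerate primer pair, optionally annotated with the
#' expected binding span (1-based, inclusive) on a reference sequence.
#'
#' @param name pair label.
#' @param forward,reverse primer sequences 5'-3' (IUPAC codes allowed).
#' @param expected_span optional integer `c(start, end)`: position of the
#'   first base of the forward site and the last base of the reverse site on
#'   the reference.
#' @return an object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse, expected_span = NULL) {
  for (p in c(forward, reverse)) {
    if (!nzchar(p)) stop_btchar("empty primer", class = "btchar_empty_primer")
    chars <- strsplit(toupper(p), "")[[1]]
    bad <- setdiff(chars, names(IUPAC_DNA))
    if (length(bad)) {
      stop_btchar("primer '", name, "' contains invalid character(s): ",
                  paste(unique(bad), collapse = ", "),
                  class = "btchar_invalid_base")
    }
  }
  if (!is.null(expected_span)) {
    stopifnot(length(expected_span) == 2, expected_span[1] >= 1,
              expected_span[1] <= expected_span[2])
  }
  structure(
    list(name = name, forward = toupper(forward), reverse = toupper(reverse),
         expected_span = expected_span),
    class = "primer_pair"
  )
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("Primer pair '", x$name, "'\n", sep = "")
  cat("  forward: ", x$forward, "\n  reverse: ", x$reverse, "\n", sep = "")
  if (!is.null(x$expected_span)) {
    cat("  expected span: ", x$expected_span[1], "-", x$expected_span[2],
        " (", x$expected_span[2] - x$expected_span[1] + 1, " bp)\n", sep = "")
  }
  invisible(x)
}

#' vip3 screening and typing primers
#'
#' The degenerate primer sets used for vip3 gene detection in Bt isolates:
#' one screening pair amplifying the N-terminal part of the gene (expected
#' product 1395 bp, positions 78-1472 on the reference) and three typing
#' pairs sharing a forward primer, whose reverse primers discriminate the
#' vip3Aa / vip3Af / vip3Ag variants by amplicon (1060, 1052 and 1027 bp).
#'
#' @return a named list of `primer_pair` objects:
#'   `screening`, `vip3Aa`, `vip3Af`, `vip3Ag`.
#' @export
vip3_primers <- function() {
  list(
    screening = primer_pair(
      "vip3-sc", "TGCCACTGGTATCAARGA",
      "CCATTAATYGGAKTCAAAAATGTTTCACTGAT", expected_span = c(78L, 1472L)),
    vip3Aa = primer_pair(
      "vip3Aa", "ASTTTAAGATATGAGGYAACAGC",
      "CATCGTAAAAATGTACAATAGGA", expected_span = c(1297L, 2356L)),
    vip3Af = primer_pair(
      "vip3Af", "ASTTTAAGATATGAGGYAACAGC",
      "TCAAATGATATATGACCACCA", expected_span = c(1297L, 2348L)),
    vip3Ag = primer_pair(
      "vip3Ag", "ASTTTAAGATATGAGGYAACAGC",
      "ATGTAAAACGAGAAAGCTCTACA", expected_span = c(1297L, 2323L))
  )
}

#' Read primer pairs from a tab-separated table
#'
#' Expects columns `name`, `forward`, `reverse` and optionally `start`,
#' `end` (expected span on the reference). A copy of the vip3 primer set in
#' this format ships at
#' `system.file("extdata", "vip3_primers.tsv", package = "btchar")`.
#'
#' @param path path to the TSV file.
#' @return named list of `primer_pair` objects.
#' @export
read_primer_pairs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "forward", "reverse") %in% names(tab)))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    span <- if (all(c("start", "end") %in% names(tab)) &&
                !is.na(tab$start[i])) {
      c(tab$start[i], tab$end[i])
    }
    primer_pair(tab$name[i], tab$forward[i], tab$reverse[i],
                expected_span = span)
  })
  stats::setNames(out, tab$name)
}

#' Find degenerate-primer binding sites on a template
#'
#' Scans both strands. A plus-strand hit is a position where the primer
#' matches the template left to right; a minus-strand hit is a position where
#' the reverse complement of the primer matches, reported by the 1-based
#' position of the site's leftmost base on the plus strand. A mismatch is a
#' template base outside the expansion set of the (possibly degenerate)
#' primer base; hits with at most `max_mismatch` mismatches are reported.
#'
#' @param template DNA string containing only A, C, G, T.
#' @param primer IUPAC primer string.
#' @param max_mismatch maximum number of mismatching positions (default 0).
#' @return data.frame with columns `position` (integer) and `strand`
#'   ("+" or "-").
#' @export
find_primer_sites <- function(template, primer, max_mismatch = 0L) {
  if (!nzchar(primer)) stop_btchar("empty primer", class = "btchar_empty_primer")
  template <- toupper(template)
  tchars <- strsplit(template, "")[[1]]
  bad <- setdiff(tchars, c("A", "C", "G", "T"))
  if (length(bad)) {
    stop_btchar("template contains non-ACGT character(s): ",
                paste(unique(bad), collapse = ", "),
                class = "btchar_invalid_base")
  }
  hits_one_strand <- function(pat) {
    pchars <- strsplit(toupper(pat), "")[[1]]
    k <- length(pchars)
    n <- length(tchars)
    if (k > n) return(integer(0))
    # logical matrix: does primer position j match template position i+j-1
    ok <- vapply(seq_len(k), function(j) {
      tchars[j:(n - k + j)] %in% IUPAC_DNA[[pchars[j]]]
    }, logical(n - k + 1L))
    if (is.null(dim(ok))) ok <- matrix(ok, nrow = 1L)
    mism <- k - rowSums(ok)
    which(mism <= max_mismatch)
  }
  plus <- hits_one_strand(primer)
  minus <- hits_one_strand(reverse_complement(primer))
  data.frame(
    position = as.integer(c(plus, minus)),
    strand = rep(c("+", "-"), c(length(plus), length(minus))),
    stringsAsFactors = FALSE
  )
}

#' Predict PCR amplicons for a primer pair on a template
#'
#' Pairs every plus-strand forward-primer hit with every minus-strand
#' reverse-primer hit lying to its right. The amplicon runs from the first
#' base of the forward site (`start`) to the last base of the reverse site
#' (`end`), both 1-based inclusive, so `length = end - start + 1`.
#'
#' @param template DNA string (A/C/G/T).
#' @param pair a `primer_pair`.
#' @param max_mismatch mismatches tolerated per primer site (default 0).
#' @param size_limits numeric `c(min, max)` product size in bp kept
#'   (default `c(50, 5000)`, suppressing spurious pairings).
#' @return data.frame with columns `start`, `end`, `length`,
#'   `forward_primer`, `reverse_primer`; zero rows when no pairing exists.
#' @examples
#' primers <- vip3_primers()
#' # a template with planted sites at the reference coordinates yields the
#' # expected 1395 bp product (78-1472)
#' @export
predict_amplicons <- function(template, pair, max_mismatch = 0L,
                              size_limits = c(50, 5000)) {
  stopifnot(inherits(pair, "primer_pair"))
  fwd <- find_primer_sites(template, pair$forward, max_mismatch)
  rev_ <- find_primer_sites(template, pair$reverse, max_mismatch)
  f_pos <- fwd$position[fwd$strand == "+"]
  r_pos <- rev_$position[rev_$strand == "-"]
  rlen <- nchar(pair$reverse)
  out <- data.frame(start = integer(0), end = integer(0), length = integer(0),
                    forward_primer = character(0), reverse_primer = character(0),
                    stringsAsFactors = FALSE)
  for (f in f_pos) {
    for (r in r_pos) {
      end <- r + rlen - 1L
      len <- end - f + 1L
      if (r > f && len >= size_limits[1] && len <= size_limits[2]) {
        out <- rbind(out, data.frame(
          start = f, end = end, length = len,
          forward_primer = paste0(pair$name, "-F"),
          reverse_primer = paste0(pair$name, "-R"),
          stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Screen a collection of genomes for a primer pair
#'
#' An isolate is positive when the pair predicts at least one amplicon in its
#' genome. The positive percentage is rounded half away from zero to the
#' nearest integer (18 carriers in 80 isolates reports 23%).
#'
#' @param genomes named character vector of genome sequences (or a
#'   `DNAStringSet`).
#' @param pair a `primer_pair`.
#' @param max_mismatch,size_limits passed to [predict_amplicons()].
#' @return list with `table` (data.frame `isolate_id`, `positive`),
#'   `n_positive` and `percent_positive`.
#' @export
screen_collection <- function(genomes, pair, max_mismatch = 0L,
                              size_limits = c(50, 5000)) {
  if (methods::is(genomes, "XStringSet")) {
    genomes <- stats::setNames(as.character(genomes), names(genomes))
  }
  if (length(genomes) < 1) stop_btchar("no genomes", class = "btchar_no_input")
  ids <- names(genomes)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop_btchar("genomes must carry unique isolate ids",
                class = "btchar_duplicate_id")
  }
  positive <- vapply(genomes, function(g) {
    nrow(predict_amplicons(g, pair, max_mismatch, size_limits)) > 0
  }, logical(1))
  n_pos <- sum(positive)
  list(
    table = data.frame(isolate_id = ids, positive = unname(positive),
                       stringsAsFactors = FALSE),
    n_positive = as.integer(n_pos),
    percent_positive = round_half_up(100 * n_pos / length(genomes))
  )
}

#' Type a vip3 gene by discriminating reverse primers
#'
#' Runs the shared typing forward primer against each candidate reverse
#' primer; the assigned type is the label of the unique reverse primer that
#' yields an amplicon. No amplicon with any reverse primer gives type
#' `"none"`; more than one is an ambiguity error.
#'
#' @param genome DNA string.
#' @param forward shared forward primer (IUPAC).
#' @param reverse_set named character vector of reverse primers, names are
#'   the type labels (default: the vip3Aa/vip3Af/vip3Ag typing primers).
#' @param max_mismatch,size_limits passed to [predict_amplicons()].
#' @return list with `assigned_type` (label or "none") and `amplicon`
#'   (one-row data.frame, or `NULL` when untyped).
#' @export
type_vip3 <- function(genome,
                      forward = vip3_primers()$vip3Aa$forward,
                      reverse_set = c(
                        vip3Aa = vip3_primers()$vip3Aa$reverse,
                        vip3Af = vip3_primers()$vip3Af$reverse,
                        vip3Ag = vip3_primers()$vip3Ag$reverse),
                      max_mismatch = 0L, size_limits = c(50, 5000)) {
  if (!length(reverse_set)) {
    stop_btchar("empty reverse primer set", class = "btchar_no_input")
  }
  labels <- names(reverse_set)
  hits <- list()
  for (lab in labels) {
    pr <- primer_pair(lab, forward, reverse_set[[lab]])
    amp <- predict_amplicons(genome, pr, max_mismatch, size_limits)
    if (nrow(amp)) hits[[lab]] <- amp[1, , drop = FALSE]
  }
  if (length(hits) == 0) {
    return(list(assigned_type = "none", amplicon = NULL))
  }
  if (length(hits) > 1) {
    stop_btchar("ambiguous typing: amplicons for ",
                paste(names(hits), collapse = ", "),
                class = "btchar_ambiguous_typing")
  }
  list(assigned_type = names(hits), amplicon = hits[[1]])
}

#' Merge two sequenced contigs by exact suffix-prefix overlap
#'
#' Joins the N-terminal and C-terminal partial gene sequences into one
#' contig: finds the longest suffix of `n_term` that exactly equals a prefix
#' of `c_term`, requires it to span at least `min_overlap` bases, and
#' returns the shortest superstring.
#'
#' @param n_term,c_term sequences to merge (N-terminal part first).
#' @param min_overlap minimum acceptable exact overlap in bases.
#' @return merged sequence string.
#' @export
merge_contigs <- function(n_term, c_term, min_overlap = 20L) {
  if (!nzchar(n_term) || !nzchar(c_term)) {
    stop_btchar("empty contig", class = "btchar_no_input")
  }
  max_ov <- min(nchar(n_term), nchar(c_term))
  for (ov in seq(max_ov, 1L)) {
    if (substring(n_term, nchar(n_term) - ov + 1L) == substring(c_term, 1L, ov)) {
      if (ov < min_overlap) break
      return(paste0(n_term, substring(c_term, ov + 1L)))
    }
  }
  stop_btchar("no exact overlap of at least ", min_overlap, " bases",
              class = "btchar_no_overlap")
}

#' Percent identity of a query against a reference
#'
#' Global alignment with free end gaps (a minimal BLAST-like surrogate:
#' match +1, mismatch -1, gap -2), computed with
#' [Biostrings::pairwiseAlignment()]. Identity is matches over aligned
#' columns (terminal gaps excluded by the ends-free alignment), reported to
#' the nearest integer; query cover is the fraction of query residues inside
#' the aligned region.
#'
#' @param query,reference sequence strings over the same alphabet.
#' @param match,mismatch,gap alignment scores (gap is the per-base cost).
#' @return list with `identity_pct`, `query_cover_pct`, `aligned_length`
#'   and `score`.
#' @export
percent_identity <- function(query, reference, match = 1, mismatch = -1,
                             gap = -2) {
  if (!nzchar(query) || !nzchar(reference)) {
    stop_btchar("empty sequence", class = "btchar_no_input")
  }
  alphabet <- sort(unique(strsplit(paste0(query, reference), "")[[1]]))
  submat <- matrix(mismatch, length(alphabet), length(alphabet),
                   dimnames = list(alphabet, alphabet))
  diag(submat) <- match
  aln <- Biostrings::pairwiseAlignment(
    query, reference, type = "overlap", substitutionMatrix = submat,
    gapOpening = 0, gapExtension = abs(gap))
  pat_chars <- as.character(Biostrings::pattern(aln))
  aligned_len <- nchar(pat_chars)
  n_match <- Biostrings::nmatch(aln)
  # query residues inside the aligned region = non-gap characters of the
  # aligned pattern (end gaps are free, so the region excludes overhangs)
  cover <- nchar(gsub("-", "", pat_chars, fixed = TRUE)) / nchar(query)
  list(
    identity_pct = round_half_up(100 * n_match / aligned_len),
    query_cover_pct = round_half_up(100 * cover),
    aligned_length = as.integer(aligned_len),
    score = Biostrings::score(aln)
  )
}
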