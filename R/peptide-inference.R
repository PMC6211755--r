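## Unique-tryptic-peptide protein inference: digestion, uniqueness indexing
## over a homologous family, the score/length/modification filter cascade,
## the two-unique-peptide positive-identification rule, and coverage.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Tryptic in-silico digestion
#'
#' Cleaves after K or R except when the next residue is P (the Keil rule).
#' With `missed_cleavages > 0`, all concatenations of up to
#' `missed_cleavages + 1` consecutive fragments are also returned.
#'
#' @param protein residue string over the standard 20-letter alphabet.
#' @param missed_cleavages number of internal uncleaved sites allowed
#'   (0, 1 or 2; default 0).
#' @param rule cleavage rule id; only `"trypsin"` is defined.
#' @return data.frame with columns `peptide`, `start`, `end`,
#'   `missed` (number of internal sites), ordered by `start` then length.
#'   With `missed_cleavages = 0` the peptides tile the protein exactly.
#' @examples
#' digest("AAKGGRCC")$peptide # "AAK" "GGR" "CC"
#' digest("AAKPGGR")$peptide # "AAKPGGR": K before P is not cleaved
#' @export
digest <- function(protein, missed_cleavages = 0L, rule = "trypsin") {
  if (!identical(rule, "trypsin")) {
    stop_btchar("unknown cleavage rule: '", rule, "'", class = "btchar_bad_rule")
  }
  if (!nzchar(protein)) stop_btchar("empty protein", class = "btchar_no_input")
  chars <- strsplit(protein, "")[[1]]
  bad <- setdiff(chars, AA20)
  if (length(bad)) {
    stop_btchar("non-standard residue(s): ", paste(unique(bad), collapse = ", "),
                class = "btchar_invalid_residue")
  }
  n <- length(chars)
  # cleavage after position i when chars[i] in {K,R} and chars[i+1] != P
  cut_after <- which(chars %in% c("K", "R") & c(chars[-1], "") != "P")
  bounds <- c(0L, cut_after[cut_after < n], n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  frag <- data.frame(
    peptide = substring(protein, starts, ends),
    start = starts, end = ends, stringsAsFactors = FALSE)
  out <- frag
  out$missed <- 0L
  if (missed_cleavages > 0) {
    for (m in seq_len(min(missed_cleavages, nrow(frag) - 1L))) {
      i <- seq_len(nrow(frag) - m)
      out <- rbind(out, data.frame(
        peptide = substring(protein, frag$start[i], frag$end[i + m]),
        start = frag$start[i], end = frag$end[i + m], missed = as.integer(m),
        stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a peptide uniqueness index over a protein family
#'
#' Indexes every tryptic peptide of every family member and records, for
#' each peptide, the set of members containing it as an exact substring of
#' the full sequence (so peptides arising with a missed cleavage still
#' classify correctly). A peptide mapping to exactly one member is "unique";
#' to two or more, "shared".
#'
#' @param family named character vector of protein sequences.
#' @param equate_IL treat I and L as identical before matching (mass
#'   spectrometry cannot distinguish them); default `FALSE`.
#' @param missed_cleavages passed to [digest()] when enumerating peptides.
#' @return object of class `uniqueness_index`: a named list mapping peptide
#'   string to a character vector of member ids, with the family stored in
#'   `attr(, "family")`.
#' @export
build_uniqueness_index <- function(family, equate_IL = FALSE,
                                   missed_cleavages = 0L) {
  if (length(family) < 1) stop_btchar("empty family", class = "btchar_no_input")
  ids <- names(family)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop_btchar("family members must carry unique ids",
                class = "btchar_duplicate_id")
  }
  norm <- function(x) if (equate_IL) gsub("I", "L", x, fixed = TRUE) else x
  seqs_n <- vapply(family, norm, character(1))
  peptides <- unique(unlist(lapply(family, function(s) {
    digest(s, missed_cleavages = missed_cleavages)$peptide
  }), use.names = FALSE))
  idx <- lapply(peptides, function(p) {
    ids[vapply(seqs_n, function(s) grepl(norm(p), s, fixed = TRUE), logical(1))]
  })
  names(idx) <- peptides
  structure(idx, class = "uniqueness_index", family = family,
            equate_IL = equate_IL)
}

#' @export
print.uniqueness_index <- function(x, ...) {
  sizes <- lengths(unclass(x))
  cat("Uniqueness index: ", length(x), " peptides over ",
      length(attr(x, "family")), " family members (",
      sum(sizes == 1), " unique, ", sum(sizes > 1), " shared)\n", sep = "")
  invisible(x)
}

#' Filter search-engine peptide rows
#'
#' The filter cascade applied to peptide-spectrum-match rows before
#' uniqueness classification: keep peptides of 6 to 20 residues, with a
#' contribution score strictly greater than 2 and no modification; then
#' collapse repeated peptide strings to a single representative (the
#' highest-contribution row).
#'
#' @param evidence data.frame with columns `peptide`, `length`,
#'   `contribution`, `modified` (a `protein_evidence` object also works).
#' @param min_len,max_len retained peptide length range (defaults 6 and 20).
#' @param min_contribution retain only rows with contribution strictly
#'   greater than this (default 2).
#' @return the retained rows, one per distinct peptide string.
#' @export
filter_peptides <- function(evidence, min_len = 6L, max_len = 20L,
                            min_contribution = 2) {
  rows <- if (inherits(evidence, "protein_evidence")) evidence$rows else evidence
  stopifnot(all(c("peptide", "length", "contribution", "modified") %in%
                  names(rows)))
  keep <- rows$length >= min_len & rows$length <= max_len &
    rows$contribution > min_contribution & !rows$modified
  rows <- rows[keep, , drop = FALSE]
  if (nrow(rows) == 0) return(rows)
  # duplicate collapse: keep the highest-contribution representative,
  # preserving first-occurrence order
  idx <- seq_len(nrow(rows))
  best <- vapply(split(idx, rows$peptide),
                 function(i) i[which.max(rows$contribution[i])], integer(1))
  rows <- rows[sort(unname(best)), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Classify filtered peptides as unique or shared
#'
#' A peptide whose index entry names exactly one family member is unique;
#' two or more, shared. Peptides absent from the index (e.g. semi-tryptic
#' artifacts) are classified by direct substring search against the family,
#' with a warning.
#'
#' @param peptides data.frame of filtered peptide rows (column `peptide`).
#' @param index a `uniqueness_index` built over the same family.
#' @return list with data.frames `unique` and `shared`; each gains a
#'   `members` column (comma-separated ids containing the peptide).
#' @export
classify_peptides <- function(peptides, index) {
  stopifnot(inherits(index, "uniqueness_index"))
  family <- attr(index, "family")
  equate_IL <- attr(index, "equate_IL")
  norm <- function(x) if (equate_IL) gsub("I", "L", x, fixed = TRUE) else x
  members_of <- function(p) {
    if (!is.null(index[[p]])) return(index[[p]])
    warning("peptide '", p, "' absent from index; classified by direct search",
            call. = FALSE)
    ids <- names(family)
    ids[vapply(family, function(s) grepl(norm(p), norm(s), fixed = TRUE),
               logical(1))]
  }
  mem <- lapply(peptides$peptide, members_of)
  peptides$members <- vapply(mem, paste, character(1), collapse = ",")
  n_mem <- lengths(mem)
  list(unique = peptides[n_mem == 1, , drop = FALSE],
       shared = peptides[n_mem > 1, , drop = FALSE])
}

#' Group peptide rows into per-protein evidence
#'
#' @param protein_id candidate protein label.
#' @param unused_score the search engine's protein-level confidence score.
#' @param rows data.frame of peptide rows for this protein (columns
#'   `peptide`, `length`, `contribution`, `modified`).
#' @return object of class `protein_evidence`.
#' @export
protein_evidence <- function(protein_id, unused_score, rows) {
  stopifnot(is.character(protein_id), length(protein_id) == 1,
            is.numeric(unused_score))
  if (!"length" %in% names(rows)) rows$length <- nchar(rows$peptide)
  structure(list(protein_id = protein_id, unused_score = unused_score,
                 rows = rows),
            class = "protein_evidence")
}

#' Identify Cry proteins from search-engine evidence by unique peptides
#'
#' The positive-identification procedure: proteins with an unused score of
#' 2 or less are excluded outright (the engine's >99% confidence cutoff);
#' the remaining evidence is filtered ([filter_peptides()]) and classified
#' against the family uniqueness index; a protein is a positive
#' identification when supported by at least `min_unique` (default 2)
#' unique peptides. Coverage is computed from the retained peptides.
#'
#' @param evidence_set list of `protein_evidence` objects, or a single
#'   data.frame PSM table with columns
#'   `protein_id`, `peptide`, `length`, `contribution`, `modified`, `unused`.
#' @param family named character vector of reference protein sequences;
#'   must contain every evidence `protein_id`.
#' @param min_unused exclude proteins with unused score <= this (default 2).
#' @param min_unique unique peptides required for a positive call (default 2).
#' @param equate_IL passed to [build_uniqueness_index()].
#' @return data.frame with one row per protein: `protein_id`,
#'   `unused_score`, `n_peptides` (retained), `n_unique`, `n_shared`,
#'   `coverage_pct`, `status` in
#'   `{"positive", "not_positive", "excluded_low_score"}`.
#' @export
identify_proteins <- function(evidence_set, family, min_unused = 2,
                              min_unique = 2L, equate_IL = FALSE) {
  if (is.data.frame(evidence_set)) {
    evidence_set <- psm_to_evidence(evidence_set)
  }
  ids <- vapply(evidence_set, function(e) e$protein_id, character(1))
  missing <- setdiff(ids, names(family))
  if (length(missing)) {
    stop_btchar("evidence references protein(s) not in family: ",
                paste(missing, collapse = ", "), class = "btchar_unknown_protein")
  }
  index <- build_uniqueness_index(family, equate_IL = equate_IL)
  res <- lapply(evidence_set, function(ev) {
    if (ev$unused_score <= min_unused) {
      return(data.frame(protein_id = ev$protein_id,
                        unused_score = ev$unused_score,
                        n_peptides = 0L, n_unique = 0L, n_shared = 0L,
                        coverage_pct = 0, status = "excluded_low_score",
                        stringsAsFactors = FALSE))
    }
    kept <- filter_peptides(ev)
    cls <- classify_peptides(kept, index)
    n_u <- nrow(cls$unique)
    n_s <- nrow(cls$shared)
    data.frame(
      protein_id = ev$protein_id, unused_score = ev$unused_score,
      n_peptides = nrow(kept), n_unique = n_u, n_shared = n_s,
      coverage_pct = coverage(family[[ev$protein_id]], kept),
      status = if (n_u >= min_unique) "positive" else "not_positive",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Split a flat PSM table into per-protein evidence objects
#'
#' @param psm data.frame with columns `protein_id`, `peptide`, `length`,
#'   `contribution`, `modified`, `unused`.
#' @return list of `protein_evidence` objects, one per protein id.
#' @export
psm_to_evidence <- function(psm) {
  needed <- c("protein_id", "peptide", "length", "contribution",
              "modified", "unused")
  stopifnot(all(needed %in% names(psm)))
  lapply(split(psm, psm$protein_id), function(d) {
    protein_evidence(d$protein_id[1], d$unused[1],
                     d[c("peptide", "length", "contribution", "modified")])
  })
}

#' Sequence coverage of a protein by a peptide set
#'
#' Percent of residue positions covered by at least one occurrence of any
#' peptide (union of all exact substring occurrence intervals), reported to
#' two decimals.
#'
#' @param protein residue string.
#' @param peptides data.frame with a `peptide` column (or character vector).
#' @return coverage percentage (0 when no peptides match).
#' @export
coverage <- function(protein, peptides) {
  peps <- if (is.data.frame(peptides)) peptides$peptide else peptides
  if (length(peps) == 0) return(0)
  n <- nchar(protein)
  mask <- logical(n)
  for (p in unique(peps)) {
    k <- nchar(p)
    if (k == 0 || k > n) next
    # position-by-position scan so overlapping occurrences also count
    for (i in seq_len(n - k + 1L)) {
      if (substring(protein, i, i + k - 1L) == p) mask[i:(i + k - 1L)] <- TRUE
    }
  }
  round_half_up(100 * sum(mask) / n, 2)
}
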