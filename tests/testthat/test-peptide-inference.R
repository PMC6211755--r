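# Tryptic digestion, uniqueness indexing, the filter cascade, the
# two-unique-peptide identification rule, and coverage.

test_that("tryptic digestion cleaves after K/R except before P", {
  expect_equal(digest("AAKGGRCC")$peptide, c("AAK", "GGR", "CC"))
  expect_equal(digest("AAKPGGR")$peptide, "AAKPGGR")
  d <- digest("AAKGGRCC")
  expect_equal(d$start, c(1L, 4L, 7L))
  expect_equal(d$end, c(3L, 6L, 8L))
  expect_error(digest("AAK", rule = "chymotrypsin"), class = "btchar_bad_rule")
  expect_error(digest("AAZ"), class = "btchar_invalid_residue")
})

test_that("digestion agrees with a regex-based oracle with missed cleavages", {
  set.seed(31)
  for (rep in 1:15) {
    prot <- random_protein(300)
    for (mc in 0:2) {
      got <- sort(digest(prot, missed_cleavages = mc)$peptide)
      want <- sort(oracle_digest(prot, mc))
      expect_equal(got, want)
    }
    # conservation: 0-missed-cleavage peptides tile the protein
    expect_equal(paste(digest(prot)$peptide, collapse = ""), prot)
  }
})

test_that("uniqueness index equals exhaustive substring search", {
  fam <- c(X = "CCKAAR", Y = "CCKDDR")
  idx <- build_uniqueness_index(fam)
  expect_equal(sort(idx[["CCK"]]), c("X", "Y"))
  expect_equal(idx[["AAR"]], "X")
  expect_equal(idx[["DDR"]], "Y")
  # single-member family: everything unique
  idx1 <- build_uniqueness_index(c(A = "MKAAARGGK"))
  expect_true(all(lengths(unclass(idx1)) == 1))
  # random families vs brute force
  set.seed(33)
  for (rep in 1:8) {
    f <- make_reference_family(150, 4, 8, seed = rep)
    idx <- build_uniqueness_index(f$sequences)
    for (p in names(idx)) {
      expect_equal(sort(idx[[p]]), sort(oracle_membership(p, f$sequences)))
    }
  }
})

test_that("family growth never makes a shared peptide unique", {
  set.seed(35)
  f <- make_reference_family(200, 4, 6, seed = 5)
  small <- build_uniqueness_index(f$sequences[1:3])
  large <- build_uniqueness_index(f$sequences)
  for (p in names(small)) {
    if (length(small[[p]]) > 1) expect_gt(length(large[[p]]), 1)
  }
})

test_that("the filter cascade applies length, score and modification rules", {
  rows <- data.frame(
    peptide = c("SHORT", "AAAAAAAAAAAAAAAAAAAAA", "GOODPEPTIDE",
                "BORDERLINE", "MODIFIEDPEP", "GOODPEPTIDE", "GOODPEPTIDE"),
    contribution = c(5, 5, 5, 2, 5, 3, 4),
    modified = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  rows$length <- nchar(rows$peptide)
  kept <- filter_peptides(rows)
  expect_false("SHORT" %in% kept$peptide)            # 5 residues
  expect_false(any(kept$length > 20))                # 21 residues
  expect_false("BORDERLINE" %in% kept$peptide)       # contribution exactly 2
  expect_false("MODIFIEDPEP" %in% kept$peptide)
  # three GOODPEPTIDE rows collapse to the highest-contribution one
  expect_equal(sum(kept$peptide == "GOODPEPTIDE"), 1)
  expect_equal(kept$contribution[kept$peptide == "GOODPEPTIDE"], 5)
})

test_that("peptides classify as unique exactly when overlapping a substitution", {
  set.seed(37)
  f <- make_reference_family(200, 2, 5, seed = 9)
  idx <- build_uniqueness_index(f$sequences)
  # positions where the two members actually differ (cleavage sites are
  # preserved by construction, so the digests align position for position)
  c1 <- strsplit(f$sequences[["M1"]], "")[[1]]
  c2 <- strsplit(f$sequences[["M2"]], "")[[1]]
  diff_pos <- which(c1 != c2)
  d1 <- digest(f$sequences[["M1"]])
  d1 <- d1[nchar(d1$peptide) >= 5, ] # very short peptides recur by chance
  rows <- data.frame(peptide = d1$peptide, length = nchar(d1$peptide),
                     contribution = 5, modified = FALSE,
                     stringsAsFactors = FALSE)
  cls <- classify_peptides(rows, idx)
  overlaps_diff <- vapply(seq_len(nrow(d1)), function(i) {
    any(diff_pos >= d1$start[i] & diff_pos <= d1$end[i])
  }, logical(1))
  expect_setequal(cls$unique$peptide, d1$peptide[overlaps_diff])
  expect_setequal(cls$shared$peptide, d1$peptide[!overlaps_diff])
  # the two lists partition the input
  expect_equal(nrow(cls$unique) + nrow(cls$shared), nrow(rows))
})

test_that("identification applies the unused-score and two-unique-peptide rules", {
  fam <- c(A = "MKGGGDDDKAAAWWWPTTRVVVYYYEEK",
           B = "MKGGGDDDKCCCWWWPTTRHHHYYYEEK")
  # A and B share GGGDDDK; AAAWWWPTTR/VVVYYYEEK unique to A
  mk <- function(id, unused, peps) {
    protein_evidence(id, unused,
                     data.frame(peptide = peps, length = nchar(peps),
                                contribution = 5, modified = FALSE,
                                stringsAsFactors = FALSE))
  }
  res <- identify_proteins(
    list(mk("A", 2.5, c("GGGDDDK", "AAAWWWPTTR", "VVVYYYEEK")),
         mk("B", 1.9, c("GGGDDDK", "CCCWWWPTTR"))),
    fam)
  expect_equal(res$status[res$protein_id == "A"], "positive")
  expect_equal(res$n_unique[res$protein_id == "A"], 2L)
  expect_equal(res$status[res$protein_id == "B"], "excluded_low_score")
  # unused above the cutoff but a single unique peptide: not positive
  res2 <- identify_proteins(list(mk("A", 3.0, c("GGGDDDK", "AAAWWWPTTR"))), fam)
  expect_equal(res2$status, "not_positive")
  expect_equal(res2$n_unique, 1L)
  expect_error(identify_proteins(list(mk("Z", 5, "GGGDDDK")), fam),
               class = "btchar_unknown_protein")
})

test_that("identification on noiseless synthetic tables recovers the truth", {
  noiseless <- list(frac_decoy_rows = 0, frac_modified = 0,
                    frac_duplicated = 0, contribution_mean = 4)
  for (seed in c(2, 14)) {
    f <- make_reference_family(300, 3, 10, seed = seed)
    true_ids <- c("M1", "M2")
    psm <- make_psm_table(true_ids, f, noise = noiseless, seed = seed)
    res <- identify_proteins(psm, f$sequences)
    # expected positives: true proteins with >= 2 unique filtered peptides,
    # computed by brute force from the digests
    idx_members <- function(p) oracle_membership(p, f$sequences)
    for (id in true_ids) {
      d <- digest(f$sequences[[id]])
      valid <- d$peptide[nchar(d$peptide) >= 6 & nchar(d$peptide) <= 20]
      n_unique <- sum(vapply(unique(valid),
                             function(p) length(idx_members(p)) == 1,
                             logical(1)))
      want <- if (n_unique >= 2) "positive" else "not_positive"
      expect_equal(res$status[res$protein_id == id], want)
    }
    expect_equal(res$status[res$protein_id == "M3"], "excluded_low_score")
  }
})

test_that("coverage equals the boolean-mask oracle", {
  expect_equal(coverage("AAAKGGGR", character(0)), 0)
  expect_equal(coverage("AAAKGGGR", "AAAKGGGR"), 100)
  set.seed(39)
  for (rep in 1:10) {
    prot <- random_protein(120)
    d <- digest(prot)$peptide
    peps <- sample(d, min(4, length(d)))
    expect_equal(coverage(prot, peps), oracle_coverage(prot, peps))
  }
})

test_that("duplicated rows injected by the generator survive filtering once", {
  f <- make_reference_family(300, 3, 8, seed = 3)
  psm <- make_psm_table(c("M1", "M2"), f, seed = 3)
  ev <- psm_to_evidence(psm)[["M1"]]
  kept <- filter_peptides(ev)
  expect_false(any(duplicated(kept$peptide)))
})
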