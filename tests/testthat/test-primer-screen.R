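# In-silico PCR: degenerate matching, site finding, amplicon prediction,
# screening, typing, contig merging, percent identity.

test_that("degenerate base matching agrees with the explicit expansion table", {
  codes <- names(ORACLE_IUPAC)
  for (p in codes) {
    for (t in c("A", "C", "G", "T")) {
      expect_identical(iupac_match(p, t), t %in% ORACLE_IUPAC[[p]])
    }
  }
  expect_true(iupac_match("R", "A"))
  expect_false(iupac_match("R", "C"))
  expect_true(iupac_match("N", "T"))
  expect_error(iupac_match("X", "A"), "X", class = "btchar_invalid_base")
  expect_error(iupac_match("A", "N"), class = "btchar_invalid_base")
})

test_that("primer site finding matches a naive scanner on random templates", {
  set.seed(42)
  primers <- c("TGCCACTGGTATCAARGA", "ASTTTAAGATATGAGGYAACAGC", "ACGTN", "RYKSWM")
  for (rep in 1:10) {
    template <- random_dna(3000)
    for (pr in primers) {
      for (mm in 0:2) {
        got <- find_primer_sites(template, pr, mm)
        want <- oracle_find_sites(template, pr, mm)
        got <- got[order(got$strand, got$position), ]
        want <- want[order(want$strand, want$position), ]
        expect_equal(got$position, want$position)
        expect_equal(got$strand, want$strand)
      }
    }
  }
})

test_that("planted sites are found on the correct strand and position", {
  set.seed(7)
  pr <- vip3_primers()$screening
  g <- random_dna(600)
  fwd <- gsub("R", "A", pr$forward) # concrete expansion
  g2 <- paste0(substr(g, 1, 9), fwd, substr(g, 10 + nchar(fwd), 600))
  hits <- find_primer_sites(g2, pr$forward)
  expect_true(any(hits$position == 10 & hits$strand == "+"))
  # reverse complement of a typing reverse primer gives one minus-strand hit
  rc <- reverse_complement("CATCGTAAAAATGTACAATAGGA")
  g3 <- paste0(substr(g, 1, 99), rc, substr(g, 100 + nchar(rc), 600))
  hits3 <- find_primer_sites(g3, "CATCGTAAAAATGTACAATAGGA")
  expect_true(any(hits3$position == 100 & hits3$strand == "-"))
})

test_that("more allowed mismatches never removes a primer hit", {
  set.seed(9)
  template <- random_dna(2000)
  pr <- "TGCCACTGGTATCAARGA"
  prev <- find_primer_sites(template, pr, 0)
  for (mm in 1:3) {
    cur <- find_primer_sites(template, pr, mm)
    key <- function(d) paste(d$position, d$strand)
    expect_true(all(key(prev) %in% key(cur)))
    prev <- cur
  }
})

test_that("amplicon coordinates and sizes obey length = end - start + 1", {
  set.seed(11)
  primers <- vip3_primers()
  expected <- c(screening = 1395L, vip3Aa = 1060L, vip3Af = 1052L,
                vip3Ag = 1027L)
  for (nm in names(expected)) {
    pair <- primers[[nm]]
    g <- plant_pair_sites(pair)
    amp <- predict_amplicons(g, pair)
    expect_equal(nrow(amp), 1)
    expect_equal(amp$start, pair$expected_span[1])
    expect_equal(amp$end, pair$expected_span[2])
    expect_equal(amp$length, expected[[nm]])
    expect_equal(amp$length, amp$end - amp$start + 1)
  }
})

test_that("no amplicon is predicted when the reverse site is absent", {
  set.seed(12)
  pair <- vip3_primers()$screening
  g <- random_dna(2000)
  fwd <- paste(vapply(strsplit(pair$forward, "")[[1]],
                      function(ch) ORACLE_IUPAC[[ch]][1], character(1)),
               collapse = "")
  substr(g, 78, 78 + nchar(fwd) - 1) <- fwd
  expect_equal(nrow(predict_amplicons(g, pair)), 0)
})

test_that("amplicon prediction is strand symmetric", {
  set.seed(13)
  pair <- vip3_primers()$vip3Aa
  g <- plant_pair_sites(pair)
  amp <- predict_amplicons(g, pair)
  # on the reverse complement with swapped roles the same product appears
  swapped <- primer_pair("swap", pair$reverse, pair$forward)
  amp_rc <- predict_amplicons(oracle_revcomp(g), swapped)
  expect_equal(nrow(amp_rc), 1)
  expect_equal(amp_rc$length, amp$length)
  # coordinates mirror: start' = L - end + 1
  expect_equal(amp_rc$start, nchar(g) - amp$end + 1)
  expect_equal(amp_rc$end, nchar(g) - amp$start + 1)
})

test_that("collection screening matches the synthetic ground truth", {
  for (seed in c(1, 23)) {
    cfg <- synthetic_config(seed = seed)
    sim <- make_isolate_genomes(cfg)
    sc <- screen_collection(sim$genomes, vip3_primers()$screening)
    expect_identical(sc$table$positive, sim$truth$carrier)
    expect_equal(sc$n_positive, 18L)
    expect_equal(sc$percent_positive, 23)
  }
  cfg0 <- synthetic_config(seed = 4, n_vip3_positive = 0)
  sim0 <- make_isolate_genomes(cfg0)
  sc0 <- screen_collection(sim0$genomes, vip3_primers()$screening)
  expect_equal(sc0$n_positive, 0L)
  expect_equal(sc0$percent_positive, 0)
  expect_error(screen_collection(c(a = "ACGT", a = "ACGT"),
                                 vip3_primers()$screening),
               class = "btchar_duplicate_id")
})

test_that("vip3 typing assigns the planted type and errors on ambiguity", {
  set.seed(17)
  primers <- vip3_primers()
  for (nm in c("vip3Aa", "vip3Af", "vip3Ag")) {
    g <- plant_pair_sites(primers[[nm]])
    res <- type_vip3(g)
    expect_equal(res$assigned_type, nm)
    expect_equal(res$amplicon$length,
                 primers[[nm]]$expected_span[2] -
                   primers[[nm]]$expected_span[1] + 1)
  }
  expect_equal(type_vip3(random_dna(2500))$assigned_type, "none")
  # planting a second reverse site (clear of the first, which ends at
  # 2356 and spans 2334-2356) makes typing ambiguous
  g2 <- plant_pair_sites(primers$vip3Aa)
  rc_af <- oracle_revcomp(primers$vip3Af$reverse)
  substr(g2, 2200 - nchar(rc_af) + 1, 2200) <- rc_af
  expect_error(type_vip3(g2), class = "btchar_ambiguous_typing")
})

test_that("the shipped primer table round trips through the TSV reader", {
  pairs <- read_primer_pairs(system.file("extdata", "vip3_primers.tsv",
                                         package = "btchar"))
  builtin <- vip3_primers()
  expect_setequal(names(pairs), names(builtin))
  for (nm in names(pairs)) {
    expect_equal(pairs[[nm]]$forward, builtin[[nm]]$forward)
    expect_equal(pairs[[nm]]$reverse, builtin[[nm]]$reverse)
    expect_equal(pairs[[nm]]$expected_span, builtin[[nm]]$expected_span)
  }
})

test_that("contig merging reconstructs a split sequence", {
  expect_equal(merge_contigs("ACGTAC", "TACGG", 3), "ACGTACGG")
  x <- random_dna(50)
  expect_equal(merge_contigs(x, x, 50), x)
  set.seed(19)
  for (rep in 1:5) {
    full <- random_dna(2000)
    cut <- sample(500:1400, 1)
    n_term <- substr(full, 1, cut + 100)
    c_term <- substr(full, cut + 1, 2000)
    expect_equal(merge_contigs(n_term, c_term, 100), full)
  }
  expect_error(merge_contigs("AAAA", "CCCC", 2), class = "btchar_no_overlap")
})

test_that("percent identity agrees with a dynamic-programming oracle", {
  expect_equal(percent_identity("ACGTACGT", "ACGTACGT")$identity_pct, 100)
  expect_equal(percent_identity("ACGTACGT", "ACGTACGT")$query_cover_pct, 100)
  # 100-base query with 6 substitutions: identity 94
  set.seed(21)
  q <- random_dna(100)
  r <- q
  # interior substitutions only: ends-free alignment would clip terminal
  # mismatches into overhangs and change the aligned-column count
  pos <- sample(10:90, 6)
  for (p in pos) {
    substr(r, p, p) <- setdiff(c("A", "C", "G", "T"),
                               substr(q, p, p))[1]
  }
  res <- percent_identity(q, r)
  expect_equal(res$identity_pct, 94)
  # alignment score equals the exhaustive DP optimum on random pairs
  for (rep in 1:20) {
    a <- random_dna(sample(10:30, 1))
    b <- random_dna(sample(10:30, 1))
    expect_equal(percent_identity(a, b)$score, oracle_overlap_score(a, b))
  }
  expect_error(percent_identity("", "ACGT"), class = "btchar_no_input")
})
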