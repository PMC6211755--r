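## Seeded synthetic-data generators emulating the study's inputs: a
## homologous protein family with controlled unique-peptide structure,
## search-engine style PSM tables with filterable noise, genomes with
## planted degenerate-primer sites, binomial probit bioassays, and
## size-exclusion calibration tables. Every generator records ground truth
## so the matching analysis stage can be checked against it.

#' Configuration for the synthetic study
#'
#' Defaults emulate the study design: an 80-isolate collection of which 18
#' carry a vip3 gene, a small Cry-like homolog family, and bioassays with
#' 5 threefold serial dilutions and 16 larvae per concentration in 3
#' replicates, generated from a probit truth model at the reference
#' strain's slope 1.05 and LC50 48 ng/cm2 with zero control mortality.
#'
#' @param seed master seed; per-generator streams are derived from it.
#' @param n_isolates collection size.
#' @param n_vip3_positive number of vip3 carriers (`<= n_isolates`).
#' @param family_size number of homologous reference proteins.
#' @param base_protein_length residues in the family's common ancestor.
#' @param divergence point substitutions per family member.
#' @param psm_noise list: `frac_decoy_rows`, `frac_modified`,
#'   `frac_duplicated`, `contribution_mean` (shifted-exponential mean above
#'   the cutoff for true peptides).
#' @param bioassay_design list: `slope`, `lc50`, `dilution_factor`,
#'   `n_doses`, `larvae_per_dose`, `replicates`, `control_mortality`.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_isolates = 80L,
                             n_vip3_positive = 18L,
                             family_size = 3L,
                             base_protein_length = 300L,
                             divergence = 8L,
                             psm_noise = list(frac_decoy_rows = 0.15,
                                              frac_modified = 0.1,
                                              frac_duplicated = 0.1,
                                              contribution_mean = 4),
                             bioassay_design = list(slope = 1.05,
                                                    lc50 = 48,
                                                    dilution_factor = 3,
                                                    n_doses = 5L,
                                                    larvae_per_dose = 16L,
                                                    replicates = 3L,
                                                    control_mortality = 0)) {
  stopifnot(n_vip3_positive <= n_isolates, n_vip3_positive >= 0,
            divergence >= 0, family_size >= 1, base_protein_length >= 50,
            bioassay_design$larvae_per_dose >= 1,
            bioassay_design$slope > 0, bioassay_design$lc50 > 0,
            bioassay_design$control_mortality >= 0,
            bioassay_design$control_mortality < 1)
  structure(list(seed = as.integer(seed), n_isolates = as.integer(n_isolates),
                 n_vip3_positive = as.integer(n_vip3_positive),
                 family_size = as.integer(family_size),
                 base_protein_length = as.integer(base_protein_length),
                 divergence = as.integer(divergence),
                 psm_noise = psm_noise, bioassay_design = bioassay_design),
            class = "synthetic_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Generate a homologous protein family with known substitution positions
#'
#' Draws one random base protein and derives each member by exactly
#' `divergence` point substitutions. Substitutions avoid K and R positions
#' and never introduce K, R or P, so the tryptic cleavage pattern of every
#' member matches the base: unique peptides are exactly those overlapping a
#' member's recorded substitutions.
#'
#' @param base_length residues in the base protein (>= 50).
#' @param n_members number of members (>= 2 for a meaningful family).
#' @param divergence substitutions per member (`< base_length`).
#' @param seed RNG seed.
#' @return object of class `reference_family`: list with `sequences`
#'   (named character vector, members `M1..Mk`), `base`, and `truth`
#'   (data.frame `member`, `position`, `from`, `to`).
#' @export
make_reference_family <- function(base_length, n_members, divergence, seed) {
  stopifnot(base_length >= 50, n_members >= 1)
  if (divergence >= base_length) {
    stop_btchar("divergence must be below base_length",
                class = "btchar_invalid_parameter")
  }
  with_seed(derive_seed(seed, "family"), {
    base <- paste(sample(AA20, base_length, replace = TRUE), collapse = "")
    bchars <- strsplit(base, "")[[1]]
    # substitutable positions: keep cleavage sites intact
    free <- which(!bchars %in% c("K", "R"))
    repl_alphabet <- setdiff(AA20, c("K", "R", "P"))
    truth <- NULL
    seqs <- character(n_members)
    for (m in seq_len(n_members)) {
      chars <- bchars
      if (divergence > 0) {
        pos <- sort(sample(free, divergence))
        for (p in pos) {
          chars[p] <- sample(setdiff(repl_alphabet, bchars[p]), 1)
        }
        truth <- rbind(truth, data.frame(
          member = paste0("M", m), position = pos,
          from = bchars[pos], to = chars[pos], stringsAsFactors = FALSE))
      }
      seqs[m] <- paste(chars, collapse = "")
    }
    structure(list(
      sequences = stats::setNames(seqs, paste0("M", seq_len(n_members))),
      base = base,
      truth = truth %||% data.frame(member = character(0), position = integer(0),
                                    from = character(0), to = character(0))),
      class = "reference_family")
  })
}

# one concrete expansion of a degenerate primer (first base of each set,
# deterministic so planted sites are reproducible)
expand_primer <- function(primer) {
  chars <- strsplit(toupper(primer), "")[[1]]
  paste(vapply(chars, function(ch) IUPAC_DNA[[ch]][1], character(1)),
        collapse = "")
}

plant <- function(genome, site, start) {
  stopifnot(start >= 1, start + nchar(site) - 1 <= nchar(genome))
  paste0(substring(genome, 1, start - 1), site,
         substring(genome, start + nchar(site)))
}

#' Generate a synthetic isolate collection with planted vip3 primer sites
#'
#' Carrier genomes receive one concrete expansion of the screening forward
#' primer and the reverse complement of one expansion of the screening
#' reverse primer at the reference coordinates (amplicon 78-1472); each
#' carrier is also assigned a vip3 type and receives the matching typing
#' primer sites (shared forward at 1297, type-specific reverse ending at
#' the type's reference coordinate). Non-carriers are plain random
#' sequence.
#'
#' @param config a `synthetic_config`.
#' @param screening_pair `primer_pair` used for screening (default the
#'   vip3 screening pair).
#' @param genome_length genome length in bp (default 2500, accommodating
#'   the reference coordinates).
#' @param types vip3 types to cycle through for carriers (default
#'   `c("vip3Aa", "vip3Af", "vip3Ag")`).
#' @return list with `genomes` (named character vector `iso001...`) and
#'   `truth` (data.frame `isolate_id`, `carrier`, `vip3_type`).
#' @export
make_isolate_genomes <- function(config,
                                 screening_pair = vip3_primers()$screening,
                                 genome_length = 2500L,
                                 types = c("vip3Aa", "vip3Af", "vip3Ag")) {
  stopifnot(inherits(config, "synthetic_config"))
  span <- screening_pair$expected_span %||% c(78L, 1472L)
  typing <- vip3_primers()[types]
  max_coord <- max(span[2],
                   vapply(typing, function(p) p$expected_span[2], numeric(1)))
  if (genome_length < max_coord) {
    stop_btchar("genome_length ", genome_length, " cannot hold the primer ",
                "coordinates (need >= ", max_coord, ")",
                class = "btchar_invalid_parameter")
  }
  with_seed(derive_seed(config$seed, "genomes"), {
    n <- config$n_isolates
    ids <- sprintf("iso%03d", seq_len(n))
    carrier <- rep(FALSE, n)
    if (config$n_vip3_positive > 0) {
      carrier[sample(n, config$n_vip3_positive)] <- TRUE
    }
    type <- rep(NA_character_, n)
    if (any(carrier)) {
      type[carrier] <- rep_len(types, sum(carrier))
    }
    fwd_site <- expand_primer(screening_pair$forward)
    rev_site <- reverse_complement(expand_primer(screening_pair$reverse))
    genomes <- vapply(seq_len(n), function(i) {
      g <- paste(sample(c("A", "C", "G", "T"), genome_length, replace = TRUE),
                 collapse = "")
      if (!carrier[i]) return(g)
      g <- plant(g, fwd_site, span[1])
      g <- plant(g, rev_site, span[2] - nchar(rev_site) + 1L)
      tp <- typing[[type[i]]]
      t_fwd <- expand_primer(tp$forward)
      t_rev <- reverse_complement(expand_primer(tp$reverse))
      g <- plant(g, t_fwd, tp$expected_span[1])
      plant(g, t_rev, tp$expected_span[2] - nchar(t_rev) + 1L)
    }, character(1))
    list(genomes = stats::setNames(genomes, ids),
         truth = data.frame(isolate_id = ids, carrier = carrier,
                            vip3_type = type, stringsAsFactors = FALSE))
  })
}

#' Generate a search-engine style PSM table
#'
#' Rows are drawn from the tryptic digests of the true proteins, with
#' contribution scores from a shifted exponential above the >2 cutoff.
#' True proteins receive an unused score well above 2; family members not
#' in `true_proteins` appear with unused scores below 2 (so the exclusion
#' filter is exercised whenever the family is larger than the truth).
#' Unless `noise` fractions are zero, the table also contains at least one
#' row violating each peptide filter: too short, too long, low
#' contribution, modified, and an exact duplicate.
#'
#' @param true_proteins character vector of family member ids truly present.
#' @param family a `reference_family` or named character vector.
#' @param noise list as in [synthetic_config()]'s `psm_noise`.
#' @param seed RNG seed.
#' @return data.frame with columns `protein_id`, `peptide`, `length`,
#'   `contribution`, `modified`, `unused`.
#' @export
make_psm_table <- function(true_proteins, family,
                           noise = list(frac_decoy_rows = 0.15,
                                        frac_modified = 0.1,
                                        frac_duplicated = 0.1,
                                        contribution_mean = 4),
                           seed = 1L) {
  seqs <- if (inherits(family, "reference_family")) family$sequences else family
  unknown <- setdiff(true_proteins, names(seqs))
  if (length(unknown)) {
    stop_btchar("unknown protein id(s): ", paste(unknown, collapse = ", "),
                class = "btchar_unknown_protein")
  }
  noiseless <- all(c(noise$frac_decoy_rows, noise$frac_modified,
                     noise$frac_duplicated) == 0)
  with_seed(derive_seed(seed, "psm"), {
    rows <- NULL
    for (id in true_proteins) {
      peps <- digest(seqs[[id]])$peptide
      rows <- rbind(rows, data.frame(
        protein_id = id, peptide = peps, length = nchar(peps),
        contribution = 2 + stats::rexp(length(peps),
                                       1 / (noise$contribution_mean - 2)),
        modified = FALSE,
        unused = stats::runif(1, 10, 600),
        stringsAsFactors = FALSE))
    }
    # low-confidence evidence for family members absent from the truth
    for (id in setdiff(names(seqs), true_proteins)) {
      peps <- digest(seqs[[id]])$peptide
      take <- utils::head(peps, 3)
      rows <- rbind(rows, data.frame(
        protein_id = id, peptide = take, length = nchar(take),
        contribution = 2 + stats::rexp(length(take), 1),
        modified = FALSE,
        unused = stats::runif(1, 0, 1.9),
        stringsAsFactors = FALSE))
    }
    if (!noiseless) {
      anchor <- rows[rows$protein_id == true_proteins[1], , drop = FALSE]
      src <- seqs[[true_proteins[1]]]
      violations <- data.frame(
        protein_id = true_proteins[1],
        peptide = c(substring(src, 1, 4),          # length < 6
                    substring(src, 1, 25),         # length > 20
                    anchor$peptide[1],             # contribution <= 2
                    anchor$peptide[1]),            # modified
        contribution = c(5, 5, 1.5, 5),
        modified = c(FALSE, FALSE, FALSE, TRUE),
        unused = anchor$unused[1],
        stringsAsFactors = FALSE)
      violations$length <- nchar(violations$peptide)
      dup_pool <- anchor[anchor$length >= 6 & anchor$length <= 20, ,
                         drop = FALSE]
      n_dup <- max(1L, round(noise$frac_duplicated * nrow(anchor)))
      dups <- dup_pool[sample(nrow(dup_pool), min(n_dup, nrow(dup_pool)),
                              replace = FALSE), , drop = FALSE]
      dups$contribution <- dups$contribution * stats::runif(nrow(dups), 0.5, 1)
      rows <- rbind(rows, violations[names(rows)], dups)
    }
    rows <- rows[order(rows$protein_id), , drop = FALSE]
    rownames(rows) <- NULL
    rows
  })
}

#' Generate a bioassay dataset from a probit truth model
#'
#' Doses form a geometric series bracketing the true LC50
#' (`lc50 * f^(-(k-1)/2 .. (k-1)/2)` for `n_doses = k`). Dead counts are
#' binomial with
#' `p = c + (1 - c) * pnorm(slope * (log10(dose) - log10(lc50)))`,
#' the Abbott-complement application of control mortality `c`.
#'
#' @param design list as in [synthetic_config()]'s `bioassay_design`.
#' @param seed RNG seed.
#' @return data.frame with columns `dose`, `n`, `dead`, `replicate`, and
#'   the truth model in `attr(, "truth")`.
#' @export
make_bioassay <- function(design, seed = 1L) {
  stopifnot(design$slope > 0, design$lc50 > 0)
  reps <- design$replicates %||% 1L
  with_seed(derive_seed(seed, "bioassay"), {
    k <- design$n_doses
    expo <- seq_len(k) - (k + 1) / 2
    doses <- design$lc50 * design$dilution_factor^expo
    cm <- design$control_mortality %||% 0
    p_model <- stats::pnorm(design$slope * (log10(doses) - log10(design$lc50)))
    p_obs <- cm + (1 - cm) * p_model
    out <- do.call(rbind, lapply(seq_len(reps), function(r) {
      data.frame(dose = doses, n = design$larvae_per_dose,
                 dead = stats::rbinom(k, design$larvae_per_dose, p_obs),
                 replicate = r)
    }))
    attr(out, "truth") <- list(slope = design$slope, lc50 = design$lc50,
                               control_mortality = cm)
    out
  })
}

#' Generate a size-exclusion calibration table and query elution volume
#'
#' Standards' elution volumes are produced from the stated
#' `Kav = slope * log10(mass) + intercept` line plus Gaussian noise;
#' volumes falling outside `[V0, Vc]` are resampled (error after 100
#' attempts). The optional query mass yields the elution volume a protein
#' of that mass would show on the noiseless line.
#'
#' @param standard_masses kDa, positive and distinct.
#' @param V0,Vc void and total column volume (ml), `V0 < Vc`.
#' @param line numeric `c(slope, intercept)` of the Kav line (slope < 0).
#' @param noise_sd elution-volume noise SD (ml).
#' @param seed RNG seed.
#' @param query_mass optional kDa for a query elution volume.
#' @return list with `standards` (data.frame `name`, `mass_kda`, `ve_ml`),
#'   `query_ve` (or `NULL`), and `truth` (the line).
#' @export
make_calibration <- function(standard_masses, V0, Vc, line, noise_sd = 0,
                             seed = 1L, query_mass = NULL) {
  stopifnot(V0 < Vc, all(standard_masses > 0),
            !anyDuplicated(standard_masses), length(line) == 2)
  with_seed(derive_seed(seed, "calibration"), {
    ve_true <- V0 + (line[1] * log10(standard_masses) + line[2]) * (Vc - V0)
    if (any(ve_true < V0 | ve_true > Vc)) {
      stop_btchar("noiseless elution volume outside [V0, Vc]: line and ",
                  "standards are inconsistent with the column",
                  class = "btchar_bad_volume")
    }
    ve <- vapply(ve_true, function(v) {
      for (i in seq_len(100L)) {
        cand <- v + stats::rnorm(1, 0, noise_sd)
        if (cand >= V0 && cand <= Vc) return(cand)
      }
      stop_btchar("could not sample elution volume inside [V0, Vc]",
                  class = "btchar_bad_volume")
    }, numeric(1))
    query_ve <- NULL
    if (!is.null(query_mass)) {
      query_ve <- V0 + (line[1] * log10(query_mass) + line[2]) * (Vc - V0)
    }
    list(standards = data.frame(
      name = paste0("std", seq_along(standard_masses)),
      mass_kda = standard_masses, ve_ml = ve, stringsAsFactors = FALSE),
      query_ve = query_ve,
      truth = list(slope = line[1], intercept = line[2]))
  })
}
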