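## End-to-end orchestration: simulate -> screen -> type -> identify ->
## fit dose-response -> characterize, with deterministic seeding and an
## optional on-disk report bundle of delimited tables plus a JSON summary.

#' Run the full synthetic characterization pipeline
#'
#' Generates a synthetic study from `config` and pushes it through every
#' analysis stage: collection screening and typing with the vip3 primers,
#' Cry protein identification from the synthetic PSM table, probit
#' dose-response fitting of the synthetic bioassay, and gel-filtration
#' characterization of a synthetic tetramer. Rerunning with the same
#' config reproduces the bundle exactly.
#'
#' @param config a [synthetic_config()].
#' @param out_dir optional directory; when given, every stage table is
#'   written as a tab-separated file plus a JSON `summary.json` and a
#'   plain-text log recording seeds and parameters.
#' @param stages character subset of
#'   `c("screen", "type", "identify", "doseresponse", "characterize")`;
#'   stages not listed are skipped.
#' @return list of stage results: `screen` (per-isolate table and summary
#'   counts), `typing` (per-carrier assigned types), `identification`
#'   (per-protein calls), `doseresponse` (`probit_fit`), `gelfiltration`
#'   (apparent mass and oligomer order), `truth` (all generator ground
#'   truth), `config`.
#' @export
run_pipeline <- function(config = synthetic_config(),
                         out_dir = NULL,
                         stages = c("screen", "type", "identify",
                                    "doseresponse", "characterize")) {
  stopifnot(inherits(config, "synthetic_config"))
  bad <- setdiff(stages, c("screen", "type", "identify", "doseresponse",
                           "characterize"))
  if (length(bad)) {
    stop_btchar("unknown stage(s): ", paste(bad, collapse = ", "),
                class = "btchar_bad_config")
  }
  res <- list(config = config, truth = list())
  primers <- vip3_primers()

  if (any(c("screen", "type") %in% stages)) {
    sim <- make_isolate_genomes(config)
    res$truth$isolates <- sim$truth
    if ("screen" %in% stages) {
      res$screen <- screen_collection(sim$genomes, primers$screening)
    }
    if ("type" %in% stages) {
      carriers <- sim$truth$isolate_id[sim$truth$carrier]
      typed <- vapply(carriers, function(id) {
        type_vip3(sim$genomes[[id]])$assigned_type
      }, character(1))
      res$typing <- data.frame(isolate_id = carriers,
                               assigned_type = unname(typed),
                               stringsAsFactors = FALSE)
    }
  }

  if ("identify" %in% stages) {
    fam <- make_reference_family(config$base_protein_length,
                                 config$family_size, config$divergence,
                                 config$seed)
    true_ids <- names(fam$sequences)[seq_len(max(1L, config$family_size - 1L))]
    psm <- make_psm_table(true_ids, fam, noise = config$psm_noise,
                          seed = config$seed)
    res$truth$family <- fam
    res$truth$true_proteins <- true_ids
    res$psm <- psm
    res$identification <- identify_proteins(psm, fam$sequences)
  }

  if ("doseresponse" %in% stages) {
    bio <- make_bioassay(config$bioassay_design, seed = config$seed)
    res$truth$bioassay <- attr(bio, "truth")
    res$bioassay <- bio
    res$doseresponse <- fit_probit(bio)
  }

  if ("characterize" %in% stages) {
    # synthetic tetramer on a synthetic column (V0 9 ml, Vc 24 ml)
    monomer <- 88.5
    cal <- make_calibration(
      standard_masses = c(669, 440, 158, 75, 43), V0 = 9, Vc = 24,
      line = c(-0.35, 1.08), noise_sd = 0, seed = config$seed,
      query_mass = 4 * monomer)
    curve <- fit_calibration(cal$standards, V0 = 9, Vc = 24)
    res$gelfiltration <- gel_filtration_result(curve, cal$query_ve, monomer)
    res$truth$gelfiltration <- list(monomer = monomer, oligomer_order = 4L)
  }

  if (!is.null(out_dir)) {
    write_report_bundle(res, out_dir)
  }
  res
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_report_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste0("seed: ", res$config$seed),
                 paste0("n_isolates: ", res$config$n_isolates),
                 paste0("n_vip3_positive: ", res$config$n_vip3_positive),
                 paste0("family_size: ", res$config$family_size),
                 paste0("divergence: ", res$config$divergence))
  summary <- list(seed = res$config$seed)
  if (!is.null(res$screen)) {
    write_tsv(res$screen$table, file.path(out_dir, "screen.tsv"))
    summary$screen <- list(n_positive = res$screen$n_positive,
                           percent_positive = res$screen$percent_positive)
  }
  if (!is.null(res$typing)) {
    write_tsv(res$typing, file.path(out_dir, "typing.tsv"))
    summary$typing <- as.list(table(res$typing$assigned_type))
  }
  if (!is.null(res$identification)) {
    write_tsv(res$identification, file.path(out_dir, "identification.tsv"))
    summary$identification <- list(
      positive = res$identification$protein_id[
        res$identification$status == "positive"])
  }
  if (!is.null(res$doseresponse)) {
    fit <- res$doseresponse
    tab <- data.frame(slope = fit$slope, slope_se = fit$slope_se,
                      lc50 = fit$lc50, fl_lo = fit$fl95[1],
                      fl_hi = fit$fl95[2], chisq = fit$chisq, df = fit$df,
                      heterogeneity = fit$heterogeneity)
    write_tsv(tab, file.path(out_dir, "doseresponse.tsv"))
    summary$doseresponse <- as.list(tab)
  }
  if (!is.null(res$gelfiltration)) {
    gf <- res$gelfiltration
    tab <- data.frame(Ve = gf$Ve, Kav = gf$Kav,
                      apparent_mass = gf$apparent_mass,
                      monomer_mass = gf$monomer_mass,
                      oligomer_order = gf$oligomer_order)
    write_tsv(tab, file.path(out_dir, "gelfiltration.tsv"))
    summary$gelfiltration <- as.list(tab)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
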