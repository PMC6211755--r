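#' Round half away from zero
#'
#' Base `round()` rounds half to even ("banker's rounding"), which is the
#' wrong convention for reporting bioassay percentages: 22.5% must print as
#' 23%, not 22%. This helper rounds ties away from zero, the convention used
#' throughout the package for reported percentages and oligomer orders.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(22.5) # 23
#' round_half_up(90.625, 0) # 91
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_btchar <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "btchar_error")))
}

## derive a per-stream seed from a master seed, staying inside 32-bit range
derive_seed <- function(seed, stream) {
  offsets <- c(
    family = 101L, genomes = 211L, psm = 307L, bioassay = 401L,
    calibration = 503L, pipeline = 601L
  )
  off <- offsets[[stream]]
  as.integer((as.double(seed) * 7919 + off) %% 2147483647)
}

#' Read sequences from a FASTA file
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::readAAStringSet()] returning a plain named character vector,
#' the representation the rest of the package works with.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta_dna <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta_dna
#' @export
read_fasta_protein <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs named character vector (DNA or protein).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  lines <- character(2L * length(seqs))
  lines[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  lines[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(lines, path)
  invisible(path)
}
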