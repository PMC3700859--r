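#' Synthetic rCRS-like mitochondrial reference sequence
#'
#' Returns a deterministic synthetic 16,569-bp nucleotide sequence laid out in
#' rCRS coordinates. It is *not* the revised Cambridge Reference Sequence:
#' GenBank material cannot be redistributed here, and none of the analyses in
#' this package depend on the true bases — only on coordinates and on a few
#' structural features, which the synthetic sequence reproduces:
#'
#' * length 16,569, positions 1-based;
#' * a poly-C tract at 303–315 (with the canonical T interruption at 310);
#' * an AC dinucleotide repeat at 515–524;
#' * pinned bases at positions used as worked examples throughout the
#'   package (e.g. `T` at 152, `A` at 7765, `C` at 16270, `T` at 16519),
#'   matching the base the true reference carries at those sites.
#'
#' @param as_string if `TRUE` (default) return a single character scalar;
#'   otherwise a character vector of single bases.
#' @return The reference sequence.
#' @export
#' @examples
#' substr(synthetic_rcrs(), 303, 315)  # poly-C tract
synthetic_rcrs <- function(as_string = TRUE) {
  bases <- .mtphylo_ref_cache$bases
  if (is.null(bases)) {
    # deterministic: own linear congruential stream, independent of .Random.seed
    n <- 16569L
    x <- integer(n)
    state <- 987654321
    for (i in seq_len(n)) {
      state <- (1103515245 * state + 12345) %% 2147483648
      x[i] <- state %% 4L
    }
    bases <- c("A", "C", "G", "T")[x + 1L]
    bases[303:315] <- "C"
    bases[310] <- "T"                       # canonical interruption
    bases[515:524] <- rep(c("A", "C"), 5)   # AC repeat
    pin <- c(`73` = "A", `150` = "C", `152` = "T", `195` = "T", `263` = "A",
             `498` = "C", `4580` = "G", `7765` = "A", `11467` = "A",
             `12308` = "A", `14766` = "C", `16069` = "C", `16126` = "T",
             `16189` = "T", `16192` = "C", `16224` = "T", `16270` = "C",
             `16298` = "T", `16311` = "T", `16519` = "T")
    bases[as.integer(names(pin))] <- pin
    .mtphylo_ref_cache$bases <- bases
  }
  if (as_string) paste(bases, collapse = "") else bases
}

.mtphylo_ref_cache <- new.env(parent = emptyenv())

#' Read a nucleotide sequence from a FASTA file
#'
#' Thin wrapper over [ape::read.FASTA()] returning plain upper-case character
#' vectors, the representation the variant caller works on.
#'
#' @param path FASTA file.
#' @return Named list of character vectors of bases.
#' @export
read_fasta_seqs <- function(path) {
  dna <- ape::read.FASTA(path)
  lapply(as.character(dna), function(x) toupper(unname(x)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named list of character vectors (or single strings) of bases.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta_seqs <- function(seqs, path) {
  stopifnot(length(names(seqs)) == length(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    if (length(s) > 1) s <- paste(s, collapse = "")
    writeLines(c(paste0(">", nm), gsub("(.{70})", "\\1\n", s)), con)
  }
  invisible(path)
}

ref_base_at <- function(reference, pos) {
  if (is.character(reference) && length(reference) == 1L)
    reference <- strsplit(reference, "")[[1]]
  reference[pos]
}
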