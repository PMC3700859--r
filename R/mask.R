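#' Mutational hotspot mask
#'
#' Hypermutable control-region sites are conventionally excluded from mtDNA
#' phylogenetic reconstruction: they recur so often that they carry
#' essentially no genealogical signal. The default mask excludes the classic
#' point hotspots 16182, 16183 and 16519, all variation in the HVS-II poly-C
#' tract (303–315) and the AC dinucleotide repeat (522–524), and every
#' length-heteroplasmy token (poly-C insertion runs) wherever it falls.
#'
#' @param positions integer vector of individually masked positions.
#' @param intervals two-column matrix (or list of `c(from, to)`) of closed
#'   masked intervals.
#' @param exclude_length_heteroplasmy drop length-variant tokens everywhere,
#'   not only inside masked intervals.
#' @return An object of class `hotspot_mask`.
#' @export
#' @examples
#' m <- hotspot_mask()
#' is_masked(c("16519", "73", "309.1C"), m)
hotspot_mask <- function(positions = c(16182L, 16183L, 16519L),
                         intervals = list(c(303L, 315L), c(522L, 524L)),
                         exclude_length_heteroplasmy = TRUE) {
  if (is.matrix(intervals)) intervals <- asplit(intervals, 1)
  intervals <- lapply(intervals, function(iv) {
    stopifnot(length(iv) == 2L, iv[1] <= iv[2])
    as.integer(iv)
  })
  structure(list(positions = sort(unique(as.integer(positions))),
                 intervals = intervals,
                 exclude_length_heteroplasmy = isTRUE(exclude_length_heteroplasmy)),
            class = "hotspot_mask")
}

#' @export
print.hotspot_mask <- function(x, ...) {
  ivs <- vapply(x$intervals, function(iv) paste(iv, collapse = "-"), "")
  cat("<hotspot_mask> positions:", paste(x$positions, collapse = ", "),
      "| intervals:", paste(ivs, collapse = ", "),
      "| length heteroplasmy excluded:", x$exclude_length_heteroplasmy, "\n")
  invisible(x)
}

#' Which variant tokens fall under a mask?
#'
#' @param labels character vector of variant tokens.
#' @param mask a [hotspot_mask()].
#' @param reference reference sequence used to parse tokens.
#' @return logical vector.
#' @export
is_masked <- function(labels, mask = hotspot_mask(),
                      reference = synthetic_rcrs()) {
  df <- parse_variants(labels, reference)
  df <- df[match(canonical_variants(labels, reference), df$label), , drop = FALSE]
  hit <- df$position %in% mask$positions
  for (iv in mask$intervals) hit <- hit | (df$position >= iv[1] & df$position <= iv[2])
  if (mask$exclude_length_heteroplasmy) hit <- hit | df$length_variant
  hit
}

#' Remove hotspot and length-heteroplasmy variants from a haplotype
#'
#' Returns a copy of the haplotype with every variant at a masked position or
#' inside a masked interval removed, along with all length-variant tokens if
#' the mask excludes them. Idempotent; the input is untouched.
#'
#' @param hap a [haplotype()].
#' @param mask a [hotspot_mask()].
#' @param reference reference sequence.
#' @return The masked haplotype; attribute `"n_masked"` records how many
#'   variants were removed (logged by the pipeline for auditability).
#' @export
apply_mask <- function(hap, mask = hotspot_mask(),
                       reference = synthetic_rcrs()) {
  stopifnot(inherits(hap, "mt_haplotype"))
  drop <- is_masked(hap$variants, mask, reference)
  out <- hap
  out$variants <- hap$variants[!drop]
  attr(out, "n_masked") <- sum(drop)
  out
}

#' Read a hotspot mask from a plain-text config file
#'
#' Format: one directive per line; `position <p>`, `interval <from> <to>`,
#' `length_heteroplasmy <true|false>`. `#` starts a comment.
#'
#' @param path config file.
#' @return A [hotspot_mask()].
#' @export
read_mask_config <- function(path) {
  lines <- trimws(sub("#.*$", "", readLines(path)))
  lines <- lines[nzchar(lines)]
  pos <- integer(); ivs <- list(); lh <- TRUE
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\\s+")[[1]]
    switch(f[1],
      position = { pos <- c(pos, as.integer(f[2])) },
      interval = { ivs <- c(ivs, list(as.integer(f[2:3]))) },
      length_heteroplasmy = { lh <- tolower(f[2]) %in% c("true", "yes", "1") },
      stop("line ", i, " of ", path, ": unknown mask directive ", sQuote(f[1]))
    )
  }
  hotspot_mask(pos, ivs, lh)
}
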