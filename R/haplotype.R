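#' An mtDNA haplotype: a sample's variant set plus metadata
#'
#' @param sample_id sample identifier.
#' @param variants character vector of variant tokens (canonicalized on
#'   construction).
#' @param population population label.
#' @param region geographic region label.
#' @param coverage `"complete_genome"`, `"control_region"`, or an explicit
#'   two-column matrix of closed position ranges. The control region is
#'   taken as 16024–16569 plus 1–576 (HVS-I + HVS-II and flanks).
#' @param reference reference sequence used to canonicalize tokens.
#' @return An object of class `mt_haplotype`.
#' @details Invariants enforced: no duplicate (position, kind) pairs, and
#'   every variant must fall inside the declared coverage ranges.
#' @export
#' @examples
#' haplotype("S1", c("16270", "152"), coverage = "control_region")
haplotype <- function(sample_id, variants = character(), population = "",
                      region = "", coverage = "complete_genome",
                      reference = synthetic_rcrs()) {
  ranges <- coverage_ranges(coverage)
  df <- parse_variants(variants, reference)
  key <- paste(df$position, df$kind,
               ifelse(is.na(df$ins_index), "", df$ins_index))
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate variant at position(s) ",
         paste(df$position[dup], collapse = ", "), " in sample ", sample_id)
  }
  outside <- !position_covered(df$position, ranges)
  if (any(outside)) {
    stop("variant(s) ", paste(df$label[outside], collapse = ", "),
         " outside declared coverage of sample ", sample_id)
  }
  structure(list(sample_id = as.character(sample_id),
                 population = as.character(population),
                 region = as.character(region),
                 variants = df$label,
                 coverage = coverage_label(coverage),
                 coverage_ranges = ranges),
            class = "mt_haplotype")
}

CONTROL_REGION_RANGES <- rbind(c(16024L, 16569L), c(1L, 576L))

coverage_ranges <- function(coverage) {
  if (is.matrix(coverage)) {
    stopifnot(ncol(coverage) == 2L, nrow(coverage) >= 1L,
              all(coverage[, 1] <= coverage[, 2]))
    return(matrix(as.integer(coverage), ncol = 2L))
  }
  switch(as.character(coverage),
    complete_genome = rbind(c(1L, 16569L)),
    control_region  = CONTROL_REGION_RANGES,
    { # "a-b;c-d" textual form
      parts <- strsplit(strsplit(coverage, ";")[[1]], "-")
      do.call(rbind, lapply(parts, function(p) as.integer(p)))
    })
}

coverage_label <- function(coverage) {
  if (!is.matrix(coverage)) return(as.character(coverage))
  paste(apply(coverage, 1, paste, collapse = "-"), collapse = ";")
}

position_covered <- function(pos, ranges) {
  if (!length(pos)) return(logical(0))
  Reduce(`|`, lapply(seq_len(nrow(ranges)), function(i) {
    pos >= ranges[i, 1] & pos <= ranges[i, 2]
  }))
}

#' @export
print.mt_haplotype <- function(x, ...) {
  cat("<mt_haplotype> ", x$sample_id,
      if (nzchar(x$population)) paste0(" (", x$population, ")"),
      " [", x$coverage, "]\n  ",
      if (length(x$variants)) paste(x$variants, collapse = " ") else "(reference)",
      "\n", sep = "")
  invisible(x)
}

#' Read / write a haplotype table
#'
#' Tab-separated, one sample per row, in the style of published mitogenome
#' supplementary tables: columns `sample_id`, `population`, `region`,
#' `coverage`, `variants` (space-separated branch-notation tokens).
#'
#' @param path file path.
#' @param reference reference sequence for token canonicalization.
#' @return `read_haplotype_table()`: a list of [haplotype()] objects.
#' @export
read_haplotype_table <- function(path, reference = synthetic_rcrs()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "population", "region", "coverage", "variants")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("haplotype table ", path, " lacks column(s) ",
         paste(miss, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    haplotype(df$sample_id[i],
              variants = df$variants[i],
              population = df$population[i], region = df$region[i],
              coverage = df$coverage[i], reference = reference)
  })
}

#' @rdname read_haplotype_table
#' @param haps list of [haplotype()] objects.
#' @export
write_haplotype_table <- function(haps, path) {
  df <- data.frame(
    sample_id = vapply(haps, `[[`, "", "sample_id"),
    population = vapply(haps, `[[`, "", "population"),
    region = vapply(haps, `[[`, "", "region"),
    coverage = vapply(haps, `[[`, "", "coverage"),
    variants = vapply(haps, function(h) paste(h$variants, collapse = " "), ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
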