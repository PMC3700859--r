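#' Call rCRS-relative variants from an aligned sample sequence
#'
#' Bridges FASTA inputs to the branch-notation variant lists the rest of the
#' pipeline consumes. The sample must be aligned to the reference: either the
#' two sequences have equal length (gap characters `-` allowed in both, as
#' written by any pairwise aligner), or — if `align = TRUE` and lengths
#' differ — a Needleman–Wunsch alignment is obtained via
#' `Biostrings::pairwiseAlignment()`.
#'
#' Positions follow rCRS numbering throughout, counted on the ungapped
#' reference, so insertions are reported in the `pos.nB` dialect (n-th base
#' inserted after `pos`) and deletions as `"pos del"`. `N` in the sample is
#' treated as no-call and skipped.
#'
#' @param sample_seq sample sequence (string or base vector, `-` for gaps).
#' @param reference reference sequence, same conventions.
#' @param range optional two-column matrix of closed rCRS ranges actually
#'   covered by the sample; differences outside are not called.
#' @param align attempt alignment when ungapped lengths differ.
#' @return Character vector of canonical variant labels, position-sorted.
#' @export
#' @examples
#' ref <- synthetic_rcrs()
#' s <- ref
#' substr(s, 16270, 16270) <- "T"   # reference carries C here
#' call_variants(s, ref)            # "16270"
call_variants <- function(sample_seq, reference = synthetic_rcrs(),
                          range = NULL, align = TRUE) {
  s <- as_base_vector(sample_seq, "sample")
  r <- as_base_vector(reference, "reference", allow_gap = TRUE)
  if (length(s) != length(r)) {
    if (!align) {
      stop("sample and reference lengths differ (", length(s), " vs ",
           length(r), "); supply aligned sequences or align = TRUE")
    }
    aln <- align_pair(paste(s, collapse = ""), paste(r, collapse = ""))
    s <- aln$sample; r <- aln$reference
  }
  if (!is.null(range)) range <- coverage_ranges(range)

  if (!any(s == "-") && !any(r == "-")) {   # substitution-only fast path
    keep <- s != r & s != "N"
    if (!is.null(range)) {
      keep <- keep & position_covered(seq_along(r), range)
      if (!any(position_covered(seq_along(r), range)))
        stop("empty overlap between sample and declared range")
    }
    pos <- which(keep)
    partner <- unname(TRANSITION_PARTNER[r[pos]])
    labels <- ifelse(s[pos] == partner, as.character(pos),
                     paste0(pos, s[pos]))
    return(canonical_variants(labels, r))
  }
  rpos <- cumsum(r != "-")          # rCRS coordinate at each column
  if (max(rpos) == 0L) stop("empty overlap: reference side is all gaps")
  labels <- character(0)
  ins_idx <- 0L
  covered <- function(p) is.null(range) || position_covered(p, range)
  for (i in seq_along(r)) {
    rb <- r[i]; sb <- s[i]
    if (rb != "-") ins_idx <- 0L
    if (sb == "N") next
    if (rb == "-" && sb == "-") next
    if (rb == "-") {                           # insertion after rpos[i]
      ins_idx <- ins_idx + 1L
      if (covered(max(rpos[i], 1L)))
        labels <- c(labels, paste0(max(rpos[i], 1L), ".", ins_idx, sb))
    } else if (sb == "-") {
      if (covered(rpos[i])) labels <- c(labels, paste(rpos[i], "del"))
    } else if (sb != rb) {
      if (covered(rpos[i])) {
        lab <- if (identical(sb, TRANSITION_PARTNER[[rb]])) {
          as.character(rpos[i])
        } else {
          paste0(rpos[i], sb)
        }
        labels <- c(labels, lab)
      }
    }
  }
  if (!is.null(range)) {
    ungapped <- rpos[s != "-" & r != "-"]
    if (!any(position_covered(ungapped, range)))
      stop("empty overlap between sample and declared range")
  }
  canonical_variants(labels, r[r != "-"])
}

as_base_vector <- function(x, what, allow_gap = TRUE) {
  if (is.character(x) && length(x) == 1L) x <- strsplit(x, "")[[1]]
  x <- toupper(x)
  ok <- c("A", "C", "G", "T", "N", if (allow_gap) "-")
  bad <- setdiff(unique(x), ok)
  if (length(bad)) {
    stop("non-nucleotide character(s) in ", what, ": ",
         paste(bad, collapse = ", "))
  }
  x
}

align_pair <- function(sample_str, ref_str) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required to align length-mismatched sequences; ",
         "otherwise supply pre-aligned sequences of equal length")
  }
  pa <- Biostrings::pairwiseAlignment(sample_str, ref_str, type = "global")
  list(sample = strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]],
       reference = strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]])
}

#' Apply a variant set to a reference sequence
#'
#' Inverse of [call_variants()]: builds the sample sequence carrying the
#' given variants. Returns the aligned pair (gap `-` in the sample for
#' deletions, in the reference for insertions) so the caller round-trips
#' through [call_variants()] exactly.
#'
#' @param labels variant tokens; back-mutated tokens (`"@x"`) leave the
#'   reference state untouched.
#' @param reference reference sequence.
#' @return list with aligned `sample` and `reference` base vectors.
#' @export
mutate_sequence <- function(labels, reference = synthetic_rcrs()) {
  r <- as_base_vector(reference, "reference", allow_gap = FALSE)
  df <- parse_variants(labels, reference)
  df <- df[!df$back_mutation, , drop = FALSE]
  s <- r
  ins_after <- vector("list", length(r))
  for (i in seq_len(nrow(df))) {
    p <- df$position[i]
    switch(df$kind[i],
      transition   = { s[p] <- TRANSITION_PARTNER[[r[p]]] },
      transversion = { s[p] <- df$derived_base[i] },
      deletion     = { s[p] <- "-" },
      insertion    = {
        ins <- ins_after[[p]]
        ins[df$ins_index[i]] <- df$derived_base[i]
        ins_after[[p]] <- ins
      })
  }
  ins_points <- which(!vapply(ins_after, is.null, TRUE))
  if (!length(ins_points)) return(list(sample = s, reference = r))
  bounds <- c(0L, ins_points, length(r))
  out_s <- list(); out_r <- list()
  for (k in seq_along(ins_points) + 1L) {
    seg <- (bounds[k - 1L] + 1L):bounds[k]
    ins <- ins_after[[bounds[k]]]
    ins[is.na(ins)] <- "N"
    out_s[[length(out_s) + 1L]] <- c(s[seg], ins)
    out_r[[length(out_r) + 1L]] <- c(r[seg], rep("-", length(ins)))
  }
  tail_seg <- if (bounds[length(bounds) - 1L] < length(r))
    (bounds[length(bounds) - 1L] + 1L):length(r) else integer(0)
  list(sample = c(unlist(out_s), s[tail_seg]),
       reference = c(unlist(out_r), r[tail_seg]))
}
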