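#' @title rCRS-relative variant notation
#'
#' @description
#' Variants are written in the branch-label notation customary in mtDNA
#' cladograms, relative to the rCRS coordinate frame (1..16569):
#'
#' * a bare position (`"7765"`) is a **transition** of the reference base
#'   (A\eqn{\leftrightarrow}G, C\eqn{\leftrightarrow}T);
#' * a base suffix (`"152A"`) names the derived base; if it is not the
#'   transition partner of the reference base the change is a
#'   **transversion**;
#' * the prefix `"@"` (`"@150"`) marks a **back mutation**, a reversion to
#'   the reference state;
#' * insertions use the `pos.nB` dialect (`"309.1C"` = one C inserted after
#'   np 309); runs of inserted C are the length-heteroplasmy token class;
#' * deletions are written `"523 del"` (also accepted: `523del`, `523d`).
#'
#' @name variant-notation
NULL

TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
PURINES <- c("A", "G")

#' Parse one variant token
#'
#' @param token character scalar in branch-label notation (see
#'   [variant-notation]).
#' @param reference reference sequence (string or base vector); defaults to
#'   the bundled synthetic rCRS-like reference.
#' @return An object of class `rcrs_variant`: a list with fields `position`,
#'   `kind` (`"transition"`, `"transversion"`, `"insertion"`, `"deletion"`),
#'   `derived_base` (`NA` unless transversion/insertion), `ins_index`,
#'   `back_mutation`, `length_variant` and the canonical `label`.
#' @export
#' @examples
#' parse_variant("7765")        # transition at np 7765
#' parse_variant("@150")        # back mutation
#' parse_variant("152A")        # transversion (reference carries T)
#' parse_variant("309.1C")      # insertion, length-variant class
parse_variant <- function(token, reference = synthetic_rcrs()) {
  stopifnot(is.character(token), length(token) == 1L)
  tok <- trimws(token)
  back <- startsWith(tok, "@")
  if (back) tok <- substring(tok, 2L)

  if (grepl("^([0-9]+)\\s*(del|d)$", tok)) {
    pos <- as.integer(sub("^([0-9]+)\\s*(del|d)$", "\\1", tok))
    return(new_variant(pos, "deletion", NA_character_, NA_integer_, back))
  }
  m <- regmatches(tok, regexec("^([0-9]+)\\.([0-9]+)([ACGT])$", tok))[[1]]
  if (length(m)) {
    pos <- as.integer(m[2]); n_ins <- as.integer(m[3]); base <- m[4]
    check_pos(pos)
    if (n_ins < 1L) stop("insertion count must be >= 1 in token ", sQuote(token))
    return(new_variant(pos, "insertion", base, n_ins, back,
                       length_variant = base == "C"))
  }
  m <- regmatches(tok, regexec("^([0-9]+)([ACGT]?)$", tok))[[1]]
  if (!length(m)) stop("malformed variant token ", sQuote(token))
  pos <- as.integer(m[2]); suffix <- m[3]
  check_pos(pos)
  ref <- ref_base_at(reference, pos)
  if (!nzchar(suffix) || identical(suffix, TRANSITION_PARTNER[[ref]])) {
    return(new_variant(pos, "transition", NA_character_, NA_integer_, back))
  }
  if (identical(suffix, ref)) {
    stop("suffix of ", sQuote(token), " equals the reference base (", ref, ")")
  }
  new_variant(pos, "transversion", suffix, NA_integer_, back)
}

new_variant <- function(position, kind, derived_base, ins_index, back_mutation,
                        length_variant = FALSE) {
  v <- list(position = position, kind = kind, derived_base = derived_base,
            ins_index = ins_index, back_mutation = back_mutation,
            length_variant = length_variant)
  v$label <- format_variant(v)
  structure(v, class = "rcrs_variant")
}

check_pos <- function(pos) {
  if (is.na(pos) || pos < 1L || pos > 16569L)
    stop("position ", pos, " outside the rCRS range 1..16569")
  invisible(pos)
}

#' Canonical label of a variant
#'
#' Inverse of [parse_variant()]: `format_variant(parse_variant(x))` is the
#' identity on canonical labels (transitions are written bare, without the
#' redundant base suffix).
#'
#' @param v an `rcrs_variant`.
#' @return character scalar.
#' @export
format_variant <- function(v) {
  core <- switch(v$kind,
    transition   = as.character(v$position),
    transversion = paste0(v$position, v$derived_base),
    insertion    = paste0(v$position, ".", v$ins_index, v$derived_base),
    deletion     = paste0(v$position, " del"),
    stop("unknown variant kind ", sQuote(v$kind))
  )
  if (isTRUE(v$back_mutation)) paste0("@", core) else core
}

#' @export
print.rcrs_variant <- function(x, ...) {
  cat("<rcrs_variant> ", x$label, "  [", x$kind,
      if (x$back_mutation) ", back mutation", "]\n", sep = "")
  invisible(x)
}

#' Parse a vector (or space-separated string) of variant tokens
#'
#' Splits on whitespace, re-joining the two-token deletion form
#' (`"523 del"`), parses each token and returns a data frame, one row per
#' variant, ordered by position.
#'
#' @param tokens character vector of tokens, or a single space-separated
#'   string.
#' @inheritParams parse_variant
#' @return data frame with columns `label`, `position`, `kind`,
#'   `derived_base`, `ins_index`, `back_mutation`, `length_variant`.
#' @export
parse_variants <- function(tokens, reference = synthetic_rcrs()) {
  tokens <- tokenize_variants(tokens)
  if (!length(tokens)) {
    return(data.frame(label = character(), position = integer(),
                      kind = character(), derived_base = character(),
                      ins_index = integer(), back_mutation = logical(),
                      length_variant = logical(), stringsAsFactors = FALSE))
  }
  rows <- lapply(tokens, function(t) {
    v <- parse_variant(t, reference)
    data.frame(label = v$label, position = v$position, kind = v$kind,
               derived_base = v$derived_base, ins_index = v$ins_index,
               back_mutation = v$back_mutation,
               length_variant = v$length_variant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(label = character(), position = integer(),
                      kind = character(), derived_base = character(),
                      ins_index = integer(), back_mutation = logical(),
                      length_variant = logical(), stringsAsFactors = FALSE)
  }
  out[order(out$position, out$label), , drop = FALSE]
}

tokenize_variants <- function(tokens) {
  if (length(tokens) == 1L && grepl("\\s", tokens)) {
    tokens <- strsplit(trimws(tokens), "\\s+")[[1]]
  }
  tokens <- tokens[nzchar(tokens)]
  # re-join "<pos> del"
  if (length(tokens) > 1L) {
    is_del <- tolower(tokens) %in% c("del", "d")
    join <- which(is_del & c(FALSE, grepl("^@?[0-9]+$", utils::head(tokens, -1))))
    if (length(join)) {
      tokens[join - 1L] <- paste(tokens[join - 1L], "del")
      tokens <- tokens[-join]
    }
  }
  tokens
}

#' Canonicalize variant tokens
#'
#' Parses and re-formats, so equivalent spellings collapse to one canonical
#' label (e.g. `"152C"` with reference T becomes the bare transition
#' `"152"`).
#'
#' @inheritParams parse_variants
#' @return character vector of canonical labels, position-sorted.
#' @export
canonical_variants <- function(tokens, reference = synthetic_rcrs()) {
  parse_variants(tokens, reference)$label
}

variant_site <- function(labels) {
  as.integer(sub("^@?([0-9]+).*$", "\\1", labels))
}

strip_back <- function(labels) sub("^@", "", labels)
is_back <- function(labels) startsWith(labels, "@")
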