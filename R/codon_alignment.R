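#' Construct a validated codon alignment
#'
#' A codon alignment holds two or more pre-aligned coding sequences of equal
#' length over the alphabet `A C G T -`. The alignment length must be a
#' multiple of three, gap runs must be codon-aligned (every run of `-` has a
#' length divisible by three and starts on a codon boundary), and no sequence
#' may contain an internal in-frame stop codon (a stop at the terminal codon
#' is allowed and can be removed with [strip_terminal_stops()]).
#'
#' Coordinates are 1-based throughout: codon `i` of a sequence occupies
#' nucleotides `3i - 2` to `3i`, and residue numbering on a reference protein
#' is the 1-based position in its ungapped translation.
#'
#' @param sequences character vector of aligned nucleotide sequences
#'   (lower-case accepted and upper-cased; `U` is rejected).
#' @param names sequence identifiers; defaults to the names of `sequences`.
#' @return An object of class `codon_alignment`: a list with elements
#'   `names`, `sequences` (upper-cased), `length` (nucleotides) and
#'   `n_codons`.
#' @examples
#' aln <- codon_alignment(c(a = "ATGGCT", b = "ATGGCA"))
#' aln$n_codons
#' @export
codon_alignment <- function(sequences, names = base::names(sequences)) {
  if (is.null(names)) {
    names <- paste0("seq", seq_along(sequences))
  }
  if (length(sequences) < 2) {
    stop("a codon alignment needs at least 2 sequences", call. = FALSE)
  }
  if (anyDuplicated(names)) {
    stop("duplicated sequence identifiers: ",
         paste(unique(names[duplicated(names)]), collapse = ", "),
         call. = FALSE)
  }
  sequences <- toupper(as.character(sequences))
  for (i in seq_along(sequences)) {
    .validate_codon_sequence(sequences[i], names[i])
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequence lengths ",
         paste(lens, collapse = ", "), call. = FALSE)
  }
  structure(
    list(names = names, sequences = unname(sequences),
         length = lens[1], n_codons = lens[1] %/% 3L),
    class = "codon_alignment"
  )
}

# Per-record validation; error messages name the offending record.
.validate_codon_sequence <- function(seq, name) {
  if (grepl("U", seq, fixed = TRUE)) {
    stop(sprintf("record '%s': contains U (RNA); DNA input required", name),
         call. = FALSE)
  }
  bad <- gsub("[ACGT-]", "", seq)
  if (nchar(bad) > 0) {
    stop(sprintf("record '%s': illegal characters '%s'", name,
                 paste(unique(strsplit(bad, "")[[1]]), collapse = "")),
         call. = FALSE)
  }
  if (nchar(seq) %% 3L != 0L) {
    stop(sprintf("record '%s': length %d not multiple of 3", name, nchar(seq)),
         call. = FALSE)
  }
  # gap runs must cover whole codons: length divisible by 3 and
  # codon-boundary aligned
  m <- gregexpr("-+", seq)[[1]]
  if (m[1] != -1) {
    runs <- attr(m, "match.length")
    starts <- as.integer(m)
    if (any(runs %% 3L != 0L) || any((starts - 1L) %% 3L != 0L)) {
      stop(sprintf("record '%s': gap run not codon-aligned", name),
           call. = FALSE)
    }
  }
  codons <- .split_codons(seq)
  aa <- .translate_codons(codons, allow_gap = TRUE)
  internal <- aa[-length(aa)]
  if (any(internal == "*")) {
    stop(sprintf("record '%s': internal stop codon at codon %d", name,
                 which(internal == "*")[1]), call. = FALSE)
  }
  invisible(TRUE)
}

.split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# genetic-code lookup shared by translate() and the codon machinery
.genetic_code <- function() Biostrings::GENETIC_CODE

.translate_codons <- function(codons, allow_gap = FALSE) {
  gc <- .genetic_code()
  aa <- unname(gc[codons])
  if (allow_gap) aa[codons == "---"] <- "-"
  aa
}

#' Read a codon alignment from a FASTA file
#'
#' Records must be pre-aligned; all [codon_alignment()] invariants are
#' checked and violations raise errors naming the offending record.
#' Input order and identifiers are preserved.
#'
#' @param path path to a multi-record FASTA file (wrapped or unwrapped).
#' @return A [codon_alignment()].
#' @export
read_codon_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) < 2) {
    stop("FASTA must contain at least 2 records, got ", length(recs),
         call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(recs))
  codon_alignment(as.character(recs), names = ids)
}

#' Write a codon alignment to FASTA
#'
#' @param x a [codon_alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_codon_fasta <- function(x, path) {
  stopifnot(inherits(x, "codon_alignment"))
  set <- Biostrings::BStringSet(x$sequences)
  names(set) <- x$names
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Translate an ungapped coding sequence
#'
#' Standard genetic code; stop codons are rendered as `*`.
#'
#' @param codon_sequence nucleotide string, ungapped, length a multiple of 3.
#' @return Protein string.
#' @examples
#' translate("ATGTTT")  # "MF"
#' @export
translate <- function(codon_sequence) {
  codon_sequence <- toupper(codon_sequence)
  if (nchar(codon_sequence) %% 3L != 0L) {
    stop("sequence length not a multiple of 3", call. = FALSE)
  }
  if (grepl("-", codon_sequence, fixed = TRUE)) {
    stop("translate() requires an ungapped sequence", call. = FALSE)
  }
  codons <- .split_codons(codon_sequence)
  aa <- .translate_codons(codons)
  if (anyNA(aa)) {
    stop("ambiguous or illegal base in codon(s) at position(s): ",
         paste(which(is.na(aa)), collapse = ", "), call. = FALSE)
  }
  paste(aa, collapse = "")
}

#' Extract one codon from an aligned sequence
#'
#' @param alignment a [codon_alignment()].
#' @param name sequence identifier.
#' @param codon_index 1-based codon position; gap codons (`---`) are
#'   returned verbatim.
#' @return Three-character codon string.
#' @export
codon_at <- function(alignment, name, codon_index) {
  stopifnot(inherits(alignment, "codon_alignment"))
  i <- match(name, alignment$names)
  if (is.na(i)) stop("no sequence named '", name, "'", call. = FALSE)
  if (!is.numeric(codon_index) || codon_index < 1 ||
      codon_index > alignment$n_codons || codon_index != round(codon_index)) {
    stop("codon_index out of range [1, ", alignment$n_codons, "]",
         call. = FALSE)
  }
  substr(alignment$sequences[i], 3L * codon_index - 2L, 3L * codon_index)
}

#' Remove terminal stop codons from an alignment
#'
#' Site and difference counting operates on sense codons only, so a final
#' codon column in which every ungapped sequence carries a stop is dropped.
#'
#' @param x a [codon_alignment()].
#' @return A [codon_alignment()] without the terminal stop column, or `x`
#'   unchanged if the last column is not all-stop.
#' @export
strip_terminal_stops <- function(x) {
  stopifnot(inherits(x, "codon_alignment"))
  last <- vapply(x$sequences, function(s)
    substr(s, x$length - 2L, x$length), character(1))
  aa <- .translate_codons(last, allow_gap = TRUE)
  if (all(aa %in% c("*", "-"))) {
    seqs <- substr(x$sequences, 1L, x$length - 3L)
    return(codon_alignment(seqs, names = x$names))
  }
  x
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon alignment: %d sequences x %d nt (%d codons)\n",
              length(x$names), x$length, x$n_codons))
  for (i in seq_along(x$names)) {
    s <- x$sequences[i]
    shown <- if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s
    cat(sprintf("  %-12s %s\n", x$names[i], shown))
  }
  invisible(x)
}

# Map aligned codon index -> 1-based residue position on the ungapped
# reference (NA where the reference is gapped).
.reference_residue_map <- function(ref_seq) {
  codons <- .split_codons(ref_seq)
  ungapped <- codons != "---"
  pos <- cumsum(ungapped)
  pos[!ungapped] <- NA_integer_
  pos
}
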