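#' Reconstruct the pre-duplication ancestor by outgroup parsimony
#'
#' Given a codon-aligned trio (two paralogs plus an outgroup ortholog), each
#' codon column is classified by the parsimony rule on a three-taxon tree
#' rooted by the outgroup:
#'
#' * **invariant** - all three codons identical;
#' * **lineage1** / **lineage2** - one paralog differs from the other
#'   paralog and the outgroup, which agree: a substitution on that paralog's
#'   branch since duplication;
#' * **shared** - the paralogs agree but the outgroup differs: the change
#'   predates the duplication (or occurred on the outgroup branch), so it is
#'   excluded from lineage event lists;
#' * **ambiguous** - all three states differ: the ancestral state cannot be
#'   polarised and the column is excluded and reported.
#'
#' A run of consecutive gap codons present in exactly one paralog is one
#' indel event on that lineage, whatever its codon span. Columns where the
#' outgroup is gapped, or both paralogs are gapped, cannot be polarised and
#' are classified `unalignable`.
#'
#' The inferred ancestor equals the outgroup codon at every non-shared,
#' non-ambiguous column and the common paralog codon at shared columns.
#' Residue coordinates of events refer to the ungapped outgroup protein.
#'
#' @param trio a [codon_alignment()] with exactly three sequences.
#' @param roles character vector of length 3 naming which records are
#'   `paralog1`, `paralog2` and `outgroup`, e.g.
#'   `c(paralog1 = "BsFLC1", paralog2 = "BsFLC2", outgroup = "AtFLC")`.
#'   Defaults to record order: paralog 1, paralog 2, outgroup.
#' @return An object of class `ancestral_assignment`: a list with the
#'   aligned trio, `ancestor` (aligned codon string, `NNN` at ambiguous
#'   columns), `classification` (factor, one level per codon column),
#'   `events` (data frame of [substitution events][substitution_events] with
#'   columns `lineage`, `codon_index`, `aa_position`, `kind`, `nt_from`,
#'   `nt_to`, `aa_from`, `aa_to`, `synonymous`, `span_codons`),
#'   `ambiguous_sites`, `shared_sites` and `residue_map`.
#' @export
reconstruct_ancestor <- function(trio, roles = NULL) {
  stopifnot(inherits(trio, "codon_alignment"))
  if (length(trio$names) != 3L) {
    stop("expected exactly three sequences (paralog1, paralog2, outgroup), got ",
         length(trio$names), call. = FALSE)
  }
  if (is.null(roles)) {
    roles <- stats::setNames(trio$names, c("paralog1", "paralog2", "outgroup"))
  }
  need <- c("paralog1", "paralog2", "outgroup")
  if (!all(need %in% names(roles)) || !all(roles[need] %in% trio$names)) {
    stop("roles must map paralog1/paralog2/outgroup to record names: ",
         paste(trio$names, collapse = ", "), call. = FALSE)
  }
  trio <- strip_terminal_stops(trio)
  p1 <- .split_codons(trio$sequences[match(roles[["paralog1"]], trio$names)])
  p2 <- .split_codons(trio$sequences[match(roles[["paralog2"]], trio$names)])
  og <- .split_codons(trio$sequences[match(roles[["outgroup"]], trio$names)])
  n <- trio$n_codons
  res_map <- .reference_residue_map(trio$sequences[match(roles[["outgroup"]],
                                                         trio$names)])

  gap <- function(x) x == "---"
  cls <- character(n)
  anc <- og
  for (j in seq_len(n)) {
    g1 <- gap(p1[j]); g2 <- gap(p2[j]); go <- gap(og[j])
    if (go || (g1 && g2)) {
      cls[j] <- "unalignable"
    } else if (g1) {
      cls[j] <- "indel1"
    } else if (g2) {
      cls[j] <- "indel2"
    } else if (p1[j] == p2[j] && p2[j] == og[j]) {
      cls[j] <- "invariant"
    } else if (p1[j] == og[j]) {
      cls[j] <- "lineage2"
    } else if (p2[j] == og[j]) {
      cls[j] <- "lineage1"
    } else if (p1[j] == p2[j]) {
      cls[j] <- "shared"
      anc[j] <- p1[j]
    } else {
      cls[j] <- "ambiguous"
      anc[j] <- "NNN"
    }
  }

  events <- .collect_events(cls, anc, p1, p2, res_map)
  structure(
    list(
      names = stats::setNames(unname(roles[need]), need),
      alignment = trio,
      ancestor = paste(anc, collapse = ""),
      classification = factor(cls, levels = c(
        "invariant", "lineage1", "lineage2", "shared", "ambiguous",
        "indel1", "indel2", "unalignable")),
      events = events,
      ambiguous_sites = which(cls == "ambiguous"),
      shared_sites = which(cls == "shared"),
      residue_map = res_map
    ),
    class = "ancestral_assignment"
  )
}

# Build the event table: one row per point-substitution codon, one row per
# contiguous indel run.
.collect_events <- function(cls, anc, p1, p2, res_map) {
  rows <- list()
  add <- function(lineage, j, kind, from, to, span = 1L) {
    aa_from <- aa_to <- NA_character_
    syn <- NA
    if (kind == "point") {
      aa_from <- .translate_codons(from)
      aa_to <- .translate_codons(to)
      syn <- identical(aa_from, aa_to)
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      lineage = lineage, codon_index = j, aa_position = res_map[j],
      kind = kind, nt_from = from, nt_to = to,
      aa_from = aa_from, aa_to = aa_to, synonymous = syn,
      span_codons = span, stringsAsFactors = FALSE)
  }
  for (lin in 1:2) {
    point_cls <- paste0("lineage", lin)
    indel_cls <- paste0("indel", lin)
    desc <- if (lin == 1) p1 else p2
    j <- 1L
    n <- length(cls)
    while (j <= n) {
      if (cls[j] == point_cls) {
        add(lin, j, "point", anc[j], desc[j])
        j <- j + 1L
      } else if (cls[j] == indel_cls) {
        k <- j
        while (k < n && cls[k + 1L] == indel_cls) k <- k + 1L
        span <- k - j + 1L
        add(lin, j, "indel",
            paste(anc[j:k], collapse = ""),
            strrep("-", 3L * span), span)
        j <- k + 1L
      } else {
        j <- j + 1L
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(
      lineage = integer(), codon_index = integer(), aa_position = integer(),
      kind = character(), nt_from = character(), nt_to = character(),
      aa_from = character(), aa_to = character(), synonymous = logical(),
      span_codons = integer(), stringsAsFactors = FALSE))
  }
  ev <- do.call(rbind, rows)
  ev[order(ev$lineage, ev$codon_index), , drop = FALSE]
}

#' Substitution events of an ancestral assignment
#'
#' @param assignment an [reconstruct_ancestor()] result.
#' @param lineage optional: restrict to lineage 1 or 2.
#' @return The event data frame (see [reconstruct_ancestor()]).
#' @export
substitution_events <- function(assignment, lineage = NULL) {
  stopifnot(inherits(assignment, "ancestral_assignment"))
  ev <- assignment$events
  if (!is.null(lineage)) ev <- ev[ev$lineage == lineage, , drop = FALSE]
  ev
}

#' @export
print.ancestral_assignment <- function(x, ...) {
  tab <- table(x$classification)
  cat("ancestral assignment (outgroup parsimony)\n")
  cat(sprintf("  paralog1=%s paralog2=%s outgroup=%s\n",
              x$names[["paralog1"]], x$names[["paralog2"]],
              x$names[["outgroup"]]))
  cat(sprintf("  %d codon columns: %s\n", length(x$classification),
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  ev <- x$events
  for (lin in 1:2) {
    e <- ev[ev$lineage == lin, , drop = FALSE]
    cat(sprintf("  lineage %d: %d events (%d syn, %d nonsyn, %d indel)\n",
                lin, nrow(e), sum(e$synonymous %in% TRUE),
                sum(e$synonymous %in% FALSE), sum(e$kind == "indel")))
  }
  invisible(x)
}
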