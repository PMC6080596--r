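#' Simulate a codon-alignment trio with planted substitution truth
#'
#' Generates a random ancestral coding sequence (codons drawn uniformly
#' from the 61 sense codons), evolves two paralog lineages by planting an
#' exact number of point substitutions on each (at distinct codons, so the
#' planted truth is recoverable without ambiguity), optionally concentrates
#' nonsynonymous changes of lineage 2 inside a protein domain, optionally
#' deletes a contiguous run of whole codons from lineage 2, and derives the
#' outgroup from the ancestor by an independent small set of changes placed
#' away from all planted-event codons (so outgroup parsimony polarises
#' every planted event correctly).
#'
#' The defaults emulate a duplicate pair in which lineage 1 carries three
#' changes (one synonymous, two nonsynonymous) and lineage 2 carries ten
#' (one synonymous, eight nonsynonymous, one three-codon in-frame
#' deletion) on a 196-residue protein, with the nonsynonymous changes of
#' lineage 2 concentrated on a K-box-like domain spanning residues 83-170.
#'
#' @param n_codons protein length in codons (default 196).
#' @param n_events_lineage1,n_events_lineage2 planted point-substitution
#'   counts (defaults 3 and 9).
#' @param syn_fraction_lineage1,syn_fraction_lineage2 fraction of each
#'   lineage's point events that are synonymous (defaults 1/3 and 1/9; the
#'   planted synonymous count is `round(fraction * n_events)`).
#' @param domain a [domain_annotation()] with
#'   `protein_length == n_codons`, or `NULL` for no domain structure.
#' @param domain_concentration probability that each nonsynonymous event on
#'   lineage 2 is placed inside the domain (default 8/9, i.e. eight of
#'   nine changes expected in-domain).
#' @param n_codon_deletions_lineage2 number of codons removed from
#'   lineage 2 in a single contiguous in-frame deletion (default 3; 0 for
#'   none).
#' @param n_outgroup_changes substitutions placed on the outgroup branch
#'   (default 5).
#' @param seed integer seed; the trio is a deterministic function of the
#'   arguments and the seed.
#' @return A list with `alignment` (the [codon_alignment()] trio named
#'   `paralog1`, `paralog2`, `outgroup`), `ancestor` (ungapped ancestral
#'   sequence) and `truth`, a data frame of planted events with columns
#'   `lineage`, `codon_index`, `aa_position`, `kind`, `nt_from`, `nt_to`,
#'   `synonymous`, `in_domain`, `span_codons`.
#' @export
simulate_trio <- function(n_codons = 196L,
                          n_events_lineage1 = 3L,
                          n_events_lineage2 = 9L,
                          syn_fraction_lineage1 = 1 / 3,
                          syn_fraction_lineage2 = 1 / 9,
                          domain = domain_annotation("K-box", 83, 170,
                                                     n_codons),
                          domain_concentration = 8 / 9,
                          n_codon_deletions_lineage2 = 3L,
                          n_outgroup_changes = 5L,
                          seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (!is.null(domain)) {
    stopifnot(inherits(domain, "domain_annotation"))
    if (domain$protein_length != n_codons) {
      stop("domain protein_length must equal n_codons", call. = FALSE)
    }
  }
  stopifnot(domain_concentration >= 0, domain_concentration <= 1)
  total_events <- n_events_lineage1 + n_events_lineage2 +
    n_codon_deletions_lineage2 + n_outgroup_changes
  if (total_events > n_codons) {
    stop("not enough codons (", n_codons, ") for ", total_events,
         " planted changes", call. = FALSE)
  }
  .with_seed(seed, {
    gc <- .genetic_code()
    sense <- names(gc)[gc != "*"]
    # synonymous planting needs a codon with a synonymous single-nt
    # neighbour; all sense codons except ATG and TGG have one
    has_syn <- vapply(sense, function(cd)
      .n_syn_neighbours(cd) > 0, logical(1))

    ancestor <- sample(sense, n_codons, replace = TRUE)
    used <- rep(FALSE, n_codons)

    plant_points <- function(n_ev, syn_frac, concentrate) {
      n_syn <- round(syn_frac * n_ev)
      n_non <- n_ev - n_syn
      ev <- NULL
      for (i in seq_len(n_syn)) {
        cand <- which(!used & has_syn[ancestor])
        if (length(cand) == 0) stop("no codon available for synonymous event",
                                    call. = FALSE)
        j <- if (length(cand) == 1) cand else sample(cand, 1)
        used[j] <<- TRUE
        ev <- rbind(ev, data.frame(codon_index = j, synonymous = TRUE))
      }
      for (i in seq_len(n_non)) {
        in_dom <- !is.null(domain) && concentrate &&
          stats::runif(1) < domain_concentration
        cand <- which(!used)
        if (in_dom) {
          cd <- cand[cand >= domain$start & cand <= domain$end]
          if (length(cd) > 0) cand <- cd
        } else if (!is.null(domain) && concentrate) {
          cd <- cand[cand < domain$start | cand > domain$end]
          if (length(cd) > 0) cand <- cd
        }
        if (length(cand) == 0) stop("no codon available for event",
                                    call. = FALSE)
        j <- if (length(cand) == 1) cand else sample(cand, 1)
        used[j] <<- TRUE
        ev <- rbind(ev, data.frame(codon_index = j, synonymous = FALSE))
      }
      ev
    }

    ev1 <- plant_points(n_events_lineage1, syn_fraction_lineage1, FALSE)
    ev2 <- plant_points(n_events_lineage2, syn_fraction_lineage2, TRUE)

    mutate <- function(seq, ev) {
      rows <- NULL
      for (i in seq_len(NROW(ev))) {
        j <- ev$codon_index[i]
        from <- seq[j]
        to <- .draw_neighbour(from, synonymous = ev$synonymous[i])
        seq[j] <- to
        rows <- rbind(rows, data.frame(
          codon_index = j, nt_from = from, nt_to = to,
          synonymous = ev$synonymous[i], stringsAsFactors = FALSE))
      }
      list(seq = seq, rows = rows)
    }

    m1 <- mutate(ancestor, ev1)
    m2 <- mutate(ancestor, ev2)
    p1 <- m1$seq; p2 <- m2$seq

    del_rows <- NULL
    if (n_codon_deletions_lineage2 > 0) {
      span <- n_codon_deletions_lineage2
      starts <- seq_len(n_codons - span + 1L)
      ok <- vapply(starts, function(s) !any(used[s:(s + span - 1L)]),
                   logical(1))
      if (!any(ok)) stop("no room for the planted deletion", call. = FALSE)
      s <- if (sum(ok) == 1) starts[ok] else sample(starts[ok], 1)
      used[s:(s + span - 1L)] <- TRUE
      del_rows <- data.frame(
        codon_index = s, nt_from = paste(ancestor[s:(s + span - 1L)],
                                         collapse = ""),
        nt_to = strrep("-", 3L * span), synonymous = NA,
        stringsAsFactors = FALSE)
      p2[s:(s + span - 1L)] <- "---"
    }

    # outgroup branch: changes at codons untouched by any planted event
    og <- ancestor
    if (n_outgroup_changes > 0) {
      cand <- which(!used)
      picks <- sample(cand, min(n_outgroup_changes, length(cand)))
      for (j in picks) og[j] <- .draw_neighbour(og[j], synonymous = NA)
    }

    aln <- codon_alignment(
      c(paralog1 = paste(p1, collapse = ""),
        paralog2 = paste(p2, collapse = ""),
        outgroup = paste(og, collapse = "")))

    pieces <- list()
    if (!is.null(m1$rows)) {
      pieces$l1 <- cbind(lineage = 1L, m1$rows, kind = "point",
                         span_codons = 1L)
    }
    if (!is.null(m2$rows)) {
      pieces$l2 <- cbind(lineage = 2L, m2$rows, kind = "point",
                         span_codons = 1L)
    }
    if (!is.null(del_rows)) {
      pieces$del <- cbind(lineage = 2L, del_rows, kind = "indel",
                          span_codons = n_codon_deletions_lineage2)
    }
    truth <- if (length(pieces) > 0) do.call(rbind, pieces) else data.frame(
      lineage = integer(), codon_index = integer(), nt_from = character(),
      nt_to = character(), synonymous = logical(), kind = character(),
      span_codons = integer(), stringsAsFactors = FALSE)
    truth$aa_position <- truth$codon_index
    truth$in_domain <- if (is.null(domain)) NA else
      truth$aa_position >= domain$start & truth$aa_position <= domain$end
    truth <- truth[order(truth$lineage, truth$codon_index),
                   c("lineage", "codon_index", "aa_position", "kind",
                     "nt_from", "nt_to", "synonymous", "in_domain",
                     "span_codons")]
    rownames(truth) <- NULL
    list(alignment = aln, ancestor = paste(ancestor, collapse = ""),
         truth = truth, domain = domain, seed = seed)
  })
}

.n_syn_neighbours <- function(codon) {
  length(.codon_neighbours(codon, synonymous = TRUE))
}

# single-nucleotide sense neighbours of a codon, optionally restricted to
# synonymous (TRUE), nonsynonymous (FALSE) or either (NA)
.codon_neighbours <- function(codon, synonymous = NA) {
  gc <- .genetic_code()
  aa0 <- gc[[codon]]
  out <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      m <- codon; substr(m, pos, pos) <- b
      if (gc[[m]] == "*") next
      keep <- if (is.na(synonymous)) TRUE else
        if (synonymous) gc[[m]] == aa0 else gc[[m]] != aa0
      if (keep) out <- c(out, m)
    }
  }
  out
}

.draw_neighbour <- function(codon, synonymous) {
  nb <- .codon_neighbours(codon, synonymous)
  if (length(nb) == 0) {
    stop("codon ", codon, " has no suitable single-nucleotide neighbour",
         call. = FALSE)
  }
  if (length(nb) == 1) nb else sample(nb, 1)
}

#' Simulate a qPCR Ct table with planted expression profiles
#'
#' For every (genotype, timepoint, replicate) sample the reference gene
#' receives `ct_ref` plus Gaussian sampling noise, and each target gene a
#' Ct of `ct_ref - true_log2 + noise`, so the expected delta-Ct relative
#' expression equals `2^true_log2`.
#'
#' @param genotypes character vector of genotype labels.
#' @param timepoints ordered character vector of time-point labels.
#' @param replicates replicates per (genotype, timepoint) cell.
#' @param gene_profiles named list: for each target gene either a numeric
#'   vector of length `length(timepoints)` (same profile in every
#'   genotype) or a matrix with one row per genotype; values are true log2
#'   expression relative to the reference.
#' @param noise_sd standard deviation of Gaussian Ct noise (cycles),
#'   applied independently to every measurement.
#' @param ct_ref baseline reference-gene Ct (default 20).
#' @param reference reference gene label (default `"ACT2"`).
#' @param seed integer seed.
#' @return A [ct_table()] including the reference gene's rows.
#' @export
simulate_qpcr <- function(genotypes, timepoints, replicates = 4L,
                          gene_profiles, noise_sd = 0.3, ct_ref = 20,
                          reference = "ACT2", seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(noise_sd >= 0, replicates >= 1)
  nt <- length(timepoints)
  profile_for <- function(gene, genotype) {
    p <- gene_profiles[[gene]]
    if (is.matrix(p)) {
      stopifnot(ncol(p) == nt)
      p[match(genotype, genotypes), ]
    } else {
      stopifnot(length(p) == nt)
      p
    }
  }
  .with_seed(seed, {
    rows <- list()
    for (g in genotypes) {
      for (ti in seq_len(nt)) {
        for (r in seq_len(replicates)) {
          ref_ct <- ct_ref + stats::rnorm(1, 0, noise_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            genotype = g, timepoint = timepoints[ti],
            replicate = paste0("rep", r), gene = reference, ct = ref_ct,
            stringsAsFactors = FALSE)
          for (gene in names(gene_profiles)) {
            mu <- profile_for(gene, g)[ti]
            rows[[length(rows) + 1L]] <- data.frame(
              genotype = g, timepoint = timepoints[ti],
              replicate = paste0("rep", r), gene = gene,
              ct = ref_ct - mu + stats::rnorm(1, 0, noise_sd),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    ct_table(do.call(rbind, rows), timepoint_levels = timepoints)
  })
}
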