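#' Nei-Gojobori synonymous and nonsynonymous site counts
#'
#' Each of the three positions of a codon contributes a synonymous-site
#' fraction equal to the proportion of its three possible single-nucleotide
#' changes that leave the encoded amino acid unchanged; changes to a stop
#' codon count as nonsynonymous (the `stop_mutations = "nonsynonymous"`
#' convention) or may be dropped from the denominator
#' (`stop_mutations = "exclude"`). S and N sum to 3 per codon under the
#' default convention.
#'
#' @param codon_sequence ungapped sense-codon nucleotide string.
#' @param stop_mutations how mutations creating a stop codon enter the site
#'   count: counted as nonsynonymous (default) or excluded.
#' @return Named numeric vector `c(S_sites = ..., N_sites = ...)`.
#' @examples
#' count_sites("TTT")  # S = 1/3 (only TTT->TTC is synonymous)
#' @export
count_sites <- function(codon_sequence,
                        stop_mutations = c("nonsynonymous", "exclude")) {
  stop_mutations <- match.arg(stop_mutations)
  codon_sequence <- toupper(codon_sequence)
  codons <- .split_codons(codon_sequence)
  if (any(grepl("-", codons, fixed = TRUE))) {
    stop("count_sites() requires ungapped codons", call. = FALSE)
  }
  aa <- .translate_codons(codons)
  if (any(aa == "*")) {
    stop("stop codon inside sequence at codon ", which(aa == "*")[1],
         call. = FALSE)
  }
  tab <- .site_table(stop_mutations)
  s <- sum(tab[codons, "S"])
  n <- sum(tab[codons, "N"])
  c(S_sites = s, N_sites = n)
}

# per-codon S/N site fractions, computed once per convention and cached
.pkg_cache <- new.env(parent = emptyenv())

.site_table <- function(stop_mutations) {
  key <- paste0("sites_", stop_mutations)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  gc <- .genetic_code()
  sense <- names(gc)[gc != "*"]
  bases <- c("A", "C", "G", "T")
  tab <- matrix(0, nrow = length(sense), ncol = 2,
                dimnames = list(sense, c("S", "N")))
  for (codon in sense) {
    aa0 <- gc[[codon]]
    for (pos in 1:3) {
      muts <- vapply(setdiff(bases, substr(codon, pos, pos)), function(b) {
        m <- codon; substr(m, pos, pos) <- b; gc[[m]]
      }, character(1))
      if (stop_mutations == "exclude") {
        keep <- muts != "*"
        if (!any(keep)) next
        tab[codon, "S"] <- tab[codon, "S"] + sum(muts[keep] == aa0) / sum(keep)
        tab[codon, "N"] <- tab[codon, "N"] + sum(muts[keep] != aa0) / sum(keep)
      } else {
        tab[codon, "S"] <- tab[codon, "S"] + sum(muts == aa0) / 3
        tab[codon, "N"] <- tab[codon, "N"] + sum(muts != aa0 | muts == "*") / 3
      }
    }
  }
  .pkg_cache[[key]] <- tab
  tab
}

#' Nei-Gojobori pathway-averaged difference counts between two codons
#'
#' With a single nucleotide difference the change is classified by
#' translation. With two or three differences, every order in which the
#' differing positions could have mutated defines a pathway; the synonymous
#' and nonsynonymous step counts are averaged over all minimal pathways.
#' Pathways passing through a stop codon are excluded from the average by
#' default; if every pathway is blocked the average falls back to including
#' them and the result carries attribute `stop_blocked = TRUE`.
#'
#' @param codon_a,codon_b sense codons (no gaps).
#' @param stop_pathways exclude (default) or include pathways through stops.
#' @return Named numeric vector `c(Sd = ..., Nd = ...)`.
#' @examples
#' count_differences("TTT", "GTA")  # Sd = 0.5, Nd = 1.5
#' @export
count_differences <- function(codon_a, codon_b,
                              stop_pathways = c("exclude", "include")) {
  stop_pathways <- match.arg(stop_pathways)
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  if (grepl("-", codon_a, fixed = TRUE) || grepl("-", codon_b, fixed = TRUE)) {
    stop("gap codon passed to count_differences()", call. = FALSE)
  }
  gc <- .genetic_code()
  if (is.na(gc[codon_a]) || is.na(gc[codon_b]) ||
      gc[[codon_a]] == "*" || gc[[codon_b]] == "*") {
    stop("count_differences() requires sense codons", call. = FALSE)
  }
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  diffpos <- which(a != b)
  nd <- length(diffpos)
  if (nd == 0L) return(c(Sd = 0, Nd = 0))

  orders <- .permutations(diffpos)
  syn_steps <- numeric(0); non_steps <- numeric(0); blocked <- logical(0)
  for (ord in orders) {
    cur <- a; s <- 0; n <- 0; hit_stop <- FALSE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- b[pos]
      aa_cur <- gc[[paste(cur, collapse = "")]]
      aa_nxt <- gc[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*") hit_stop <- TRUE
      if (aa_cur == aa_nxt) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    syn_steps <- c(syn_steps, s); non_steps <- c(non_steps, n)
    blocked <- c(blocked, hit_stop)
  }
  use <- if (stop_pathways == "exclude" && !all(blocked)) !blocked else
    rep(TRUE, length(blocked))
  out <- c(Sd = mean(syn_steps[use]), Nd = mean(non_steps[use]))
  if (stop_pathways == "exclude" && all(blocked)) {
    attr(out, "stop_blocked") <- TRUE
  }
  out
}

# all orderings of a short vector (at most 3 elements here)
.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

#' Per-site divergence from Nei-Gojobori counts
#'
#' Forms proportions `pS = Sd / S_sites`, `pN = Nd / N_sites`, applies an
#' optional Jukes-Cantor multiple-hit correction
#' `d = -(3/4) log(1 - (4/3) p)`, and derives `omega = dN / dS`. In
#' `rounding = "truncate"` mode dS and dN are truncated (floored) at
#' `decimals` places *before* forming omega; this reproduces the arithmetic
#' of counting-method tables printed at fixed precision. `omega` is `NA`
#' when dS is zero.
#'
#' @param Sd,Nd synonymous / nonsynonymous difference counts (fractional
#'   values allowed).
#' @param S_sites,N_sites synonymous / nonsynonymous site counts.
#' @param lineage optional lineage label carried through to the result.
#' @param correction `"none"` or `"jukes_cantor"`.
#' @param rounding `"none"`, `"round"` or `"truncate"` applied to dS and dN.
#' @param decimals digits used by `rounding`.
#' @param indel_events number of indel events excluded from the counts
#'   (reported, not used in arithmetic).
#' @return Object of class `divergence_estimate`.
#' @examples
#' divergence_estimate(Sd = 1, S_sites = 134.33, Nd = 2, N_sites = 444.67,
#'                     correction = "jukes_cantor", rounding = "truncate",
#'                     decimals = 4)
#' @export
divergence_estimate <- function(Sd, S_sites, Nd, N_sites, lineage = NA,
                                correction = c("jukes_cantor", "none"),
                                rounding = c("none", "round", "truncate"),
                                decimals = 4L, indel_events = 0L) {
  correction <- match.arg(correction)
  rounding <- match.arg(rounding)
  stopifnot(Sd >= 0, Nd >= 0, S_sites > 0, N_sites > 0)
  pS <- Sd / S_sites
  pN <- Nd / N_sites
  corr <- function(p) {
    if (correction == "none") return(p)
    if (p >= 0.75) {
      stop("proportion p = ", signif(p, 4),
           " >= 3/4: Jukes-Cantor correction undefined", call. = FALSE)
    }
    -0.75 * log(1 - 4 / 3 * p)
  }
  dS <- corr(pS); dN <- corr(pN)
  shave <- switch(rounding,
                  none = identity,
                  round = function(d) round(d, decimals),
                  truncate = function(d) trunc(d * 10^decimals) / 10^decimals)
  dS <- shave(dS); dN <- shave(dN)
  omega <- if (dS > 0) dN / dS else NA_real_
  structure(
    list(lineage = lineage, Sd = Sd, Nd = Nd,
         S_sites = S_sites, N_sites = N_sites,
         dS = dS, dN = dN, omega = omega,
         correction = correction, rounding = rounding, decimals = decimals,
         indel_events = indel_events),
    class = "divergence_estimate"
  )
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf(
    "divergence estimate%s: Sd=%.4g S=%.6g dS=%.4f | Nd=%.4g N=%.6g dN=%.4f | dN/dS=%s\n",
    if (is.na(x$lineage)) "" else paste0(" (lineage ", x$lineage, ")"),
    x$Sd, x$S_sites, x$dS, x$Nd, x$N_sites, x$dN,
    if (is.na(x$omega)) "NA (dS = 0)" else sprintf("%.4f", x$omega)))
  invisible(x)
}

#' Lineage-specific Nei-Gojobori divergence from an ancestral assignment
#'
#' Compares the inferred ancestor with one paralog over all codon columns
#' that are sense codons in both (indel columns and ambiguous columns are
#' excluded; the indels are reported separately as events). Site counts are
#' averaged between ancestor and descendant, the standard pairwise
#' convention.
#'
#' @param assignment result of [reconstruct_ancestor()].
#' @param lineage 1 or 2.
#' @inheritParams divergence_estimate
#' @param stop_pathways passed to [count_differences()].
#' @return A [divergence_estimate()].
#' @export
lineage_divergence <- function(assignment, lineage,
                               correction = c("jukes_cantor", "none"),
                               rounding = c("none", "round", "truncate"),
                               decimals = 4L,
                               stop_pathways = c("exclude", "include")) {
  stopifnot(inherits(assignment, "ancestral_assignment"), lineage %in% 1:2)
  correction <- match.arg(correction)
  rounding <- match.arg(rounding)
  stop_pathways <- match.arg(stop_pathways)

  trio <- assignment$alignment
  desc_name <- assignment$names[[paste0("paralog", lineage)]]
  desc <- .split_codons(trio$sequences[match(desc_name, trio$names)])
  anc <- .split_codons(assignment$ancestor)
  cls <- as.character(assignment$classification)

  usable <- anc != "NNN" & anc != "---" & desc != "---" & cls != "unalignable"
  anc_u <- anc[usable]; desc_u <- desc[usable]

  sites_anc <- count_sites(paste(anc_u, collapse = ""))
  sites_desc <- count_sites(paste(desc_u, collapse = ""))
  S_sites <- (sites_anc[["S_sites"]] + sites_desc[["S_sites"]]) / 2
  N_sites <- (sites_anc[["N_sites"]] + sites_desc[["N_sites"]]) / 2

  Sd <- 0; Nd <- 0
  for (j in which(anc_u != desc_u)) {
    d <- count_differences(anc_u[j], desc_u[j], stop_pathways = stop_pathways)
    Sd <- Sd + d[["Sd"]]; Nd <- Nd + d[["Nd"]]
  }

  ev <- assignment$events
  n_indel <- sum(ev$lineage == lineage & ev$kind == "indel")
  divergence_estimate(Sd = Sd, S_sites = S_sites, Nd = Nd, N_sites = N_sites,
                      lineage = lineage, correction = correction,
                      rounding = rounding, decimals = decimals,
                      indel_events = n_indel)
}
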