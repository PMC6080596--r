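#' Fit the post-duplication divergence analysis to a codon-aligned trio
#'
#' The central entry point: from a codon alignment of two paralogs and an
#' outgroup ortholog it (1) reconstructs the pre-duplication ancestor by
#' outgroup parsimony ([reconstruct_ancestor()]), (2) computes per-lineage
#' Nei-Gojobori site and difference counts and Jukes-Cantor-corrected dS,
#' dN and dN/dS ([lineage_divergence()]), and (3) runs Tajima's relative
#' rate test on all changes, on amino-acid-changing events and on
#' synonymous events ([rrt_from_events()]).
#'
#' `rounding = "truncate"` with `decimals = 4` reproduces the arithmetic
#' of divergence tables printed at four decimal places (dS and dN floored
#' before forming the ratio).
#'
#' @param x a [codon_alignment()] with three sequences, or a path to a
#'   FASTA file holding one.
#' @param roles see [reconstruct_ancestor()].
#' @inheritParams divergence_estimate
#' @return An object of class `paralog_divergence`: list with
#'   `assignment`, `estimates` (one [divergence_estimate()] per lineage),
#'   `table` (data frame in S-differences / S-sites / dS / N-differences /
#'   N-sites / dN / omega column order), `rrt` (list `all`,
#'   `nonsynonymous`, `synonymous`), `events` and `call`. Methods:
#'   `print`, `summary`, `coef`, `as.data.frame`.
#' @examples
#' sim <- simulate_trio(seed = 1)
#' fit <- paralog_divergence(sim$alignment)
#' fit
#' coef(fit)
#' @export
paralog_divergence <- function(x, roles = NULL,
                               correction = c("jukes_cantor", "none"),
                               rounding = c("none", "round", "truncate"),
                               decimals = 4L) {
  cl <- match.call()
  correction <- match.arg(correction)
  rounding <- match.arg(rounding)
  if (is.character(x) && length(x) == 1L) x <- read_codon_fasta(x)
  stopifnot(inherits(x, "codon_alignment"))
  asg <- reconstruct_ancestor(x, roles = roles)
  est <- lapply(1:2, function(lin)
    lineage_divergence(asg, lin, correction = correction,
                       rounding = rounding, decimals = decimals))
  tab <- do.call(rbind, lapply(est, function(e) data.frame(
    lineage = e$lineage, S_differences = e$Sd, S_sites = e$S_sites,
    dS = e$dS, N_differences = e$Nd, N_sites = e$N_sites, dN = e$dN,
    omega = e$omega, indel_events = e$indel_events)))
  rownames(tab) <- asg$names[c("paralog1", "paralog2")]
  rrt <- list()
  for (class in c("all", "nonsynonymous", "synonymous")) {
    rrt[[class]] <- tryCatch(rrt_from_events(asg, class),
                             error = function(e) NULL)
  }
  structure(
    list(assignment = asg, estimates = est, table = tab, rrt = rrt,
         events = asg$events, correction = correction,
         rounding = rounding, decimals = decimals, call = cl),
    class = "paralog_divergence"
  )
}

#' @export
print.paralog_divergence <- function(x, digits = 4, ...) {
  cat("Post-duplication divergence of paralogs vs outgroup\n\n")
  print(x$assignment)
  cat(sprintf("\nNei-Gojobori divergence per lineage (correction: %s%s)\n",
              x$correction,
              if (x$rounding != "none")
                sprintf("; %s at %d decimals", x$rounding, x$decimals)
              else ""))
  tab <- x$table
  tab[] <- lapply(tab, function(col)
    if (is.numeric(col)) round(col, digits) else col)
  print(tab)
  cat("\nTajima relative rate tests\n")
  for (class in names(x$rrt)) {
    r <- x$rrt[[class]]
    if (is.null(r)) next
    cat(sprintf("  %-14s (m1=%g, m2=%g): X2 = %.3f, P = %.3f\n", class,
                r$estimate[["m1"]], r$estimate[["m2"]],
                r$statistic, r$p.value))
  }
  invisible(x)
}

#' @method summary paralog_divergence
#' @export
summary.paralog_divergence <- function(object, threshold = 56, ...) {
  gr <- suppressMessages(classify_substitutions(object$events,
                                                threshold = threshold))
  structure(list(fit = object, grantham = gr, threshold = threshold),
            class = "summary.paralog_divergence")
}

#' @export
print.summary.paralog_divergence <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nGrantham classification (threshold %g):\n", x$threshold))
  if (nrow(x$grantham) == 0) cat("  no nonsynonymous point events\n") else
    print(x$grantham, row.names = FALSE)
  invisible(x)
}

#' @method coef paralog_divergence
#' @export
coef.paralog_divergence <- function(object, ...) {
  m <- as.matrix(object$table[, c("dS", "dN", "omega")])
  rownames(m) <- rownames(object$table)
  m
}

#' @method as.data.frame paralog_divergence
#' @export
as.data.frame.paralog_divergence <- function(x, ...) {
  cbind(gene = rownames(x$table), x$table)
}
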