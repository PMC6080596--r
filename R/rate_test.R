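#' Tajima's relative rate test
#'
#' Tests whether two lineages descending from a common ancestor have
#' accumulated changes at equal rates, using only the counts of changes
#' unique to each lineage (polarised by an outgroup). The statistic
#' `chi2 = (m1 - m2)^2 / (m1 + m2)` is compared with a chi-square
#' distribution on 1 degree of freedom (upper tail).
#'
#' @param m1,m2 non-negative counts of changes unique to lineage 1 and 2;
#'   not both zero.
#' @return An object of classes `tajima_rrt` and `htest` with `statistic`,
#'   `parameter` (df = 1), `p.value` and the counts in `estimate`.
#' @examples
#' tajima_rrt(3, 10)  # chi2 = 3.769, p = 0.052
#' @export
tajima_rrt <- function(m1, m2) {
  if (m1 < 0 || m2 < 0) stop("counts must be non-negative", call. = FALSE)
  if (m1 + m2 == 0) {
    stop("m1 = m2 = 0: relative rate statistic undefined", call. = FALSE)
  }
  chi2 <- (m1 - m2)^2 / (m1 + m2)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(
    list(statistic = c("X-squared" = chi2),
         parameter = c(df = 1),
         p.value = p,
         estimate = c(m1 = m1, m2 = m2),
         method = "Tajima relative rate test",
         data.name = sprintf("m1 = %g unique changes vs m2 = %g", m1, m2)),
    class = c("tajima_rrt", "htest")
  )
}

#' Relative rate test from lineage-assigned substitution events
#'
#' Extracts per-lineage change counts from an [reconstruct_ancestor()]
#' result and delegates to [tajima_rrt()]. Change classes:
#'
#' * `"all"` - point events plus indel events;
#' * `"nonsynonymous"` - nonsynonymous point events plus indel events
#'   (an in-frame deletion removes amino acids, so it is amino-acid
#'   changing); set `include_indels = FALSE` for point events only;
#' * `"synonymous"` - synonymous point events only.
#'
#' @param assignment an `ancestral_assignment`.
#' @param change_class which changes to count.
#' @param include_indels count indel events in the `all` and
#'   `nonsynonymous` classes (default TRUE).
#' @return A [tajima_rrt()] result.
#' @export
rrt_from_events <- function(assignment,
                            change_class = c("all", "nonsynonymous",
                                             "synonymous"),
                            include_indels = TRUE) {
  stopifnot(inherits(assignment, "ancestral_assignment"))
  change_class <- match.arg(change_class)
  ev <- assignment$events
  count <- function(lin) {
    e <- ev[ev$lineage == lin, , drop = FALSE]
    pts <- e[e$kind == "point", , drop = FALSE]
    ind <- sum(e$kind == "indel")
    switch(change_class,
           all = nrow(pts) + if (include_indels) ind else 0L,
           nonsynonymous = sum(!pts$synonymous) +
             if (include_indels) ind else 0L,
           synonymous = sum(pts$synonymous))
  }
  m1 <- count(1); m2 <- count(2)
  if (m1 + m2 == 0) {
    stop("no events of class '", change_class, "' on either lineage",
         call. = FALSE)
  }
  res <- tajima_rrt(m1, m2)
  res$data.name <- sprintf("%s changes: lineage1 = %d, lineage2 = %d",
                           change_class, m1, m2)
  res
}
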