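#' The Grantham (1974) amino-acid distance matrix
#'
#' Physicochemical dissimilarity between the 20 standard amino acids,
#' combining composition, polarity and molecular volume. Off-diagonal
#' values range from 5 (Leu-Ile) to 215 (Cys-Trp). Shipped as a plain-text
#' table (`inst/extdata/grantham1974.tsv`) and loaded on first use.
#'
#' @return A symmetric 20 x 20 integer matrix with single-letter row and
#'   column names and a zero diagonal.
#' @export
grantham_matrix <- function() {
  if (is.null(.pkg_cache$grantham)) {
    path <- system.file("extdata", "grantham1974.tsv", package = "paralogdiv",
                        mustWork = TRUE)
    tab <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(tab[, -1])
    rownames(m) <- tab[[1]]
    storage.mode(m) <- "integer"
    stopifnot(isSymmetric(m), all(diag(m) == 0))
    .pkg_cache$grantham <- m
  }
  .pkg_cache$grantham
}

#' Grantham distance between two amino acids
#'
#' @param aa1,aa2 single-letter codes for standard amino acids.
#' @return Distance in Grantham units (0 iff `aa1 == aa2`).
#' @examples
#' grantham_distance("L", "I")  # 5
#' grantham_distance("C", "W")  # 215
#' @export
grantham_distance <- function(aa1, aa2) {
  m <- grantham_matrix()
  aa1 <- toupper(aa1); aa2 <- toupper(aa2)
  bad <- setdiff(c(aa1, aa2), rownames(m))
  if (length(bad) > 0) {
    stop("non-standard amino acid letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(m[cbind(aa1, aa2)])
}

#' Classify amino-acid substitutions as conservative or radical
#'
#' Annotates every nonsynonymous point event with its Grantham distance and
#' a conservative/radical call: a substitution is *radical* when its
#' distance is at or above the threshold (default 56 Grantham units).
#' Synonymous events are excluded; indel events are skipped with a message.
#'
#' @param events event data frame from [reconstruct_ancestor()] /
#'   [substitution_events()].
#' @param threshold Grantham units separating conservative from radical.
#' @return Data frame with columns `lineage`, `aa_position`, `aa_from`,
#'   `aa_to`, `distance`, `classification`, `threshold`, ordered by
#'   position.
#' @export
classify_substitutions <- function(events, threshold = 56) {
  stopifnot(is.data.frame(events))
  n_indel <- sum(events$kind == "indel")
  if (n_indel > 0) {
    message(n_indel, " indel event(s) skipped by Grantham classification")
  }
  ev <- events[events$kind == "point" & !events$synonymous, , drop = FALSE]
  if (nrow(ev) == 0) {
    return(data.frame(lineage = integer(), aa_position = integer(),
                      aa_from = character(), aa_to = character(),
                      distance = integer(), classification = character(),
                      threshold = numeric(), stringsAsFactors = FALSE))
  }
  d <- grantham_distance(ev$aa_from, ev$aa_to)
  out <- data.frame(
    lineage = ev$lineage, aa_position = ev$aa_position,
    aa_from = ev$aa_from, aa_to = ev$aa_to, distance = d,
    classification = ifelse(d >= threshold, "radical", "conservative"),
    threshold = threshold, stringsAsFactors = FALSE)
  out[order(out$aa_position), , drop = FALSE]
}
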