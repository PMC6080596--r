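# Independent oracles and small fixture builders used across the suite.

# exhaustive pathway-enumeration oracle for Nei-Gojobori difference
# counting, written independently of the package implementation:
# lexicographic iterative permutation generation, explicit step walk
oracle_count_differences <- function(a, b, exclude_stops = TRUE) {
  code <- oracle_genetic_code()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  d <- which(av != bv)
  if (length(d) == 0) return(c(Sd = 0, Nd = 0))
  perms <- oracle_perms(length(d))
  syn <- numeric(0); non <- numeric(0); ok <- logical(0)
  for (r in seq_len(nrow(perms))) {
    order_pos <- d[perms[r, ]]
    cur <- av; s <- 0; n <- 0; clean <- TRUE
    for (pos in order_pos) {
      nxt <- cur
      nxt[pos] <- bv[pos]
      aa1 <- code[paste(cur, collapse = "")]
      aa2 <- code[paste(nxt, collapse = "")]
      if (aa2 == "*") clean <- FALSE
      if (aa1 == aa2) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    syn <- c(syn, s); non <- c(non, n); ok <- c(ok, clean)
  }
  keep <- if (exclude_stops && any(ok)) ok else rep(TRUE, length(ok))
  c(Sd = mean(syn[keep]), Nd = mean(non[keep]))
}

# all permutations of 1..n as a matrix, lexicographic order
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- oracle_perms(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# standard genetic code transcribed via seqinr (independent of Biostrings)
oracle_genetic_code <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- sort(codons)
  aa <- vapply(codons, function(cd)
    seqinr::translate(strsplit(cd, "")[[1]]), character(1))
  stats::setNames(aa, codons)
}

sense_codons <- function() {
  code <- oracle_genetic_code()
  names(code)[code != "*"]
}

# write a small FASTA fixture and return its path
write_fasta_fixture <- function(records, dir = NULL, wrap = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("fasta_fix")
    dir.create(dir)
  }
  path <- file.path(dir, "trio.fasta")
  lines <- character(0)
  for (nm in names(records)) {
    seq <- records[[nm]]
    if (!is.null(wrap)) {
      seq <- regmatches(seq, gregexpr(sprintf(".{1,%d}", wrap), seq))[[1]]
    }
    lines <- c(lines, paste0(">", nm), seq)
  }
  writeLines(lines, path)
  path
}

# minimal hand-built trio: 4 codons, one lineage-1 nonsyn change (codon 2),
# one lineage-2 syn change (codon 3)
tiny_trio <- function() {
  codon_alignment(c(
    paralog1 = paste0("ATG", "GAT", "AAA", "TTT"),
    paralog2 = paste0("ATG", "GCT", "AAG", "TTT"),
    outgroup = paste0("ATG", "GCT", "AAA", "TTT")))
}
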