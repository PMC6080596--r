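#' Run the full divergence and expression analysis and write reports
#'
#' Orchestrates every stage over file inputs and writes a machine-readable
#' report bundle: `divergence.tsv` (one row per lineage in S-differences /
#' S-sites / dS / N-differences / N-sites / dN / omega order),
#' `rrt.json`, `grantham.tsv`, `cluster_test.json`,
#' `expression_correlations.tsv`, `events.json` and `manifest.json`
#' (package version, seed and a config echo). All input paths are
#' validated before any computation; on error, partially written outputs
#' are removed.
#'
#' @param config named list (or path to a `key = value` text file, one
#'   pair per line; `#` comments allowed) with entries:
#'   \describe{
#'     \item{fasta}{path to the codon-aligned trio FASTA (required).}
#'     \item{ct_table}{path to the qPCR Ct table (optional).}
#'     \item{domain}{domain as `"name:start:end"` (optional; required for
#'       the cluster test).}
#'     \item{correction, rounding, decimals}{divergence-mode flags, see
#'       [paralog_divergence()]; defaults `jukes_cantor`, `none`, `4`.}
#'     \item{threshold}{Grantham threshold, default 56.}
#'     \item{n_trials}{cluster-test trials, default 1000.}
#'     \item{sampling}{cluster-test sampling scheme, default
#'       `without_replacement`.}
#'     \item{genotype, reference}{expression-analysis labels (genotype
#'       defaults to the first in the table; reference `ACT2`).}
#'     \item{seed}{integer seed, required (recorded in every report).}
#'     \item{out_dir}{output directory, created if absent (required).}
#'   }
#' @return Invisibly, a named vector of the report file paths.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  stopifnot(is.list(config))
  get <- function(key, default = NULL) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  fasta <- get("fasta")
  out_dir <- get("out_dir")
  seed <- get("seed")
  if (is.null(fasta) || is.null(out_dir) || is.null(seed)) {
    stop("config requires 'fasta', 'out_dir' and 'seed'", call. = FALSE)
  }
  seed <- as.integer(seed)
  ct_path <- get("ct_table")
  domain_spec <- get("domain")
  # validate everything before computing anything
  for (p in c(fasta, ct_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input file not found: ", p, call. = FALSE)
    }
  }
  domain <- NULL
  if (!is.null(domain_spec)) {
    parts <- strsplit(domain_spec, ":")[[1]]
    if (length(parts) == 2) parts <- c("domain", parts)
    if (length(parts) != 3) {
      stop("domain must be 'name:start:end', got '", domain_spec, "'",
           call. = FALSE)
    }
    domain <- list(name = parts[1], start = as.integer(parts[2]),
                   end = as.integer(parts[3]))
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(divergence = "divergence.tsv", rrt = "rrt.json",
             grantham = "grantham.tsv", cluster = "cluster_test.json",
             expression = "expression_correlations.tsv",
             events = "events.json", manifest = "manifest.json")
  paths <- stats::setNames(file.path(out_dir, files), names(files))
  written <- character(0)
  on.exit({
    # a failed run leaves no partial bundle behind
    if (!identical(written, unname(paths))) unlink(written)
  })

  fit <- paralog_divergence(
    fasta,
    correction = get("correction", "jukes_cantor"),
    rounding = get("rounding", "none"),
    decimals = as.integer(get("decimals", 4L)))

  tab <- as.data.frame(fit)
  utils::write.table(tab, paths[["divergence"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  written <- c(written, paths[["divergence"]])

  rrt_out <- lapply(fit$rrt, function(r) {
    if (is.null(r)) return(NULL)
    list(m1 = unname(r$estimate[["m1"]]), m2 = unname(r$estimate[["m2"]]),
         chi2 = unname(r$statistic), df = 1, p = r$p.value)
  })
  .write_json(rrt_out, paths[["rrt"]])
  written <- c(written, paths[["rrt"]])

  gr <- suppressMessages(
    classify_substitutions(fit$events,
                           threshold = as.numeric(get("threshold", 56))))
  utils::write.table(gr, paths[["grantham"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  written <- c(written, paths[["grantham"]])

  cluster_out <- NULL
  if (!is.null(domain)) {
    ref_len <- nchar(gsub("-", "",
      fit$assignment$alignment$sequences[
        match(fit$assignment$names[["outgroup"]],
              fit$assignment$alignment$names)])) %/% 3L
    dom <- domain_annotation(domain$name, domain$start, domain$end, ref_len)
    ev2 <- fit$events[fit$events$lineage == 2 &
                        !(fit$events$synonymous %in% TRUE), , drop = FALSE]
    n_draws <- nrow(ev2)
    k_obs <- sum(ev2$aa_position >= dom$start & ev2$aa_position <= dom$end,
                 na.rm = TRUE)
    ct <- domain_cluster_test(
      L = ref_len, n = n_draws, domain = dom, k_obs = k_obs,
      n_trials = as.integer(get("n_trials", 1000L)), seed = seed,
      sampling = get("sampling", "without_replacement"))
    cluster_out <- list(
      protein_length = ct$protein_length, n_substitutions = ct$n_substitutions,
      domain = list(name = dom$name, start = dom$start, end = dom$end),
      observed_in_domain = ct$observed_in_domain, n_trials = ct$n_trials,
      trials_at_least_observed = ct$trials_at_least_observed,
      empirical_p = ct$empirical_p, analytic_p = ct$analytic_p,
      sampling = ct$sampling, seed = ct$seed)
  }
  .write_json(cluster_out, paths[["cluster"]])
  written <- c(written, paths[["cluster"]])

  expr_out <- data.frame()
  if (!is.null(ct_path)) {
    ct_tab <- read_ct_table(ct_path)
    genotype <- get("genotype", as.character(ct_tab$genotype[1]))
    expr_out <- expression_correlations(ct_tab, genotype,
                                        reference = get("reference", "ACT2"))
  }
  utils::write.table(expr_out, paths[["expression"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  written <- c(written, paths[["expression"]])

  .write_json(fit$events, paths[["events"]])
  written <- c(written, paths[["events"]])

  manifest <- list(
    package = "paralogdiv",
    version = as.character(utils::packageVersion("paralogdiv")),
    seed = seed,
    config = config[order(names(config))])
  .write_json(manifest, paths[["manifest"]])
  written <- c(written, paths[["manifest"]])

  invisible(paths)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

#' Read a plain key = value pipeline config file
#'
#' One `key = value` pair per line; blank lines and lines starting with
#' `#` are ignored; values are kept as strings.
#'
#' @param path config file path.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3]
  if (length(bad) > 0) {
    stop("malformed config line(s): ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  stats::setNames(
    lapply(kv, function(m) trimws(m[3])),
    vapply(kv, function(m) trimws(m[2]), character(1)))
}
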