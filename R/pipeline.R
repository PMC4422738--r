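#' End-to-end pipeline runs
#'
#' Thin orchestration layer over the package: simulate a scenario to
#' files, compute the per-cluster diversity report and F_ST matrix, or run
#' the founder-estimation grid, each writing its outputs to a directory
#' with a provenance header (resolved configuration, seed and package
#' version). Logs go to `stderr` via [message()]; data only to files.
#'
#' @param scenario A [scenario_spec()] or path to a scenario YAML file.
#' @param out Output directory (created if absent).
#' @param seed Integer seed.
#' @return Invisibly, a named list of the written file paths.
#' @export
pipeline_simulate <- function(scenario, out, seed = 1L) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  stopifnot(inherits(scenario, "scenario_spec"))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sim <- emit_dataset(scenario, seed = seed)
  paths <- list(
    genepop = file.path(out, "genotypes.gen"),
    long = file.path(out, "genotypes.tsv"),
    clusters = file.path(out, "clusters.tsv"),
    truth = file.path(out, "truth.json")
  )
  write_genepop(sim$genotypes, paths$genepop, clusters = sim$clusters,
                title = paste0("synthetic scenario, seed ", seed))
  write_long_table(sim$genotypes, sim$clusters, paths$long)
  write_clusters(sim$clusters, paths$clusters)
  truth_json <- purrr::map(sim$truth, function(tr) {
    list(n_founders = tr$n_founders,
         founder_alleles = tr$founder_alleles,
         lost_to_drift = tr$lost_to_drift,
         sampled_admixed = as.list(tr$sampled_admixed))
  })
  jsonlite::write_json(list(seed = seed, clusters = truth_json),
                       paths$truth, auto_unbox = TRUE, pretty = TRUE)
  sizes <- table(sim$clusters$cluster)
  message("simulated ", length(sizes), " clusters (N = ",
          paste(sizes, collapse = ", "), ") at ",
          length(loci(sim$genotypes)), " loci -> ", out)
  invisible(paths)
}

# Read genotype + cluster inputs for the analysis commands.
load_inputs <- function(input, format = c("long", "genepop"), clusters = NULL) {
  format <- match.arg(format)
  if (format == "long") {
    lt <- read_long_table(input)
    if (!is.null(clusters)) lt$clusters <- read_clusters(clusters)
    lt
  } else {
    g <- read_genepop(input)
    cl <- if (is.null(clusters)) genepop_pops(g) else read_clusters(clusters)
    list(genotypes = g, clusters = cl)
  }
}

provenance_header <- function(seed, extra = list()) {
  c(sprintf("# founderest %s",
            as.character(utils::packageVersion("founderest"))),
    sprintf("# seed: %s", seed),
    purrr::imap_chr(extra, function(v, k) sprintf("# %s: %s", k, v)))
}

#' @rdname pipeline_simulate
#' @param input Genotype file (long table or GENEPOP).
#' @param format `"long"` or `"genepop"`.
#' @param clusters Optional cluster TSV; defaults to the long table's
#'   cluster column or the GENEPOP POP blocks.
#' @param g Rarefaction base (diploid individuals); `NULL` for automatic.
#' @param floor_fst Floor negative F_ST estimates at zero in the report.
#' @export
pipeline_stats <- function(input, out, format = "long", clusters = NULL,
                           g = NULL, floor_fst = FALSE, seed = 1L) {
  dat <- load_inputs(input, format, clusters)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stats <- cluster_stats(dat$genotypes, dat$clusters, g = g)
  fst <- pairwise_fst(dat$genotypes, dat$clusters, floor_zero = floor_fst)
  paths <- list(stats = file.path(out, "cluster_stats.tsv"),
                fst = file.path(out, "fst_matrix.tsv"))
  hdr <- provenance_header(seed, list(input = input))
  readr::write_lines(hdr, paths$stats)
  readr::write_tsv(format_stats_table(stats), paths$stats, append = TRUE,
                   col_names = TRUE)
  m <- fst_matrix(fst)
  readr::write_lines(hdr, paths$fst)
  readr::write_tsv(tibble::as_tibble(m, rownames = "cluster"), paths$fst,
                   append = TRUE, col_names = TRUE)
  message("wrote cluster stats for ", nrow(stats), " clusters -> ", out)
  invisible(paths)
}

# Table-2-shaped presentation: N, A, A_R, H_O, uH_E, pA, freq_pA.
format_stats_table <- function(stats) {
  tibble::tibble(
    Site = stats$cluster,
    N = stats$N,
    A = round(stats$A, 1),
    A_R = round(stats$A_R, 1),
    H_O = round(stats$H_O, 2),
    uH_E = round(stats$uH_E, 2),
    pA = stats$pA,
    freq_pA = ifelse(stats$pA == 0, "-",
                     ifelse(stats$freq_pA_min == stats$freq_pA_max,
                            sprintf("%.3f", stats$freq_pA_min),
                            sprintf("%.3f-%.3f", stats$freq_pA_min,
                                    stats$freq_pA_max)))
  )
}

#' @rdname pipeline_simulate
#' @param modes,variants,replicates,success_threshold,low_freq_threshold,n_max
#'   Passed to [run_founder_table()].
#' @param curves Also write one capture-curve TSV per estimated cell.
#' @export
pipeline_founders <- function(input, out, format = "long", clusters = NULL,
                              modes = c("resample", "empirical", "equal"),
                              variants = c("all", "drop_low_freq",
                                           "drop_nonprivate_low_freq"),
                              replicates = 1000, success_threshold = 0.05,
                              low_freq_threshold = 0.02, n_max = "auto",
                              seed = 1L, curves = FALSE) {
  dat <- load_inputs(input, format, clusters)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  report <- run_founder_table(dat$genotypes, dat$clusters,
                              modes = modes, variants = variants,
                              replicates = replicates,
                              success_threshold = success_threshold,
                              low_freq_threshold = low_freq_threshold,
                              n_max = n_max, seed = seed,
                              keep_estimates = curves)
  paths <- list(tsv = file.path(out, "founder_estimates.tsv"),
                json = file.path(out, "founder_estimates.json"))
  hdr <- provenance_header(seed, list(
    input = input, replicates = replicates,
    success_threshold = success_threshold,
    low_freq_threshold = low_freq_threshold, n_max = paste(n_max)))
  readr::write_lines(hdr, paths$tsv)
  readr::write_tsv(report, paths$tsv, append = TRUE, col_names = TRUE)
  jsonlite::write_json(
    list(config = list(seed = seed, replicates = replicates,
                       success_threshold = success_threshold,
                       low_freq_threshold = low_freq_threshold,
                       modes = modes, variants = variants,
                       version = as.character(utils::packageVersion("founderest"))),
         estimates = report),
    paths$json, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (curves) {
    ests <- attr(report, "estimates")
    dir.create(file.path(out, "curves"), showWarnings = FALSE)
    for (key in names(ests)) {
      readr::write_tsv(ests[[key]]$curve,
                       file.path(out, "curves", paste0(key, ".tsv")))
    }
    paths$curves <- file.path(out, "curves")
  }
  n_fail <- sum(grepl("^error:", report$footnote %||% character(0)), na.rm = TRUE)
  message("founder report: ", nrow(report), " cells (", n_fail,
          " failed) -> ", out)
  invisible(paths)
}
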