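#' Run the whole-mitogenome analysis pipeline
#'
#' Orchestrates simulate/load -> diversity -> AMOVA -> genealogy and
#' homoplasy -> codon classification -> clock, writing tab-delimited
#' reports and a run log to an output directory. All validation happens
#' before any file is written, and every stochastic stage draws from the
#' single seed, so a run is a pure function of (inputs, config, seed).
#'
#' @param config a list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{simulate}{logical or list of [sim_config()] overrides; when
#'       TRUE/list, data are simulated instead of read.}
#'     \item{fasta,partitions,samples}{input paths (when not simulating).}
#'     \item{tree}{optional user newick; default: neighbor-joining.}
#'     \item{rates}{optional rate-table TSV (`species`, `rate`) for the
#'       clock stage.}
#'     \item{sites}{site count L for the clock stage.}
#'     \item{k}{optional mean synonymous differences for a divergence
#'       date.}
#'     \item{model}{distance model for AMOVA, default `"K2P"`.}
#'     \item{n_perm}{permutations for significance tests, default 1000.}
#'   }
#' @param out_dir output directory (created if needed).
#' @param seed integer seed used for every stochastic stage.
#' @return Invisibly, a list with the in-memory results and `paths` of the
#'   written reports.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  model <- config$model %||% "K2P"
  n_perm <- config$n_perm %||% 1000L

  # ---- acquire inputs (pre-flight: everything validated before writing)
  simulate <- !is.null(config$simulate) && !identical(config$simulate, FALSE)
  if (simulate) {
    overrides <- if (is.list(config$simulate)) config$simulate else list()
    sc <- do.call(sim_config, overrides)
    sim <- simulate_mitogenomes(sc, seed = seed)
    aln <- sim$alignment; samples <- sim$samples; parts <- sim$partitions
    user_tree <- NULL
  } else {
    for (f in c("fasta", "partitions", "samples")) {
      if (is.null(config[[f]]) || !file.exists(config[[f]])) {
        abort(paste0("Missing input: ", f), class = "mito_config_error")
      }
    }
    aln <- read_fasta(config$fasta)
    parts <- read_partition_table(config$partitions, aln)
    samples <- read_sample_table(config$samples, aln)
    user_tree <- if (!is.null(config$tree)) read_newick(config$tree) else NULL
    sim <- NULL
  }
  samples <- validate_samples(samples, aln)
  parts <- validate_partitions(parts, aln)
  if (!is.null(user_tree)) check_tree_tips(user_tree, aln)

  # ---- analyses
  haps <- collapse_haplotypes(aln)
  report <- segregating_sites(aln, haps)
  density <- partition_density(aln, parts, report)
  dm <- pairwise_distances(aln, model = model)
  pstats <- mean_pairwise_stats(dm, aln_length(aln))
  fit_amova <- amova(dm, samples, n_perm = n_perm, seed = seed)
  phi_pairs <- pairwise_phi_pt(dm, samples, n_perm = n_perm, seed = seed)

  tree <- user_tree %||% nj_tree(dm)
  indices <- site_indices(tree, aln, parts, report = report)
  # D-loop-only genealogy versus whole genome (the partition-conflict check)
  rf_conflict <- NA_integer_
  dloop_cols <- which(class_membership(parts, aln_length(aln))["dloop", ])
  if (length(dloop_cols)) {
    rf_conflict <- tryCatch({
      daln <- mito_alignment(unclass(aln)[, dloop_cols, drop = FALSE])
      rf_distance(tree, nj_tree(pairwise_distances(daln, model = "p")))
    }, error = function(e) NA_integer_)
  }

  changes <- classify_substitutions(aln, parts, report)
  branches <- branch_changes(tree, aln, parts)
  excess <- tryCatch(
    replacement_excess_test(changes, samples, haps = haps,
                            n_perm = n_perm, seed = seed),
    error = function(e) NULL)

  clock <- NULL
  if (!is.null(config$rates)) {
    rates <- readr::read_tsv(config$rates, show_col_types = FALSE,
                             progress = FALSE)
    L <- config$sites %||% 3796L
    wt <- waiting_times(rates, L)
    fit <- fit_lognormal(wt, sites = L)
    clock <- list(fit = fit, summary = glance(fit),
                  tmrca = if (!is.null(config$k)) tmrca(config$k, fit))
  }

  # ---- write reports
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(tibble::as_tibble(haps), p("haplotypes.tsv"),
                   progress = FALSE)
  site_out <- dplyr::left_join(report,
                               locate_positions(parts, report$position),
                               by = "position")
  readr::write_tsv(site_out, p("sites.tsv"), progress = FALSE)
  readr::write_tsv(density, p("partition_density.tsv"), progress = FALSE)
  readr::write_tsv(pstats, p("pairwise_summary.tsv"), progress = FALSE)
  readr::write_tsv(tidy(dm), p("distances.tsv"), progress = FALSE)
  readr::write_tsv(tidy(fit_amova), p("amova.tsv"), progress = FALSE)
  readr::write_tsv(fit_amova$phi, p("amova_phi.tsv"), progress = FALSE)
  readr::write_tsv(tidy(phi_pairs), p("pairwise_phi.tsv"), progress = FALSE)
  write_newick(tree, p("tree.nwk"))
  readr::write_tsv(indices, p("site_homoplasy.tsv"), progress = FALSE)
  readr::write_tsv(dplyr::select(changes, -"carriers"),
                   p("codon_changes.tsv"), progress = FALSE)
  readr::write_tsv(branches, p("branch_changes.tsv"), progress = FALSE)
  if (!is.null(excess)) {
    readr::write_tsv(glance(excess), p("replacement_excess.tsv"),
                     progress = FALSE)
  }
  if (!is.null(clock)) {
    readr::write_tsv(clock$summary, p("clock_fit.tsv"), progress = FALSE)
    if (!is.null(clock$tmrca)) {
      readr::write_tsv(clock$tmrca, p("tmrca.tsv"), progress = FALSE)
    }
  }
  log_lines <- c(
    paste0("mitolineage ", as.character(utils::packageVersion("mitolineage"))),
    paste0("seed: ", seed),
    paste0("config_hash: ", rlang::hash(config)),
    paste0("samples: ", n_samples(aln), "  columns: ", aln_length(aln)),
    paste0("haplotypes: ", length(unique(haps$haplotype)),
           "  segregating_sites: ", nrow(report)),
    paste0("rf_dloop_vs_genome: ", rf_conflict),
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  writeLines(log_lines, p("run_log.txt"))

  invisible(list(alignment = aln, samples = samples, partitions = parts,
                 haplotypes = haps, sites = report, density = density,
                 distances = dm, pairwise = pstats, amova = fit_amova,
                 pairwise_phi = phi_pairs, tree = tree, indices = indices,
                 rf_dloop_vs_genome = rf_conflict, changes = changes,
                 branches = branches, excess = excess, clock = clock,
                 truth = if (!is.null(sim)) sim$truth,
                 out_dir = out_dir))
}
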