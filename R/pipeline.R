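#' Run the full two-lineage differentiation workflow on a simulated dataset
#'
#' Chains every stage of the package on one dataset: simulation, SNP
#' extraction and clade-specific SNP scanning, sliding-window F_ST with peak
#' calling, pan-genome partition with clade-specific genes, accessory-genome
#' Jaccard distances and neighbor joining, geographic/habitat/phylogenetic
#' distance matrices with Mantel and partial Mantel tests, recombination
#' origin assignment and summary, and growth-rate comparison. All artifacts
#' are written to `out_dir` as plain-text files plus a JSON manifest.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [sim_config()]; its seed governs all randomness.
#' @param window,step,fold Window scan parameters (bp, bp, fold-over-mean).
#' @param n_perm Mantel permutations.
#' @param epsilon,tau Origin-assignment parameters (see [assign_origins()]).
#' @param k_min,r2_min Growth-rate fit parameters (see [growth_rate()]).
#' @return Invisibly, a named list with every in-memory result and the file
#'   paths written.
#' @export
run_pipeline <- function(out_dir, config = sim_config(),
                         window = 5000, step = 2500, fold = 4,
                         n_perm = 10000, epsilon = 0.1, tau = 0.045,
                         k_min = 5, r2_min = 0.95) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  sim <- simulate_dataset(config)
  write_alignment(sim$alignment, p("core_alignment.fasta"))
  write_gene_matrix(sim$genes, p("gene_matrix.tsv"))
  write_metadata(sim$metadata, p("metadata.tsv"))
  write_events(sim$truth$recomb_events, p("recomb_events.tsv"))
  write_growth(sim$growth, p("growth.tsv"))
  jsonlite::write_json(
    list(planted_fixed_diff_positions = sim$truth$planted_fixed_diff_positions,
         planted_genes = sim$truth$planted_genes,
         realized_mutation_count = sim$truth$realized_mutation_count,
         realized_imported_substitutions =
           sim$truth$realized_imported_substitutions),
    p("truth.json"), auto_unbox = TRUE, digits = NA)

  clades <- sim$truth$clade_assignment

  snps <- extract_snps(sim$alignment)
  cs <- clade_specific_snps(snps, clades)
  readr::write_tsv(as_tibble(cs), p("clade_specific_snps.tsv"))
  counts <- window_counts(cs, window = window, step = step)
  write_window_track(counts, p("snp_windows.tsv"))
  peaks <- call_peaks(counts, fold = fold)
  readr::write_tsv(peaks, p("snp_peaks.tsv"))

  fst <- window_fst(sim$alignment, clades, window = window, step = step)
  write_window_track(fst, p("fst_windows.tsv"))
  readr::write_tsv(track_summary(fst), p("fst_summary.tsv"))

  part <- partition_pangenome(sim$genes)
  jsonlite::write_json(glance(part), p("pangenome.json"), auto_unbox = TRUE,
                       digits = NA)
  cg <- clade_specific_genes(sim$genes, clades)
  readr::write_tsv(cg, p("clade_specific_genes.tsv"))
  jac <- jaccard_distances(sim$genes, partition = part)
  write_distance_matrix(jac, p("jaccard_distances.tsv"))
  ape::write.tree(neighbor_joining(jac), p("accessory_nj.nwk"))

  geo <- geo_distance_matrix(sim$metadata)
  hab <- habitat_matrix(sim$metadata)
  phy <- phylo_distance_matrix(aln = sim$alignment)
  samp <- rownames(geo)
  mantel_habitat <- partial_mantel_test(phy[samp, samp], hab[samp, samp],
                                        geo, n_perm = n_perm,
                                        seed = config$seed)
  mantel_geo <- partial_mantel_test(phy[samp, samp], geo, hab[samp, samp],
                                    n_perm = n_perm, seed = config$seed)
  jsonlite::write_json(
    list(habitat_partial = tidy(mantel_habitat),
         geography_partial = tidy(mantel_geo)),
    p("mantel.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")

  panel <- source_panel(sim)
  origins <- assign_origins(sim$truth$recomb_events, sim$alignment, panel,
                            clades, epsilon = epsilon, tau = tau)
  write_events(origins, p("recomb_origins.tsv"))
  jsonlite::write_json(summarize_origins(origins, clades),
                       p("origin_summary.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")

  rates <- growth_rates(sim$growth, k_min = k_min, r2_min = r2_min)
  readr::write_tsv(rates, p("growth_rates.tsv"))
  growth_cmp <- compare_growth(rates, clades)
  jsonlite::write_json(growth_cmp, p("growth_comparison.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  write_manifest(p("manifest.json"), seed = config$seed,
                 params = list(window = window, step = step, fold = fold,
                               n_perm = n_perm, epsilon = epsilon, tau = tau,
                               k_min = k_min, r2_min = r2_min,
                               config = unclass(config)[setdiff(
                                 names(config), "geo_centroids")]),
                 inputs = p(c("core_alignment.fasta", "gene_matrix.tsv",
                              "metadata.tsv", "growth.tsv")))

  invisible(list(sim = sim, snps = snps, clade_specific = cs,
                 snp_windows = counts, peaks = peaks, fst = fst,
                 partition = part, clade_genes = cg, jaccard = jac,
                 mantel_habitat = mantel_habitat, mantel_geo = mantel_geo,
                 origins = origins, rates = rates,
                 growth_comparison = growth_cmp, dir = out_dir))
}
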