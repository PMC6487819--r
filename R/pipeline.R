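#' Run the full by-catch microbiome pipeline on synthetic data
#'
#' End-to-end driver exercising every stage on one generated data set:
#' generate community + metadata -> deduplication fixture -> minimum-read
#' filter -> library-size frequency test -> co-occurrence network ->
#' guilt-by-association removal -> genome-size + TSS normalization ->
#' Bray-Curtis / binary Jaccard distances -> PCoA + driving taxa ->
#' PERMANOVA + dispersion test -> driving-taxa subnetworks (GraphML +
#' edge list) -> source attribution -> diatom association models. All
#' declared TSV/GraphML outputs are written under `outdir`.
#'
#' @param scenario A [synthetic_scenario()], or a path to a YAML scenario
#'   config.
#' @param outdir Output directory (created if needed).
#' @param seed RNG seed for the whole run.
#' @param n_null Null replicates for the co-occurrence network.
#' @param n_perm PERMANOVA permutations.
#' @param min_reads Detection threshold for the taxon filter.
#' @param alpha Significance level used throughout.
#' @return Invisibly, a list with every intermediate result and the paths
#'   written.
#' @export
run_pipeline <- function(scenario = synthetic_scenario(), outdir = tempfile("skimb_"),
                         seed = 1L, n_null = 999, n_perm = 9999,
                         min_reads = 5L, alpha = 0.05) {
  if (is.character(scenario)) scenario <- scenario_from_yaml(scenario)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outdir, f)

  ## 1. generate ---------------------------------------------------------
  sim <- generate_profiles(scenario, seed = seed)
  write_counts_tsv(sim$counts, pth("counts_raw.tsv"))
  write_table_tsv(sim$metadata, pth("metadata.tsv"))
  write_table_tsv(sim$genome_sizes, pth("genome_sizes.tsv"))
  write_table_tsv(sim$truth$taxa, pth("truth_labels.tsv"))

  ## 2. dedup fixture -----------------------------------------------------
  fq <- pth("reads_synth.fastq")
  gen <- generate_duplicated_reads(200, dup_rate = 0.3, path = fq)
  dd <- merge_identical_reads(fq, output = pth("reads_dedup.fasta"))
  write_table_tsv(data.frame(n_in = dd$n_in, n_out = dd$n_out,
                             truth_unique = gen$n_unique),
                  pth("dedup_stats.tsv"))

  ## 3. filter + forensics ------------------------------------------------
  counts <- filter_min_reads(sim$counts, min_reads = min_reads)
  ft <- taxon_frequency_test(counts, sim$metadata, alpha = alpha)
  write_table_tsv(`class<-`(ft, "data.frame"), pth("frequency_test.tsv"))

  cooc <- cooccurrence_network(counts, n_null = n_null, seed = seed + 1L)
  write_counts_tsv(cooc$score, pth("cooccurrence_scores.tsv"))
  seeds <- unique(c(sim$truth$seed_taxon[!is.na(sim$truth$seed_taxon)],
                    ft$taxon[ft$flagged]))
  removal <- if (length(seeds)) expand_contaminants(cooc, seeds, alpha = alpha)
             else character(0)
  rem <- apply_removal(counts, removal)
  write_table_tsv(data.frame(taxon = rem$removed), pth("removal_report.tsv"))
  if (length(rem$excluded_samples))
    rem$counts <- rem$counts[, !(colnames(rem$counts) %in% rem$excluded_samples),
                             drop = FALSE]
  clean <- rem$counts
  write_counts_tsv(clean, pth("counts_filtered.tsv"))

  ## 4. normalize + beta diversity ---------------------------------------
  gsn <- genome_size_normalize(clean, sim$genome_sizes)
  tssn <- tss_normalize(gsn)
  d_bc <- community_distance(gsn, "bray_curtis")
  d_ja <- community_distance(clean, "jaccard_binary")
  write_dist_tsv(d_bc, pth("dist_bray_curtis.tsv"))
  write_dist_tsv(d_ja, pth("dist_jaccard.tsv"))

  ord <- pcoa(d_bc)
  write_table_tsv(data.frame(axis = seq_along(ord$eigenvalues),
                             eigenvalue = ord$eigenvalues),
                  pth("pcoa_eigenvalues.tsv"))
  write_table_tsv(data.frame(sample = rownames(ord$coordinates),
                             ord$coordinates, check.names = FALSE),
                  pth("pcoa_coordinates.tsv"))
  loads <- taxon_loadings(ord, tssn)
  write_table_tsv(data.frame(taxon = rownames(loads), loads,
                             check.names = FALSE), pth("pcoa_loadings.tsv"))
  driving <- driving_taxa(loads)
  writeLines(driving, pth("driving_taxa.txt"))

  md <- sim$metadata[match(attr(stats::as.dist(d_bc), "Labels"),
                           sim$metadata$sample), ]
  md$log_library_size <- log10(colSums(clean)[md$sample])
  md$human_pct <- 100 * md$human_reads / md$total_reads
  perm <- permanova(d_bc, md,
                    terms = c("latitude", "longitude", "group",
                              "log_library_size", "human_pct"),
                    n_perm = n_perm, seed = seed + 2L)
  write_table_tsv(`class<-`(perm, "data.frame"), pth("permanova.tsv"))
  disp <- dispersion_test(d_bc, md$group)

  ## 5. networks ----------------------------------------------------------
  g <- driving_subnetworks(cooc, driving, top_k = 20, alpha = alpha)
  export_graph(g, pth("network.graphml"), format = "both")

  ## 6. source attribution ------------------------------------------------
  ss <- generate_source_sink(n_sources = 3,
                             mixing = rbind(c(0.6, 0.3, 0.1), c(1, 0, 0)),
                             seed = seed + 3L)
  attr_tab <- attribute_all(ss$sinks, ss$sources, seed = seed + 4L)
  write_table_tsv(attr_tab, pth("attribution.tsv"))

  ## 7. diatom models -----------------------------------------------------
  md_all <- sim$metadata[sim$metadata$sample %in% colnames(clean), ]
  algae <- grep("^algae_", rownames(clean), value = TRUE)
  dmods <- diatom_association_models(md_all, clean, algae_taxa = algae,
                                     pathogen_taxon = "Tenacibaculum_dicentrarchi")
  dm_tab <- do.call(rbind, lapply(names(dmods$models), function(nm) {
    co <- dmods$models[[nm]]$coefficients
    cbind(model = nm, co, dispersion = dmods$models[[nm]]$dispersion)
  }))
  write_table_tsv(dm_tab, pth("diatom_models.tsv"))
  grade <- tryCatch(colour_grade_association(md_all), error = function(e) NULL)

  invisible(list(scenario = scenario, sim = sim, dedup = dd, counts = clean,
                 freq_test = ft, cooccurrence = cooc, removal = rem,
                 distances = list(bray_curtis = d_bc, jaccard = d_ja),
                 ordination = ord, loadings = loads, driving = driving,
                 permanova = perm, dispersion = disp, network = g,
                 source_sink = ss, attribution = attr_tab,
                 diatom_models = dmods, colour_grade = grade,
                 outdir = outdir))
}
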