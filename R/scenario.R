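#' Default ecotype sampling design
#'
#' Five host groups with the sampling layout of the motivating study system:
#' two North Pacific ecotypes (10 samples each) and three Antarctic ecotypes
#' (8, 11 and 10 samples). Latitude/longitude are representative group
#' centroids in decimal degrees; per-sample jitter is added at generation
#' time.
#'
#' @return A data.frame with columns `label`, `latitude`, `longitude`, `n`.
#' @export
default_groups <- function() {
  data.frame(
    label     = c("resident", "transient", "B1", "B2", "C"),
    latitude  = c(55, 52, -64.5, -64.0, -71.5),
    longitude = c(-150, -145, -62.5, -61.0, 169.0),
    n         = c(10, 10, 8, 11, 10),
    stringsAsFactors = FALSE
  )
}

#' Construct a synthetic-data scenario
#'
#' A scenario bundles every parameter of the synthetic community generator:
#' the sampling design, the taxon-class sizes, sequencing-depth range, the
#' planted contamination model, and effect sizes linking diatom load to the
#' pathogen/algae taxon block.
#'
#' Defaults emulate the study conditions the generator is meant to mirror:
#' 49 samples in five groups, ~300 taxa with heavy-tailed (log-normal)
#' abundances, 20 reagent contaminants with constant absolute DNA input per
#' sample, a human-associated contaminant block co-occurring with a seeded
#' contaminant, microbial library sizes spanning two orders of magnitude, a
#' group (ecotype) effect sized to explain roughly 10% of Bray-Curtis
#' community variance, and a diatom-load gradient confined to the Antarctic
#' groups.
#'
#' @param n_samples Total number of samples; must equal `sum(groups$n)`.
#' @param groups Data.frame of group label, latitude, longitude, n.
#' @param n_core_taxa Taxa shared across all groups.
#' @param n_group_taxa Group-enriched taxa (distributed round-robin).
#' @param n_reagent_contaminants Taxa with constant absolute input per sample.
#' @param n_human_block Human-associated contaminant taxa co-varying with the
#'   per-sample human-contamination fraction; the first is the designated
#'   seed contaminant (`Cutibacterium_acnes`).
#' @param n_diatom_block Algae-associated taxa whose abundance tracks diatom
#'   load (one extra pathogen taxon, `Tenacibaculum_dicentrarchi`, is always
#'   added).
#' @param library_size_range Min/max microbial (non-host) reads per sample;
#'   depths are drawn log-uniformly so the range spans the ratio
#'   `max / min` (default 100x).
#' @param contaminant_absolute_count Expected absolute reads contributed by a
#'   reagent contaminant to every sample, independent of library size.
#' @param abundance_shape Log-normal sigma of baseline taxon abundances
#'   (heavy tail).
#' @param group_effect Multiplicative enrichment of a group taxon within its
#'   own group (default calibrated so the group term explains ~10% of
#'   Bray-Curtis variance at the default design).
#' @param diatom_effect Log-scale effect of standardized diatom load on the
#'   pathogen and algae-block taxa (0 = independence).
#' @param human_effect Log-scale effect of the standardized per-sample
#'   human-contamination fraction on the human-contaminant block (seed
#'   included) — the mechanism making the block co-occur with the seed.
#' @param n_lanes Sequencing lanes each sample's pool is split across.
#' @param host_fraction Fraction of total sequenced reads that map to the
#'   host (bookkeeping only; no host reads are generated).
#' @param sample_noise Log-normal sigma of per-sample, per-taxon abundance
#'   noise.
#' @param seed Optional RNG seed stored with the scenario.
#'
#' @return An object of class `syn_scenario` (a validated list).
#' @export
synthetic_scenario <- function(n_samples = 49L,
                               groups = default_groups(),
                               n_core_taxa = 220L,
                               n_group_taxa = 40L,
                               n_reagent_contaminants = 20L,
                               n_human_block = 15L,
                               n_diatom_block = 8L,
                               library_size_range = c(5e3, 5e5),
                               contaminant_absolute_count = 400,
                               abundance_shape = 1.75,
                               group_effect = 2.75,
                               diatom_effect = 3,
                               human_effect = 3,
                               n_lanes = 2L,
                               host_fraction = 0.975,
                               sample_noise = 0.6,
                               seed = NULL) {
  sc <- list(
    n_samples = as.integer(n_samples),
    groups = groups,
    n_core_taxa = as.integer(n_core_taxa),
    n_group_taxa = as.integer(n_group_taxa),
    n_reagent_contaminants = as.integer(n_reagent_contaminants),
    n_human_block = as.integer(n_human_block),
    n_diatom_block = as.integer(n_diatom_block),
    library_size_range = as.numeric(library_size_range),
    contaminant_absolute_count = as.numeric(contaminant_absolute_count),
    abundance_shape = as.numeric(abundance_shape),
    group_effect = as.numeric(group_effect),
    diatom_effect = as.numeric(diatom_effect),
    human_effect = as.numeric(human_effect),
    n_lanes = as.integer(n_lanes),
    host_fraction = as.numeric(host_fraction),
    sample_noise = as.numeric(sample_noise),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(sc) <- "syn_scenario"
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "syn_scenario"))
  counts <- c(sc$n_core_taxa, sc$n_group_taxa, sc$n_reagent_contaminants,
              sc$n_human_block, sc$n_diatom_block, sc$n_lanes)
  if (any(is.na(counts)) || any(counts < 0))
    stop("invalid scenario: all taxon/lane counts must be >= 0")
  if (sc$n_samples < 1L)
    stop("invalid scenario: zero samples")
  if (sc$n_core_taxa + sc$n_group_taxa + sc$n_reagent_contaminants +
      sc$n_human_block + sc$n_diatom_block < 1L)
    stop("invalid scenario: zero taxa")
  if (!is.data.frame(sc$groups) ||
      !all(c("label", "latitude", "longitude", "n") %in% names(sc$groups)))
    stop("invalid scenario: groups must have label/latitude/longitude/n")
  if (sum(sc$groups$n) != sc$n_samples)
    stop("invalid scenario: group sample counts must sum to n_samples")
  if (length(sc$library_size_range) != 2 || sc$library_size_range[1] < 1 ||
      diff(sc$library_size_range) < 0)
    stop("invalid scenario: library_size_range must be (min >= 1, max >= min)")
  if (sc$contaminant_absolute_count < 0)
    stop("invalid scenario: contaminant_absolute_count must be >= 0")
  if (sc$n_lanes < 1L)
    stop("invalid scenario: n_lanes must be >= 1")
  invisible(sc)
}

#' @export
print.syn_scenario <- function(x, ...) {
  n_taxa <- x$n_core_taxa + x$n_group_taxa + x$n_reagent_contaminants +
    x$n_human_block + x$n_diatom_block + 1L
  cat("Synthetic community scenario\n")
  cat(sprintf("  samples: %d in %d groups (%s)\n", x$n_samples,
              nrow(x$groups), paste(x$groups$label, collapse = ", ")))
  cat(sprintf("  taxa: %d (core %d, group %d, reagent %d, human block %d, algae block %d, pathogen 1)\n",
              n_taxa, x$n_core_taxa, x$n_group_taxa,
              x$n_reagent_contaminants, x$n_human_block, x$n_diatom_block))
  cat(sprintf("  microbial depth: %g-%g reads; reagent input %g reads/sample\n",
              x$library_size_range[1], x$library_size_range[2],
              x$contaminant_absolute_count))
  cat(sprintf("  effects: group x%g, diatom %g; lanes: %d\n",
              x$group_effect, x$diatom_effect, x$n_lanes))
  invisible(x)
}

#' Read a scenario from a YAML config
#'
#' Any field of [synthetic_scenario()] may appear in the YAML file; `groups`
#' is given as a list of `{label, latitude, longitude, n}` records. Missing
#' fields take the scenario defaults.
#'
#' @param path Path to a YAML file.
#' @return A `syn_scenario`.
#' @export
scenario_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$groups)) {
    cfg$groups <- do.call(rbind, lapply(cfg$groups, function(g) {
      # YAML 1.1 parses a bare `n` key as the boolean FALSE
      n_val <- if (!is.null(g[["n"]])) g[["n"]] else g[["FALSE"]]
      data.frame(label = g$label, latitude = g$latitude,
                 longitude = g$longitude, n = n_val,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(cfg$n_samples)) cfg$n_samples <- sum(cfg$groups$n)
  }
  known <- names(formals(synthetic_scenario))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown scenario fields: ", paste(unknown, collapse = ", "))
  do.call(synthetic_scenario, cfg)
}
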