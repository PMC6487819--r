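#' Generate a synthetic taxon-by-sample community with known ground truth
#'
#' Draws a taxon-by-sample integer count table whose statistical structure
#' mirrors shotgun by-catch microbiome data: heavy-tailed (log-normal)
#' baseline abundances, group-enriched taxa, reagent contaminants with a
#' constant expected absolute read input per sample (so their *proportion*
#' is inversely related to library size), a human-associated contaminant
#' block that co-varies with the per-sample human-contamination fraction
#' (seeded by `Cutibacterium_acnes`), and a pathogen plus algae-associated
#' block whose abundance increases with each sample's diatom load.
#'
#' Counts are multinomial draws at a log-uniformly distributed microbial
#' depth, so every column sum equals the drawn library size exactly. Host
#' reads are bookkeeping only: `total_reads` in the metadata is the depth
#' divided by the non-host fraction. Each sample's counts are additionally
#' split multinomially across its group's sequencing lanes.
#'
#' @param scenario A [synthetic_scenario()].
#' @param seed RNG seed; overrides `scenario$seed`.
#'
#' @return A list of class `syn_community`:
#' \describe{
#'   \item{counts}{taxa x samples integer matrix}
#'   \item{metadata}{data.frame: sample, group, latitude, longitude,
#'     total_reads, human_reads, diatom_reads, lanes, colour_grade}
#'   \item{genome_sizes}{data.frame: taxon, size_bp, level}
#'   \item{truth}{ground-truth labels: `taxa` (taxon, class),
#'     `diatom_load` (named per-sample vector), `seed_taxon`,
#'     `human_fraction`}
#'   \item{lane_counts}{taxa x samples x n_lanes array summing to `counts`}
#' }
#' @export
generate_profiles <- function(scenario = synthetic_scenario(), seed = NULL) {
  validate_scenario(scenario)
  seed <- if (!is.null(seed)) seed else scenario$seed
  if (!is.null(seed)) set.seed(seed)

  grp <- scenario$groups
  groups <- rep(grp$label, grp$n)
  m <- scenario$n_samples
  samples <- sprintf("%s_%02d", groups, stats::ave(seq_len(m), groups, FUN = seq_along))

  ## taxon universe -----------------------------------------------------
  classes <- c(rep("core", scenario$n_core_taxa),
               rep("group_specific", scenario$n_group_taxa),
               rep("reagent_contaminant", scenario$n_reagent_contaminants),
               rep("human_contaminant", scenario$n_human_block),
               rep("diatom_associated", scenario$n_diatom_block),
               "pathogen")
  taxa <- character(length(classes))
  taxa[classes == "core"] <- sprintf("core_%03d", seq_len(scenario$n_core_taxa))
  if (scenario$n_group_taxa > 0) {
    owner <- grp$label[(seq_len(scenario$n_group_taxa) - 1L) %% nrow(grp) + 1L]
    taxa[classes == "group_specific"] <-
      sprintf("grp_%s_%02d", owner, stats::ave(seq_len(scenario$n_group_taxa), owner, FUN = seq_along))
  } else owner <- character(0)
  taxa[classes == "reagent_contaminant"] <-
    sprintf("reagent_%02d", seq_len(scenario$n_reagent_contaminants))
  if (scenario$n_human_block > 0)
    taxa[classes == "human_contaminant"] <-
      c("Cutibacterium_acnes",
        sprintf("human_%02d", seq_len(scenario$n_human_block))[-1])
  taxa[classes == "diatom_associated"] <-
    sprintf("algae_%02d", seq_len(scenario$n_diatom_block))
  taxa[classes == "pathogen"] <- "Tenacibaculum_dicentrarchi"
  n_tax <- length(taxa)
  seed_taxon <- if (scenario$n_human_block > 0) "Cutibacterium_acnes" else NA_character_

  ## per-sample covariates ----------------------------------------------
  lr <- log(scenario$library_size_range)
  depth <- round(exp(stats::runif(m, lr[1], lr[2])))
  depth <- pmax(depth, 1)
  total_reads <- round(depth / (1 - scenario$host_fraction))
  human_frac <- stats::rbeta(m, 0.5, 312)  # mean ~0.16%, upper tail ~5%
  human_reads <- round(human_frac * total_reads)
  antarctic <- grp$latitude[match(groups, grp$label)] < 0
  diatom_load <- ifelse(antarctic,
                        pmin(stats::rlnorm(m, log(0.010), 1.0), 0.2),
                        pmin(stats::rlnorm(m, log(0.002), 0.8), 0.2))
  names(diatom_load) <- samples
  diatom_reads <- round(diatom_load * total_reads)
  lat <- grp$latitude[match(groups, grp$label)] + stats::runif(m, -1, 1)
  lon <- grp$longitude[match(groups, grp$label)] + stats::runif(m, -1.5, 1.5)

  ## baseline abundances -------------------------------------------------
  base <- stats::rlnorm(n_tax, 0, scenario$abundance_shape)
  ## human-associated taxa are moderately prevalent; the seed dominates
  hb_idx <- classes == "human_contaminant"
  base[hb_idx] <- stats::rlnorm(sum(hb_idx), 1, 1)
  ## algae-block taxa sit at modest baseline abundance; the pathogen is
  ## rare enough that its presence tracks diatom load, not just depth
  db_idx <- classes %in% c("diatom_associated", "pathogen")
  base[db_idx] <- stats::rlnorm(sum(db_idx), -1, 1)
  base[classes == "pathogen"] <- stats::rlnorm(1, -3, 0.5)
  if (!is.na(seed_taxon))
    base[taxa == seed_taxon] <- base[taxa == seed_taxon] * 50  # dominant contaminant
  is_reagent <- classes == "reagent_contaminant"
  reagent_abs <- scenario$contaminant_absolute_count *
    stats::rlnorm(n_tax, 0, 0.25) * is_reagent

  ## standardized log diatom load / human fraction (0 when degenerate) ----
  zstd <- function(v) {
    lv <- log(v)
    if (length(lv) > 1 && stats::sd(lv) > 0) (lv - mean(lv)) / stats::sd(lv)
    else rep(0, length(lv))
  }
  z <- zstd(diatom_load)
  zh <- zstd(pmax(human_frac, 1e-12))

  counts <- matrix(0L, n_tax, m, dimnames = list(taxa, samples))
  group_of_taxon <- rep(NA_character_, n_tax)
  group_of_taxon[classes == "group_specific"] <- owner

  for (s in seq_len(m)) {
    mult <- rep(1, n_tax)
    gt <- classes == "group_specific"
    mult[gt] <- ifelse(group_of_taxon[gt] == groups[s], scenario$group_effect, 1)
    mult[hb_idx] <- exp(scenario$human_effect * zh[s])
    ## the abundant seed loads slightly less on the human factor, keeping
    ## its library-size scaling (and hence a broad co-occurrence pool)
    if (!is.na(seed_taxon))
      mult[taxa == seed_taxon] <-
        exp(0.8 * scenario$human_effect * zh[s])
    db <- classes %in% c("diatom_associated", "pathogen")
    mult[db] <- exp(scenario$diatom_effect * z[s])
    ## the rare pathogen responds more sharply to diatom load than the
    ## algae block, so its presence pattern tracks load rather than depth
    mult[classes == "pathogen"] <- exp(1.5 * scenario$diatom_effect * z[s])
    rel <- base * mult * stats::rlnorm(n_tax, 0, scenario$sample_noise)
    rel[is_reagent] <- 0

    a <- reagent_abs  # expected absolute reagent reads, constant across samples
    budget <- max(depth[s] - sum(a), 0.1 * depth[s])
    e <- if (sum(rel) > 0) rel / sum(rel) * budget else rel
    e[is_reagent] <- a[is_reagent]
    if (sum(e) <= 0) stop("degenerate scenario: no taxon has positive abundance")
    p <- e / sum(e)
    counts[, s] <- stats::rmultinom(1, depth[s], p)[, 1]
  }

  ## lane split ----------------------------------------------------------
  nl <- scenario$n_lanes
  lane_counts <- array(0L, dim = c(n_tax, m, nl),
                       dimnames = list(taxa, samples, paste0("lane", seq_len(nl))))
  lane_ids <- character(m)
  for (s in seq_len(m)) {
    gi <- match(groups[s], grp$label)
    ids <- sprintf("L%d_%d", gi, seq_len(nl))
    lane_ids[s] <- paste(ids, collapse = ";")
    ## equal-probability multinomial split, drawn as a binomial chain
    remaining <- counts[, s]
    for (k in seq_len(nl - 1L)) {
      x <- stats::rbinom(n_tax, remaining, 1 / (nl - k + 1L))
      lane_counts[, s, k] <- x
      remaining <- remaining - x
    }
    lane_counts[, s, nl] <- remaining
  }

  ## colour grades for Antarctic B1/B2 hosts ------------------------------
  grades <- c("clean", "slight", "moderate", "prominent")
  colour <- rep(NA_character_, m)
  bb <- groups %in% c("B1", "B2")
  if (any(bb)) {
    q <- stats::quantile(diatom_load[bb], c(0.25, 0.5, 0.75))
    colour[bb] <- grades[findInterval(diatom_load[bb], q) + 1L]
  }

  metadata <- data.frame(
    sample = samples, group = groups, latitude = lat, longitude = lon,
    total_reads = total_reads, human_reads = human_reads,
    diatom_reads = diatom_reads, lanes = lane_ids,
    colour_grade = colour, stringsAsFactors = FALSE
  )

  genome_sizes <- data.frame(
    taxon = taxa,
    size_bp = round(stats::runif(n_tax, 1e6, 1e7)),
    level = sample(c("strain", "species"), n_tax, replace = TRUE, prob = c(0.3, 0.7)),
    stringsAsFactors = FALSE
  )

  out <- list(
    counts = counts,
    metadata = metadata,
    genome_sizes = genome_sizes,
    truth = list(
      taxa = data.frame(taxon = taxa, class = classes, stringsAsFactors = FALSE),
      diatom_load = diatom_load,
      seed_taxon = seed_taxon,
      human_fraction = stats::setNames(human_frac, samples)
    ),
    lane_counts = lane_counts
  )
  class(out) <- "syn_community"
  out
}

#' @export
print.syn_community <- function(x, ...) {
  cat(sprintf("Synthetic community: %d taxa x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$truth$taxa$class)),
                                  table(x$truth$taxa$class)), collapse = ", "), "\n")
  cat(sprintf("  depth: %d-%d microbial reads/sample\n",
              min(colSums(x$counts)), max(colSums(x$counts))))
  invisible(x)
}

#' Generate source communities and mixed sink samples
#'
#' Builds `n_sources` source environments with disjoint taxon pools plus a
#' disjoint "Unknown" pool, then draws each sink as a multinomial sample
#' from the stated mixture of source community distributions; the
#' remainder (1 - sum of mixing proportions) is drawn from the Unknown
#' pool. Ground-truth mixing proportions are returned for attribution
#' benchmarking.
#'
#' @param n_sources Number of source environments.
#' @param mixing Matrix (sinks x sources) or single vector of mixing
#'   proportions; each row must be nonnegative and sum to at most 1.
#' @param n_taxa_per_source Taxa in each source pool.
#' @param n_unknown_taxa Taxa in the Unknown pool.
#' @param sink_depth Reads per sink sample.
#' @param source_depth Reads per source profile.
#' @param abundance_shape Log-normal sigma of within-source profiles.
#' @param seed RNG seed.
#'
#' @return List of class `syn_source_sink`: `sources` (taxa x n_sources
#'   counts), `sinks` (taxa x n_sinks counts), `mixing` (truth, with an
#'   Unknown column), `profiles` (true source probability vectors).
#' @export
generate_source_sink <- function(n_sources = 3L, mixing = c(0.6, 0.3, 0.1),
                                 n_taxa_per_source = 50L, n_unknown_taxa = 50L,
                                 sink_depth = 5000L, source_depth = 10000L,
                                 abundance_shape = 1.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(mixing))) mixing <- matrix(mixing, nrow = 1)
  mixing <- as.matrix(mixing)
  if (ncol(mixing) != n_sources)
    stop("mixing must have one proportion per source")
  if (any(mixing < 0) || any(rowSums(mixing) > 1 + 1e-9))
    stop("mixing proportions must be >= 0 and sum to <= 1 per sink")

  taxa <- c(unlist(lapply(seq_len(n_sources), function(k)
    sprintf("src%d_taxon%03d", k, seq_len(n_taxa_per_source)))),
    sprintf("unknown_taxon%03d", seq_len(n_unknown_taxa)))
  n_tax <- length(taxa)

  profiles <- matrix(0, n_tax, n_sources + 1L,
                     dimnames = list(taxa, c(sprintf("source_%d", seq_len(n_sources)), "Unknown")))
  for (k in seq_len(n_sources)) {
    idx <- (k - 1L) * n_taxa_per_source + seq_len(n_taxa_per_source)
    w <- stats::rlnorm(n_taxa_per_source, 0, abundance_shape)
    profiles[idx, k] <- w / sum(w)
  }
  uidx <- n_sources * n_taxa_per_source + seq_len(n_unknown_taxa)
  w <- stats::rlnorm(n_unknown_taxa, 0, abundance_shape)
  profiles[uidx, n_sources + 1L] <- w / sum(w)

  sources <- sapply(seq_len(n_sources), function(k)
    stats::rmultinom(1, source_depth, profiles[, k])[, 1])
  dimnames(sources) <- list(taxa, sprintf("source_%d", seq_len(n_sources)))

  n_sinks <- nrow(mixing)
  sinks <- matrix(0L, n_tax, n_sinks,
                  dimnames = list(taxa, sprintf("sink_%d", seq_len(n_sinks))))
  for (i in seq_len(n_sinks)) {
    p <- profiles[, seq_len(n_sources), drop = FALSE] %*% mixing[i, ] +
      (1 - sum(mixing[i, ])) * profiles[, n_sources + 1L]
    sinks[, i] <- stats::rmultinom(1, sink_depth, p)[, 1]
  }

  truth <- cbind(mixing, Unknown = 1 - rowSums(mixing))
  colnames(truth) <- c(sprintf("source_%d", seq_len(n_sources)), "Unknown")
  rownames(truth) <- colnames(sinks)
  structure(list(sources = sources, sinks = sinks, mixing = truth,
                 profiles = profiles),
            class = "syn_source_sink")
}

#' Generate a FASTQ read set with controlled PCR-style duplication
#'
#' Emits `n_unique` distinct random sequences, each repeated `1 + G` times
#' with `G` geometric with success probability `1 - dup_rate`, so the
#' expected total read count is `n_unique / (1 - dup_rate)`. Serves as a
#' fixture with known truth for the identical-read deduplication utility.
#'
#' @param n_unique Number of distinct sequences.
#' @param dup_rate Duplication probability in `[0, 1)`.
#' @param read_length Sequence length (bp).
#' @param path Optional output FASTQ path; written as plain 4-line records.
#' @param seed RNG seed.
#'
#' @return List: `path` (or NULL), `sequences` (emitted, duplicates
#'   included, in shuffled order), `n_unique`, `n_total`.
#' @export
generate_duplicated_reads <- function(n_unique, dup_rate = 0, read_length = 60L,
                                      path = NULL, seed = NULL) {
  if (dup_rate < 0 || dup_rate >= 1) stop("dup_rate must be in [0, 1)")
  if (n_unique < 0) stop("n_unique must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  uniq <- character(0)
  while (length(uniq) < n_unique) {
    need <- n_unique - length(uniq)
    fresh <- vapply(seq_len(need), function(i)
      paste(sample(c("A", "C", "G", "T"), read_length, replace = TRUE), collapse = ""),
      character(1))
    uniq <- unique(c(uniq, fresh))
  }
  copies <- 1L + stats::rgeom(n_unique, prob = 1 - dup_rate)
  reads <- rep(uniq, times = copies)
  if (length(reads) > 1) reads <- sample(reads)
  ids <- sprintf("@read_%06d", seq_along(reads))
  if (!is.null(path)) {
    qual <- strrep("I", read_length)
    writeLines(rbind(ids, reads, rep("+", length(reads)),
                     rep(qual, length(reads))), con = path)
  }
  list(path = path, sequences = reads, n_unique = n_unique,
       n_total = length(reads))
}
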