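# Small deterministic fixtures shared across tests.

toy_counts <- function() {
  m <- matrix(c(10, 0, 5, 25,
                2, 3, 0, 7,
                40, 12, 8, 1,
                0, 0, 6, 6,
                1, 9, 9, 9), nrow = 5, byrow = TRUE)
  dimnames(m) <- list(paste0("t", 1:5), paste0("s", 1:4))
  m
}

small_scenario <- function(...) {
  defaults <- list(
    n_samples = 20L,
    groups = data.frame(label = c("A", "B"), latitude = c(55, -65),
                        longitude = c(-150, -60), n = c(10, 10)),
    n_core_taxa = 60L, n_group_taxa = 10L, n_reagent_contaminants = 5L,
    n_human_block = 6L, n_diatom_block = 4L,
    library_size_range = c(2e3, 2e4)
  )
  do.call(synthetic_scenario, utils::modifyList(defaults, list(...)))
}

# independently coded CSS oracle: quantile-capped cumulative sums
css_oracle <- function(counts, p = 0.5) {
  sf <- stats::setNames(numeric(ncol(counts)), colnames(counts))
  for (s in seq_len(ncol(counts))) {
    x <- counts[, s]
    nz <- sort(x[x > 0])
    q <- stats::quantile(nz, p, names = FALSE)
    sf[s] <- sum(x[x <= q])
  }
  med <- stats::median(sf)
  out <- counts
  for (s in seq_len(ncol(counts))) out[, s] <- counts[, s] / sf[s] * med
  list(counts = out, factors = sf)
}
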