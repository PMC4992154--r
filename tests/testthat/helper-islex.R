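# Shared test fixtures and independent oracles.

# Hand-built dataset: 4 islands, 8 populations, no randomness.
toy_dataset <- function() {
  islands <- data.frame(
    island_id = c("i1", "i2", "i3", "i4"),
    area = c(0.4, 5, 60, 900),
    elevation = c(3, 40, 300, 1500),
    precipitation = c(600, 1100, 1500, 2400),
    mean_temperature = c(25, 22, 20, 17),
    temperature_seasonality = c(2, 3, 4, 6),
    human_presence = c(0L, 0L, 1L, 1L),
    stringsAsFactors = FALSE
  )
  for (g in invasive_groups()) islands[[g]] <- 0L
  islands$rats <- c(0L, 1L, 1L, 1L)
  islands$felids <- c(0L, 0L, 1L, 1L)
  populations <- data.frame(
    species_id = c("a", "b", "a", "c", "d", "e", "f", "g"),
    island_id = c("i1", "i1", "i2", "i2", "i3", "i3", "i4", "i4"),
    class_volancy = c("reptile", "volant_bird", "reptile", "amphibian",
                      "nonvolant_mammal", "bat", "volant_bird",
                      "nonvolant_bird"),
    outcome = c(0L, 0L, 1L, 0L, 1L, 0L, 1L, 0L),
    stringsAsFactors = FALSE
  )
  islex_dataset(islands, populations, provenance = "toy")
}

# O(n^2) concordance-count AUC with ties counted 1/2.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Brute-force bivariate-normal orthant probability P(Z1 < a, Z2 < b; r)
# by midpoint-rule grid integration (independent of mvtnorm).
brute_force_orthant <- function(a, b, r, n = 3000L) {
  lo <- -8
  z1 <- seq(lo, a, length.out = n + 1L)
  z2 <- seq(lo, b, length.out = n + 1L)
  m1 <- (z1[-1L] + z1[-(n + 1L)]) / 2
  m2 <- (z2[-1L] + z2[-(n + 1L)]) / 2
  h1 <- z1[2L] - z1[1L]
  h2 <- z2[2L] - z2[1L]
  dens <- outer(m1, m2, function(x, y) {
    exp(-(x^2 - 2 * r * x * y + y^2) / (2 * (1 - r^2))) /
      (2 * pi * sqrt(1 - r^2))
  })
  sum(dens) * h1 * h2
}

# Moment estimate of the common within-cluster Pearson correlation of a
# binary outcome, given known marginal probabilities.
moment_outcome_correlation <- function(y, p, cluster) {
  e <- (y - p) / sqrt(p * (1 - p))
  cl <- factor(cluster)
  se <- rowsum(e, cl)
  s2 <- rowsum(e^2, cl)
  ni <- as.integer(table(cl))
  sum((se^2 - s2) / 2) / sum(ni * (ni - 1) / 2)
}

# Minimal design wrapper so fit_gee can run on a raw matrix in tests.
manual_design <- function(X, y, cluster) {
  structure(list(y = as.integer(y), X = X, cluster = as.character(cluster),
                 term_map = data.frame(column = colnames(X),
                                       term = colnames(X),
                                       stringsAsFactors = FALSE),
                 keys = data.frame(species_id = as.character(seq_along(y)),
                                   island_id = as.character(cluster),
                                   stringsAsFactors = FALSE),
                 extant = 1L - as.integer(y),
                 class_volancy = rep("reptile", length(y)),
                 single_island_endemic = rep(1L, length(y)),
                 spec = NULL, use_historical_presence = TRUE,
                 n_dropped = 0L),
            class = "islex_design")
}
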