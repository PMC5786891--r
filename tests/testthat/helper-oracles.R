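# Independent oracles used by the property and acceptance tests.  These
# deliberately avoid the package's code paths: the PSD oracle is a direct
# O(n^2) DFT, and the K-means oracle enumerates all partitions.

# Direct-definition PSD: per channel, U[q] = sum_t x[t] exp(-2*pi*i*q*t/n)
# on the zero-padded indicator, summed |U|^2 over channels.
oracle_psd <- function(residues, n = nchar(residues), drop_dc = FALSE) {
  chars <- strsplit(toupper(residues), "", fixed = TRUE)[[1]]
  out <- numeric(n)
  for (base in c("A", "G", "C", "T")) {
    x <- as.numeric(chars == base)
    x <- c(x, numeric(n - length(x)))
    for (q in 0:(n - 1)) {
      u <- sum(x * exp(-2i * pi * q * (0:(n - 1)) / n))
      out[q + 1] <- out[q + 1] + Mod(u)^2
    }
  }
  if (drop_dc) out[1] <- 0
  out
}

# All ways to label m items with exactly k blocks, as restricted growth
# strings (canonical set partitions; no relabeling duplicates).
enumerate_partitions <- function(m, k) {
  out <- list()
  recurse <- function(labels, used) {
    i <- length(labels) + 1L
    if (i > m) {
      if (used == k) out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    # pruning: remaining positions must be able to reach k blocks
    if (used + (m - i + 1L) < k) return(invisible())
    for (lab in seq_len(min(used + 1L, k))) {
      recurse(c(labels, lab), max(used, lab))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Minimal within-cluster sum of squares over all exact-k partitions.
oracle_best_objective <- function(x, k) {
  parts <- enumerate_partitions(nrow(x), k)
  best <- Inf
  for (labels in parts) {
    counts <- tabulate(labels, nbins = k)
    sums <- rowsum(x, labels)
    # SSW = sum ||x||^2 - sum_j ||S_j||^2 / m_j
    obj <- sum(x^2) - sum(rowSums(sums^2) / counts)
    if (obj < best) best <- obj
  }
  best
}

# Random nucleotide string (unambiguous unless asked otherwise).
random_seq <- function(len, ambiguous = FALSE) {
  alphabet <- c("A", "C", "G", "T", if (ambiguous) c("N", "R", "Y"))
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Three well-separated synthetic families used across tests: period-2 and
# period-3 motif ancestors plus a uniform-composition ancestor, 15 x 300,
# per-site substitution probability 0.02.
planted_families <- function(seed = 2024L, n = 15L, len = 300L,
                             mu = 0.02) {
  generate_dataset(list(
    family_spec("per2", n, len, mu, motif = "AT"),
    family_spec("per3", n, len, mu, motif = "ACA"),
    family_spec("unif", n, len, mu)), seed = seed)
}
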