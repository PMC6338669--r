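# shared fixtures and independent oracles

# small synthetic dataset; thin wrapper keeping test-local sizes in one place
small_cells <- function(n_cells = 300, n_replicates = 1, seed = 42, ...) {
  simulate_cells(sim_config(n_cells = n_cells, n_replicates = n_replicates,
                            seed = seed, ...))
}

# independent plug-in MI oracle: entropies of a contingency table, in bits
mi_from_table <- function(tab) {
  p <- tab / sum(tab)
  H <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  H(rowSums(p)) + H(colSums(p)) - H(as.vector(p))
}

# binary entropy, bits
H2 <- function(p) {
  out <- numeric(length(p))
  i <- p > 0 & p < 1
  out[i] <- -p[i] * log2(p[i]) - (1 - p[i]) * log2(1 - p[i])
  out
}

one_replicate <- function(cells, r = "1") {
  out <- cells[cells$replicate == r, , drop = FALSE]
  class(out) <- c("cell_table", "data.frame")
  out
}
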