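# shared fixtures and independent oracles, all generated in code

# small simulated volume for module tests
small_sim <- function(seed = 1, n_sections = 2, spots_per_section = 300,
                      n_genes = 400, ...) {
  p <- sim_params(n_sections = n_sections,
                  spots_per_section = spots_per_section,
                  n_genes = n_genes, seed = seed, ...)
  ref <- make_reference(p)
  sim <- simulate_volume(p, ref$signature_matrix)
  list(params = p, ref = ref, sim = sim)
}

# oracle: naive MatrixMarket triplet reader -> dense matrix
naive_mtx_dense <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "%")]
  hdr <- scan(text = lines[1], quiet = TRUE)
  m <- matrix(0, hdr[1], hdr[2])
  for (l in lines[-1]) {
    tr <- scan(text = l, quiet = TRUE)
    m[tr[1], tr[2]] <- tr[3]
  }
  m
}

# oracle: step-up BH adjustment from the definition
manual_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# oracle: exact hypergeometric upper tail by enumerating all C(N, n) draws
enumerated_tail <- function(N, K, n, k) {
  draws <- combn(N, n)
  inset <- seq_len(K)  # wlog the first K universe elements form the set
  overlaps <- apply(draws, 2, function(d) sum(d %in% inset))
  mean(overlaps >= k)
}

# oracle: hand-rolled NB sampling check helper
write_tsv_counts <- function(m, path) {
  df <- data.frame(barcode = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
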