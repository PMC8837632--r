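toy_norm <- function(v) {
  dimnames(v) <- list(sprintf("r%02d", seq_len(nrow(v))),
                      sprintf("g%02d", seq_len(ncol(v))))
  spot_matrix(v, "sizefactor")
}

test_that("co-expression validity: sign rule, self-correlation, brute force", {
  set.seed(31)
  n <- 40
  base <- rnorm(n)
  v <- cbind(base + rnorm(n, 0, .1), base + rnorm(n, 0, .1),
             base + rnorm(n, 0, .1), -base + rnorm(n, 0, .1))
  m <- toy_norm(v)
  keep <- valid_coexpressed_genes(m, colnames(m$values))
  expect_equal(keep, c("g01", "g02", "g03"))
  # a marker paired with itself correlates exactly 1
  expect_equal(cor(v[, 1], v[, 1]), 1)
  # brute force on random values, both rules
  set.seed(32)
  w <- matrix(rnorm(10 * 6), 10, 6)
  mw <- toy_norm(w)
  cc <- cor(w)
  for (rule in c("mean", "all_pairs")) {
    expected <- colnames(mw$values)[vapply(1:6, function(j) {
      off <- cc[j, -j]
      if (rule == "mean") mean(off) > 0 else all(off > 0)
    }, logical(1))]
    expect_equal(valid_coexpressed_genes(mw, colnames(mw$values), rule = rule),
                 expected)
  }
})

test_that("marker presence below the threshold makes a type unscoreable", {
  set.seed(33)
  m <- toy_norm(matrix(abs(rnorm(20 * 8)), 20, 8))
  expect_equal(valid_coexpressed_genes(m, c("g01", "g02", "g03")),
               character(0))
  expect_warning(
    keep <- valid_coexpressed_genes(
      toy_norm(cbind(matrix(abs(rnorm(20 * 4)), 20, 4), 0, 0) + 0),
      paste0("g0", 1:6), min_markers = 4),
    "zero-variance")
})

test_that("the three-spot two-type worked example evaluates by hand", {
  v <- matrix(c(2, 0, 1,
                0, 4, 1), nrow = 3,
              dimnames = list(c("r1", "r2", "r3"), c("gA", "gB")))
  m <- spot_matrix(v, "sizefactor")
  sig <- signature_set(data.frame(cell_type = c("A", "B"),
                                  gene = c("gA", "gB"),
                                  avg_logfc = 2, fdr = 1e-4))
  sc <- score_cell_types(m, sig, min_markers = 1)
  expect_equal(unname(sc$raw[, "A"]), c(2, 0, 1))
  expect_equal(unname(sc$raw[, "B"]), c(0, 4, 1))
  expect_equal(unname(sc$max_scaled[, "A"]), c(1, 0, 0.5))
  expect_equal(unname(sc$max_scaled[, "B"]), c(0, 1, 0.25))
  expect_equal(unname(sc$proportions["r3", ]), c(2 / 3, 1 / 3))
  expect_equal(unname(sc$proportions["r1", ]), c(1, 0))
  # single-type degenerate case: proportion 1 wherever the score is nonzero
  sc1 <- score_cell_types(m, sig[1], min_markers = 1)
  expect_equal(unname(sc1$proportions[c(1, 3), 1]), c(1, 1))
  expect_true(is.na(sc1$proportions[2, 1]))  # zero-score spot undefined
})

test_that("score invariants hold on simulated data", {
  fx <- small_sim(seed = 34, spots_per_section = 250, n_sections = 1)
  norm <- normalize_spots(filter_spots(fx$sim$counts, 50), "size_factor_log")
  sc <- score_cell_types(norm, fx$ref$signatures)
  ok <- sc$scoreable
  expect_true(all(sc$raw[, ok] >= 0))
  expect_true(all(sc$max_scaled[, ok] >= 0 & sc$max_scaled[, ok] <= 1))
  expect_equal(unname(apply(sc$max_scaled[, ok], 2, max)), rep(1, sum(ok)))
  sums <- rowSums(sc$proportions[, ok, drop = FALSE])
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-9))
  # doubling every normalized value changes neither max-scaled nor proportions
  m2 <- spot_matrix(as.matrix(norm$values) * 2, "sizefactor")
  sc2 <- score_cell_types(m2, fx$ref$signatures)
  expect_equal(sc2$max_scaled, sc$max_scaled)
  expect_equal(sc2$proportions, sc$proportions)
})

test_that("scoring is equivariant under type and spot permutations", {
  fx <- small_sim(seed = 35, spots_per_section = 150, n_sections = 1,
                  n_genes = 300)
  norm <- normalize_spots(filter_spots(fx$sim$counts, 50), "size_factor_log")
  sc <- score_cell_types(norm, fx$ref$signatures)
  perm <- rev(seq_along(fx$ref$signatures))
  sig_p <- fx$ref$signatures[perm]
  class(sig_p) <- "signature_set"
  sc_p <- score_cell_types(norm, sig_p)
  expect_equal(sc_p$proportions, sc$proportions[, perm])
  rows <- sample(nrow(norm$values))
  m_p <- spot_matrix(as.matrix(norm$values)[rows, ], "sizefactor")
  sc_r <- score_cell_types(m_p, fx$ref$signatures)
  expect_equal(sc_r$proportions, sc$proportions[rows, ])
})

test_that("zone-dominant types are recovered from the proportions", {
  fx <- small_sim(seed = 36, spots_per_section = 400, n_sections = 2)
  sim <- fx$sim
  norm <- normalize_spots(filter_spots(sim$counts, 100), "size_factor_log")
  sc <- score_cell_types(norm, fx$ref$signatures)
  tr <- sim$truth[match(rownames(sc$proportions), sim$truth$barcode), ]
  props_true <- as.matrix(tr[, paste0("prop_", colnames(sc$proportions))])
  zones <- unique(tr$true_cluster)
  hits <- vapply(zones, function(z) {
    est <- colMeans(sc$proportions[tr$true_cluster == z, , drop = FALSE])
    tru <- colMeans(props_true[tr$true_cluster == z, , drop = FALSE])
    which.max(est) == which.max(tru)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("colocalization matches the textbook correlation", {
  a <- c(2.1, 3.5, 1.2, 4.8, 2.9, 3.3, 0.7, 4.1, 2.2, 3.9)
  b <- c(1.9, 3.1, 1.5, 4.2, 3.4, 2.8, 1.1, 4.5, 1.8, 3.6)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  cl <- colocalize(a, b)
  expect_equal(cl$pearson_r, r_hand)
  expect_equal(colocalize(a, a)$pearson_r, 1)
  expect_equal(colocalize(a, -a)$pearson_r, -1)
  expect_warning(z <- colocalize(rep(1, 5), a[1:5]), "zero variance")
  expect_true(is.nan(z$pearson_r))
  expect_error(colocalize(a[1:2], b[1:2]), class = "spatlo_validation_error")
})
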