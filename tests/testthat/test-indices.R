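test_that("RSCU equals the family-uniform expectation ratio", {
  # equal counts in a family -> all RSCU 1
  r <- rscu(c(GCT = 10, GCC = 10, GCA = 10, GCG = 10))
  expect_equal(r$rscu[r$amino_acid == "Ala"], rep(1, 4))

  # empty families give NA, not zero
  expect_true(all(is.na(r$rscu[r$amino_acid == "Lys"])))

  # ATG and TGG have RSCU 1 when present
  r2 <- rscu(c(ATG = 5, TGG = 3))
  expect_equal(r2$rscu[r2$codon %in% c("ATG", "TGG")], c(1, 1))
})

test_that("RSCU family sums equal degeneracy on random count tables", {
  set.seed(14)
  for (rep in 1:20) {
    counts <- stats::setNames(rpois(64, lambda = 30) + 1, codon_table()$codon)
    r <- rscu(counts, include_stops = TRUE)
    sums <- tapply(r$rscu, r$amino_acid, sum)
    ks <- tapply(r$k, r$amino_acid, unique)
    expect_true(all(abs(sums - ks) < 1e-6))
  }
})

test_that("per-gene RSCU matrix agrees with pooled RSCU for single genes", {
  seqs <- random_cds_set(n = 5, n_body = 150, seed = 2)
  counts <- count_codons(seqs)
  mat <- rscu_matrix(counts)
  for (i in c(1, 3)) {
    one <- rscu(dplyr::slice(counts, i))
    one <- one[one$codon %in% colnames(mat), ]
    expect_equal(unname(mat[i, one$codon]), one$rscu)
  }
})

test_that("ENc matches a direct evaluation in the one-codon-per-family limit", {
  # 100 counts on a single codon of every family: each F = 1, ENc = 20
  ct <- codon_table()
  one_per <- tapply(ct$codon[ct$aa1 != "*"], ct$amino_acid[ct$aa1 != "*"],
                    function(x) x[1])
  counts <- stats::setNames(rep(100, length(one_per)), unname(one_per))
  expect_equal(enc(counts)$enc, 20)

  # perfectly uniform usage in every family, large n -> near 61
  uniform <- stats::setNames(rep(600, sum(ct$aa1 != "*")),
                             ct$codon[ct$aa1 != "*"])
  expect_lt(abs(enc(uniform)$enc - 61), 0.5)
})

test_that("ENc equals an independently coded estimator on synthetic genes", {
  seqs <- random_cds_set(n = 50, n_body = 150, seed = 17)
  counts <- count_codons(seqs)
  got <- enc(counts)
  m <- as.matrix(counts[, -1])
  rownames(m) <- counts$id
  for (i in seq_len(nrow(m))) {
    expect_equal(got$enc[i], oracle_enc(m[i, ]), tolerance = 1e-9)
  }
  expect_true(all(got$enc >= 20 & got$enc <= 61))
})

test_that("ENc handles degenerate inputs", {
  # all families with n <= 1: no information
  expect_true(is.na(enc(c(TTT = 1, AAA = 1, GGT = 1))$enc))
  # only one informative family still yields a (partial-class) value
  expect_false(is.na(enc(c(TTT = 30, TTC = 10))$enc))
})

test_that("concentrating usage within families never increases ENc", {
  base <- stats::setNames(rep(20, 64), codon_table()$codon)
  shift <- base
  # majorize the Ala family: move counts onto GCT
  shift[c("GCT", "GCC", "GCA", "GCG")] <- c(50, 10, 10, 10)
  expect_lte(enc(shift)$enc, enc(base)$enc)
  shift2 <- shift
  shift2[c("GCT", "GCC", "GCA", "GCG")] <- c(77, 1, 1, 1)
  expect_lte(enc(shift2)$enc, enc(shift)$enc)
})

test_that("the expected-ENc curve matches its closed form", {
  expect_equal(expected_enc(0.5), 60.5)
  expect_equal(expected_enc(0), 31)
  # independent evaluation at an arbitrary point
  s <- 0.466
  expect_equal(expected_enc(s), 2 + s + 29 / (s^2 + (1 - s)^2))
  # symmetry about 0.5 up to the linear term
  ss <- seq(0.05, 0.95, by = 0.05)
  expect_equal(expected_enc(ss) - ss, expected_enc(1 - ss) - (1 - ss))
})

test_that("ENc deviation is the relative shortfall from expectation", {
  expect_equal(enc_deviation(60, 60), 0)
  expect_equal(enc_deviation(54, 60), 0.1)
})

test_that("CAI weights score within-family relative adaptiveness", {
  w <- suppressWarnings(cai_weights(c(AAA = 4, AAG = 2)))  # other families empty
  expect_equal(w$w[w$codon == "AAA"], 1)
  expect_equal(w$w[w$codon == "AAG"], 0.5)

  # empty families are uninformative, warned and set to 1
  expect_warning(w2 <- cai_weights(c(AAA = 4)), "empty families")
  expect_true(all(w2$w[w2$amino_acid == "Phe"] == 1))

  # zero-count codons in a present family are floored, not zero
  w3 <- suppressWarnings(cai_weights(c(GCT = 10, GCC = 0)))
  expect_equal(w3$w[w3$codon == "GCC"], 0.05)
  expect_gt(min(w3$w), 0)
})

test_that("CAI is the geometric mean of weights over informative codons", {
  seqs <- random_cds_set(n = 6, n_body = 120, seed = 9)
  counts <- count_codons(seqs)
  w_uniform <- suppressWarnings(
    cai_weights(stats::setNames(rep(1, 64), codon_table()$codon)))
  expect_equal(cai(counts, w_uniform)$cai, rep(1, 6))

  # two-codon gene with w = {1, 0.25} -> sqrt(0.25)
  w <- suppressWarnings(cai_weights(c(TTT = 4, TTC = 1)))
  two <- tibble::tibble(id = "g", sequence = "ATGTTTTTCTGA")
  expect_equal(cai(count_codons(two), w)$cai, 0.5)

  # brute-force product-then-root on a random gene
  w_ref <- suppressWarnings(cai_weights(pool_counts(counts)))
  got <- cai(counts, w_ref)
  wmap <- stats::setNames(w_ref$w, w_ref$codon)
  for (i in 1:3) {
    codons <- split_codons(seqs$sequence[i])
    codons <- codons[codons %in% names(wmap)]
    expect_equal(got$cai[i], prod(wmap[codons])^(1 / length(codons)))
  }
})

test_that("CAI is invariant to family-wise weight rescaling", {
  seqs <- random_cds_set(n = 4, n_body = 110, seed = 27)
  counts <- count_codons(seqs)
  ref <- pool_counts(counts) + 1
  w <- cai_weights(ref)
  # scaling a family's reference counts leaves w (hence CAI) unchanged
  ref2 <- ref
  fam <- codon_table()$codon[codon_table()$amino_acid == "Ala"]
  ref2[fam] <- ref2[fam] * 7
  expect_equal(cai(counts, cai_weights(ref2))$cai, cai(counts, w)$cai)
})

test_that("planted preferred codons are the argmax of reference weights", {
  sim <- generate_dataset(sim_config(n_genes = 25, max_aa = 200,
                                     expression_coupling = 0,
                                     bias_strength = 3, seed = 31))
  counts <- count_codons(sim$cds)
  w <- suppressWarnings(cai_weights(counts))
  top <- vapply(split(w, w$amino_acid),
                function(f) f$codon[which.max(f$w)], character(1))
  planted <- stats::setNames(sim$preferred$codon, sim$preferred$amino_acid)
  agree <- mean(top[names(planted)] == planted)
  expect_gt(agree, 0.85)
})
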