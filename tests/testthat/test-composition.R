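test_that("positional GC matches hand counts on small genes", {
  # non-stop codons: ATG GCG CGC; positions 1: A,G,C  2: T,C,G  3: G,G,C
  comp <- codon_composition(tibble::tibble(id = "g", sequence = "ATGGCGCGCTGA"))
  expect_equal(comp$gc1, 2 / 3)
  expect_equal(comp$gc2, 2 / 3)
  expect_equal(comp$gc3, 1)
  expect_equal(comp$gc_all, (comp$gc1 + comp$gc2 + comp$gc3) / 3)
  expect_equal(comp$gc_all, 7 / 9)  # direct character count over ATGGCGCGC

  # body ATG TTT: thirds {G, T}, six coding bases with one G
  comp2 <- codon_composition(tibble::tibble(id = "g", sequence = "ATGTTTTGA"))
  expect_equal(comp2$gc3, 1 / 2)
  expect_equal(comp2$frac_g, 1 / 6)
})

test_that("GC3s uses only synonymous codons and flags empty denominators", {
  # no synonymous codon at all: body is Met/Trp only
  none <- codon_composition(tibble::tibble(id = "g", sequence = "ATGATGTGGTGA"))
  expect_true(is.na(none$gc3s))

  # Phe pair TTT/TTC -> one T-ending, one C-ending
  phe <- codon_composition(tibble::tibble(id = "g", sequence = "ATGTTTTTCTGA"))
  expect_equal(phe$gc3s, 1 / 2)
})

test_that("composition equals brute-force character counts on random genes", {
  seqs <- random_cds_set(n = 40, n_body = 110, seed = 21)
  comp <- codon_composition(seqs)
  for (i in seq_len(nrow(seqs))) {
    expect_equal(comp$gc_all[i], oracle_gc(seqs$sequence[i]))
  }
  expect_true(all(abs(comp$frac_a + comp$frac_t + comp$frac_g + comp$frac_c - 1)
                  < 1e-9))
  expect_true(all(abs(comp$gc_all - (comp$gc1 + comp$gc2 + comp$gc3) / 3)
                  < 1e-9))

  # GC3s against a direct enumeration over the synonymous-codon subset
  syn <- SENSE[!SENSE %in% c("ATG", "TGG")]
  for (i in 1:5) {
    codons <- split_codons(seqs$sequence[i])
    codons <- codons[-length(codons)]
    in_syn <- codons[codons %in% syn]
    expect_equal(comp$gc3s[i],
                 mean(substr(in_syn, 3, 3) %in% c("G", "C")))
  }
})

test_that("third-position counts respect the codon scope", {
  # one Val codon per third base; Val is fourfold so both scopes agree
  cds <- tibble::tibble(id = "g", sequence = "ATGGTTGTAGTCGTGTGA")
  ff <- third_position_counts(count_codons(cds), "fourfold_only")
  expect_equal(unlist(ff[, c("a3", "u3", "g3", "c3")], use.names = FALSE),
               c(1, 1, 1, 1))
  syn <- third_position_counts(count_codons(cds), "all_synonymous")
  expect_equal(ff[, c("a3", "u3", "g3", "c3")], syn[, c("a3", "u3", "g3", "c3")])

  # random genes: both scopes match a brute-force tally
  seqs <- random_cds_set(n = 10, n_body = 140, seed = 8)
  counts <- count_codons(seqs)
  quartets <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
  for (scope in c("fourfold_only", "all_synonymous")) {
    got <- third_position_counts(counts, scope)
    for (i in seq_len(nrow(seqs))) {
      codons <- split_codons(seqs$sequence[i])
      codons <- codons[-length(codons)]
      keep <- if (scope == "fourfold_only") {
        substr(codons, 1, 2) %in% quartets
      } else {
        codons %in% SENSE & !codons %in% c("ATG", "TGG")
      }
      third <- substr(codons[keep], 3, 3)
      expect_equal(unlist(got[i, c("a3", "u3", "g3", "c3")], use.names = FALSE),
                   as.numeric(c(sum(third == "A"), sum(third == "T"),
                                sum(third == "G"), sum(third == "C"))))
    }
    # counts in scope sum to the number of codons in scope
  }
})

test_that("complementing every base leaves GC metrics invariant", {
  seqs <- random_cds_set(n = 6, n_body = 120, seed = 33)
  comp <- codon_composition(seqs)
  # complement the body (A<->T, G<->C preserves GC-ness per position) and
  # re-append a stop so both versions exclude the same terminal codon
  body <- substr(seqs$sequence, 1, nchar(seqs$sequence) - 3)
  flipped <- tibble::tibble(
    id = seqs$id,
    sequence = paste0(chartr("ATGC", "TACG", body), "TAA")
  )
  fcomp <- codon_composition(flipped)
  expect_equal(fcomp$gc_all, comp$gc_all)
  expect_equal(fcomp$gc1, comp$gc1)
  expect_equal(fcomp$gc2, comp$gc2)
  expect_equal(fcomp$gc3, comp$gc3)
})

test_that("GC histogram bins cover every gene once", {
  seqs <- random_cds_set(n = 25, n_body = 110, seed = 5)
  comp <- codon_composition(seqs)
  h <- gc_histogram(comp)
  expect_equal(sum(h$n), nrow(comp))
  expect_true(all(diff(h$bin_low) == 2.5))
})
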