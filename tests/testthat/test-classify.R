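ab15 <- aa_alphabet("reduced15")
ab20 <- aa_alphabet("full20")

# 4 classes x 2 sequences; columns written per class for readability
aln4 <- function(A, B, C, D, subtypes = NULL) {
  make_msa(A = A, B = B, C = C, D = D, subtypes = subtypes)
}

test_that("column verdicts follow the invariant / eta / delta definitions", {
  aln <- aln4(
    #      1:invariant  2:distinctive-C,eta-within-C  3:distinctive-C
    #      4:two-deviators  5:gap-breaks-invariance  6:gap-in-eta-class
    #      7:gap-in-distinct-class-only
    A = c("GWKK--N", "GWKKAGN"),
    B = c("GWKKAGN", "GWKKAGN"),
    C = c("GAQQANQ", "GWQQAN-"),
    D = c("GWKWAGN", "GWKKAGN"))
  sites <- classify_sites(aln, ab15)

  expect_equal(sites$category,
               c("invariant", "distinctive", "distinctive", "other",
                 "other", "other", "distinctive"))
  # col 2: C deviates (A vs eta W); eta also occurs inside C (row C2)
  expect_equal(sites$distinct_class[2], "C")
  expect_equal(sites$eta_symbol[2], "W")
  expect_equal(sites$delta[[2]]$symbol, "A")
  expect_equal(sites$delta[[2]]$carriers[[1]], "C1")
  # col 3: K vs Q, distinct class C, both C rows carry delta
  expect_equal(sites$distinct_class[3], "C")
  expect_equal(sites$variation_category[3], "conserved_delta")
  # col 4: both C and D deviate from K -> other (d-site logic may rescue later)
  # col 5: gap in a would-be invariant column kills the call
  # col 6: gap sits in a non-distinct class (A) -> eta-conservation disqualified
  # col 7: gap inside the distinct class C is ignored; C1's Q still flags it
  expect_equal(sites$distinct_class[7], "C")

  # signature indices are consecutive per class in column order
  idx <- sites$signature_index[sites$category == "distinctive" &
                                 sites$distinct_class == "C"]
  expect_equal(idx, seq_along(idx))
})

test_that("classification agrees with the six-pair zero/nonzero MI pattern", {
  set.seed(3)
  for (seed in 1:10) {
    gen <- generate_alignment(small_spec(seed))
    scan <- pairwise_scan(gen$aln, ab15)
    sites <- classify_sites(gen$aln, ab15, scan)
    zero_by_col <- split(scan$is_zero, scan$column)
    involving <- function(cl) {
      s1 <- scan[scan$column == 1, ]
      s1$class_a == cl | s1$class_b == cl
    }
    for (j in sites$column) {
      z <- zero_by_col[[as.character(j)]]
      if (sites$category[j] == "invariant") {
        expect_true(all(z), info = paste("col", j, "seed", seed))
      } else if (sites$category[j] == "distinctive") {
        inv <- involving(sites$distinct_class[j])
        expect_true(all(z[!inv]) && all(!z[inv]),
                    info = paste("col", j, "seed", seed))
      }
    }
  }
})

test_that("subtype variation categories split as defined", {
  subtypes <- list(C = c("C_st1", "C_st1", "C_st2", "C_st2"))
  base <- list(A = c("GGG", "GGG"), B = c("GGG", "GGG"), D = c("GGG", "GGG"))
  # col1 conserved delta; col2 single subtype; col3 two subtypes, two deltas
  aln <- make_msa(A = base$A, B = base$B, D = base$D,
                  C = c("WGW", "WGN", "WNQ", "WNQ"),
                  subtypes = subtypes)
  sites <- classify_sites(aln, ab15)
  expect_equal(sites$category, rep("distinctive", 3))
  expect_equal(sites$variation_category,
               c("conserved_delta", "single_subtype", "subtype_variable"))
  expect_error(variation_category(sites[0, ], aln, ab15), "distinctive")
  other <- sites[1, ]; other$category <- "other"
  expect_error(variation_category(other, aln, ab15), "distinctive")
})

test_that("merged letters are one value: K/R and I/L columns stay invariant", {
  aln <- aln4(A = c("KI", "RI"), B = c("KL", "RL"),
              C = c("KI", "KI"), D = c("RL", "RL"))
  sites <- classify_sites(aln, ab15)
  expect_equal(sites$category, c("invariant", "invariant"))
  # under the full alphabet the same columns are not invariant
  sites20 <- classify_sites(aln, ab20)
  expect_true(all(sites20$category != "invariant"))
})

test_that("full20-distinctive columns whose groups stay distinct under
           reduced15 remain distinctive under reduced15", {
  set.seed(19)
  for (rep in 1:15) {
    gen <- generate_alignment(small_spec(rep + 100))
    s20 <- classify_sites(gen$aln, ab20)
    s15 <- classify_sites(gen$aln, ab15)
    d20 <- s20[s20$category == "distinctive", ]
    for (k in seq_len(nrow(d20))) {
      eta20 <- d20$eta_symbol[k]
      deltas20 <- d20$delta[[k]]$symbol
      g <- unique(ab15$map[c(eta20, deltas20)])
      if (length(g) == length(c(eta20, deltas20))) {
        cat15 <- s15$category[s15$column == d20$column[k]]
        expect_equal(cat15, "distinctive",
                     info = paste("column", d20$column[k], "rep", rep))
      }
    }
  }
})

test_that("planted synthetic alignments are recovered perfectly (spot seeds)", {
  for (seed in c(7, 23)) {
    gen <- generate_alignment(small_spec(seed))
    sites <- classify_sites(gen$aln, ab15)
    expect_equal(sites$category, truth_seq_category(gen$truth))
    d <- sites$category == "distinctive"
    expect_equal(sites$distinct_class[d], gen$truth$distinct_class[d])
    expect_equal(sites$eta_symbol[d], gen$truth$eta_symbol[d])
    expect_equal(sites$delta_symbols[d], gen$truth$delta_symbols[d])
    expect_equal(sites$variation_category[d], gen$truth$variation_category[d])
  }
})

test_that("site summaries reconcile with the table they summarize", {
  gen <- generate_alignment(small_spec(5))
  sites <- classify_sites(gen$aln, ab15)
  s <- summarize_sites(sites)
  expect_equal(Reduce(`+`, s$counts), nrow(sites))
  expect_equal(Reduce(`+`, s$distinctive_by_class),
               s$counts$distinctive)
  expect_equal(Reduce(`+`, s$variation_split), s$counts$distinctive)
})
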