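ab15 <- aa_alphabet("reduced15")

# shared fixture: planted alignment + toy structure with known contacts
fixture_structure <- function(seed = 7, d_dist = 4.2) {
  gen <- generate_alignment(small_spec(seed))
  sites <- classify_sites(gen$aln, ab15)
  truth <- gen$truth
  dc <- truth$column[truth$category == "d_candidate"]
  anchor_of <- vapply(dc, function(cc) {
    D <- truth$distinct_class[truth$column == cc]
    cand <- truth$column[truth$category == "distinctive" &
                           truth$distinct_class == D]
    cand[which.min(abs(cand - cc))]
  }, 0L)
  contacts <- tibble::tibble(column_a = anchor_of, column_b = dc,
                             distance = d_dist)
  row1 <- analysis_ids(gen$aln)[1]
  st <- generate_structure(gen$aln, row1, tempfile(fileext = ".pdb"),
                           contacts = contacts,
                           interface = tibble::tibble(column = 1:4,
                                                      distance = c(3.5, 3.9,
                                                                   3.2, 2.8)),
                           n_partner = 6, seed = seed)
  model <- read_structure(st$path)
  map <- map_columns_to_structure(gen$aln, row1, model, "A")
  list(gen = gen, sites = sites, truth = truth, st = st, model = model,
       map = map, contacts = contacts, row1 = row1)
}

test_that("minimum residue distance: identity, 3-4-5, planted value, oracle", {
  fx <- fixture_structure()
  keys <- unique(fx$model$atoms$res_key)
  expect_equal(min_residue_distance(fx$model, keys[1], keys[1]), 0)

  # hand-built two-atom structure at (0,0,0) and (3,4,0)
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.000   4.000   0.000  1.00  0.00           C",
    "END"), tf)
  toy <- read_structure(tf)
  expect_equal(min_residue_distance(toy, "A|1|", "A|2|"), 5.0)

  # planted contacts are realized exactly and match the exhaustive oracle
  res_of <- stats::setNames(fx$st$residues$resno, fx$st$residues$column)
  for (k in seq_len(nrow(fx$contacts))) {
    ka <- paste0("A|", res_of[[as.character(fx$contacts$column_a[k])]], "|")
    kb <- paste0("A|", res_of[[as.character(fx$contacts$column_b[k])]], "|")
    d <- min_residue_distance(fx$model, ka, kb)
    expect_equal(d, fx$contacts$distance[k], tolerance = 1e-9)
    expect_equal(d, min_dist_brute(fx$model, ka, kb), tolerance = 1e-12)
  }
  # symmetry, on a handful of random pairs
  set.seed(1)
  for (r in 1:10) {
    p <- sample(keys, 2)
    expect_equal(min_residue_distance(fx$model, p[1], p[2]),
                 min_residue_distance(fx$model, p[2], p[1]))
  }
  expect_error(min_residue_distance(fx$model, "A|9999|", keys[1]),
               "no coordinates")
})

test_that("neighbor queries equal the exhaustive all-pairs oracle", {
  fx <- fixture_structure()
  keys <- unique(fx$model$atoms$res_key[fx$model$atoms$chain == "A"])
  set.seed(2)
  probe <- sample(keys, min(12, length(keys)))
  for (ka in probe[1:4]) {
    fast <- vapply(probe, function(kb) min_residue_distance(fx$model, ka, kb), 0)
    brute <- vapply(probe, function(kb) min_dist_brute(fx$model, ka, kb), 0)
    expect_equal(fast, brute, tolerance = 1e-12)
  }
})

test_that("structure reading drops hydrogens, handles altloc and insert codes", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  H   ALA A   1       0.500   0.000   0.000  1.00  0.00           H",
    "ATOM      3  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      4  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      5  CA  GLY A   2A      3.000   0.000   0.000  1.00  0.00           C",
    "HETATM    6  O   HOH A 100      50.000   0.000   0.000  1.00  0.00           O",
    "END"), tf)
  m <- read_structure(tf)
  expect_false(any(grepl("^H", m$atoms$elety)))
  expect_false(any(m$atoms$resid == "HOH"))
  # highest-occupancy conformer kept (x = 9, occupancy 0.6)
  ca <- m$atoms[m$atoms$elety == "CA" & m$atoms$resno == 1, ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 9)
  # insertion code preserved in the residue key
  expect_true("A|2|A" %in% m$atoms$res_key)
})

test_that("column-structure mapping is exact on identical sequences and
           robust to missing termini", {
  fx <- fixture_structure()
  expect_equal(nrow(fx$map), fx$gen$aln$n_columns) # gap-free row, all mapped
  expect_equal(attr(fx$map, "mismatch_rate"), 0)
  expect_true(all(fx$map$match))

  # drop the first 10 residues from the structure: those columns unmap
  at <- fx$model$atoms
  trunc <- fx$model
  trunc$atoms <- at[!(at$chain == "A" & at$resno <= 10), ]
  map2 <- map_columns_to_structure(fx$gen$aln, fx$row1, trunc, "A")
  expect_false(any(fx$st$residues$column[1:10] %in% map2$column))
  expect_equal(nrow(map2), nrow(fx$map) - 10)

  # wrong chain (6-residue partner) cannot cover half the row
  expect_error(map_columns_to_structure(fx$gen$aln, fx$row1, fx$model, "B"),
               "wrong chain")
  expect_error(map_columns_to_structure(fx$gen$aln, fx$row1, fx$model, "Z"),
               "chain not in structure")
})

test_that("chimeric rows map with logged mismatches", {
  fx <- fixture_structure()
  aln <- fx$gen$aln
  # mutate 3 residues of the row to force strict-letter mismatches
  chim <- aln$aa
  row <- chim[fx$row1, ]
  pos <- which(row != "-")[c(5, 15, 25)]
  chim[fx$row1, pos] <- ifelse(row[pos] == "W", "G", "W")
  seqs <- stats::setNames(apply(chim, 1, paste, collapse = ""), rownames(chim))
  aln2 <- msa(seqs, aln$meta)
  expect_message(
    map3 <- map_columns_to_structure(aln2, fx$row1, fx$model, "A"),
    "mismatch")
  expect_equal(sum(!map3$match), 3)
})

test_that("d sites are found exactly at planted candidates and nowhere else", {
  fx <- fixture_structure()
  d <- find_d_sites(fx$gen$aln, fx$sites, fx$model, fx$map, ab15)
  planted <- fx$truth$column[fx$truth$category == "d_candidate"]
  expect_setequal(d$column, planted)
  expect_equal(d$min_distance, rep(4.2, nrow(d)), tolerance = 1e-9)
  # eta and conserved/varying classes match the plant
  for (k in seq_len(nrow(d))) {
    tr <- fx$truth[fx$truth$column == d$column[k], ]
    expect_equal(d$eta_symbol[k], tr$eta_symbol)
    varying <- sort(strsplit(d$varying_classes[k], ",")[[1]])
    expect_setequal(varying, c(tr$distinct_class, tr$d_extra_class))
  }

  # shrinking the cutoff below the planted distance removes all d sites
  d2 <- find_d_sites(fx$gen$aln, fx$sites, fx$model, fx$map, ab15,
                     cutoff = 4.0)
  expect_equal(nrow(d2), 0)

  # monotonicity in cutoff: growing cutoff never loses d sites
  prev <- integer(0)
  for (cut in c(2, 4.5, 5, 8)) {
    dk <- find_d_sites(fx$gen$aln, fx$sites, fx$model, fx$map, ab15,
                       cutoff = cut)
    expect_true(all(prev %in% dk$column), info = paste("cutoff", cut))
    prev <- dk$column
  }

  # applying d sites never reassigns invariant or distinctive columns
  upd <- apply_d_sites(fx$sites, d)
  keep <- fx$sites$category %in% c("invariant", "distinctive")
  expect_equal(upd$category[keep], fx$sites$category[keep])
  expect_equal(sum(upd$category == "d"), nrow(d))

  # no mapped distinctive sites is a hard error
  no_dist <- fx$sites
  no_dist$category[no_dist$category == "distinctive"] <- "other"
  expect_error(find_d_sites(fx$gen$aln, no_dist, fx$model, fx$map, ab15),
               "no distinctive columns")
})

test_that("d-site results do not depend on residue enumeration order", {
  fx <- fixture_structure()
  d1 <- find_d_sites(fx$gen$aln, fx$sites, fx$model, fx$map, ab15)
  shuffled <- fx$map[sample(nrow(fx$map)), ]
  d2 <- find_d_sites(fx$gen$aln, fx$sites, fx$model, shuffled, ab15)
  expect_setequal(d1$column, d2$column)
})

test_that("interface composition counts, size and core fraction reconcile", {
  fx <- fixture_structure()
  rep <- interface_composition(fx$model, fx$map, "A", "B", fx$sites)
  # exactly the 4 planted interface residues, all strictly under 4 A
  expect_equal(rep$size, 4)
  expect_setequal(rep$residues$column, 1:4)
  expect_true(all(rep$residues$min_partner_distance < 4))
  expect_equal(Reduce(`+`, rep$counts), rep$size)
  core <- 100 * (rep$counts$invariant + rep$counts$distinctive) / rep$size
  expect_equal(rep$core_fraction_percent, core)
  expect_gte(rep$core_fraction_percent, 0)
  expect_lte(rep$core_fraction_percent, 100)
  # the categories match the site table at those columns
  expect_equal(rep$residues$category,
               fx$sites$category[match(rep$residues$column, fx$sites$column)])

  # interface monotonicity: shrinking the cutoff never adds residues
  r35 <- interface_composition(fx$model, fx$map, "A", "B", fx$sites,
                               cutoff = 3.4)
  expect_true(all(r35$residues$column %in% rep$residues$column))
  expect_lte(r35$size, rep$size)
  # planted 3.5 and 3.9 contacts drop out below their distances
  expect_false(any(c(1, 2) %in% r35$residues$column))

  # distant chains: empty interface
  r0 <- interface_composition(fx$model, fx$map, "A", "B", fx$sites,
                              cutoff = 1.0)
  expect_equal(r0$size, 0)

  expect_error(interface_composition(fx$model, fx$map, "A", character(0),
                                     fx$sites), "empty partner")
  expect_error(interface_composition(fx$model, fx$map, "A", "A", fx$sites),
               "receptor chain")
})

test_that("contact cutoffs are strict: a pair at exactly the cutoff is out", {
  # two chains, single-atom residues, exact 3-4-5 distance of 5.0
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY B   1       3.000   4.000   0.000  1.00  0.00           C",
    "END"), tf)
  toy <- read_structure(tf)
  aln <- make_msa(A = "A", B = "A", C = "A", D = "A")
  map <- tibble::tibble(column = 1L, res_key = "A|1|", resno = 1L,
                        insert = "", resid = "ALA", row_letter = "A",
                        struct_letter = "A", match = TRUE)
  sites <- classify_sites(aln, ab15)
  at5 <- interface_composition(toy, map, "A", "B", sites, cutoff = 5.0)
  expect_equal(at5$size, 0)
  above <- interface_composition(toy, map, "A", "B", sites, cutoff = 5.0 + 1e-9)
  expect_equal(above$size, 1)
})

test_that("focal-class interfaces demote other classes' distinctive sites", {
  fx <- fixture_structure()
  rep_all <- interface_composition(fx$model, fx$map, "A", "B", fx$sites)
  dist_cols <- rep_all$residues$column[rep_all$residues$category == "distinctive"]
  if (length(dist_cols) > 0) {
    cl <- fx$sites$distinct_class[fx$sites$column == dist_cols[1]]
    other_cl <- setdiff(unique(fx$gen$aln$meta$class), cl)[1]
    rep_f <- interface_composition(fx$model, fx$map, "A", "B", fx$sites,
                                   focal_class = other_cl)
    expect_lt(rep_f$counts$distinctive, rep_all$counts$distinctive + 1)
    expect_false(dist_cols[1] %in%
                   rep_f$residues$column[rep_f$residues$category == "distinctive"])
  } else {
    succeed("no distinctive column landed in this interface fixture")
  }
})
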