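#' Specify a synthetic classified alignment
#'
#' Builds the blueprint for a seeded random alignment with planted column
#' categories, so every downstream stage can be validated against recorded
#' ground truth. Defaults emulate the scale and composition of a curated
#' mammalian G-alpha analysis set: 4 classes, 14 subtypes, about 4 sequences
#' per subtype, and column-category proportions in line with a family where
#' roughly a quarter of columns are invariant and one in seven is
#' class-distinctive.
#'
#' Planting is combinatorial, matching exactly what the classifier assumes:
#' no substitution model or tree is simulated. Free columns draw letters
#' i.i.d. uniform over the 20 amino acids per sequence (maximally
#' adversarial for false invariance at small n) and are rejection-sampled to
#' be truly non-invariant, non-distinctive, so ground truth is exact at gap
#' rate 0.
#'
#' @param classes class labels (default 4 G-alpha-like families).
#' @param subtypes_per_class integer vector (recycled) of subtype counts.
#' @param seqs_per_subtype sequences per subtype: scalar or per-subtype
#'   vector.
#' @param n_columns total alignment columns.
#' @param n_invariant,n_distinctive,n_d_candidate planted counts; remaining
#'   columns are free. `n_distinctive` is spread over classes round-robin
#'   unless `distinctive_split` fixes the per-class counts.
#' @param distinctive_split optional named integer vector (names = classes)
#'   giving how many distinctive columns each class receives; must sum to
#'   `n_distinctive`.
#' @param gap_rate per-cell gap probability applied after planting (planted
#'   labels describe the gap-free column; gaps can only remove calls).
#' @param alphabet the [aa_alphabet] planting is performed on.
#' @param seed integer seed; fully determines the output.
#' @return List of class `alignment_spec`.
#' @export
alignment_spec <- function(classes = c("G12", "Gio", "Gq", "Gs"),
                           subtypes_per_class = c(2, 7, 3, 2),
                           seqs_per_subtype = 4,
                           n_columns = 80,
                           n_invariant = round(0.28 * n_columns),
                           n_distinctive = round(0.15 * n_columns),
                           n_d_candidate = round(0.04 * n_columns),
                           distinctive_split = NULL,
                           gap_rate = 0,
                           alphabet = aa_alphabet("reduced15"),
                           seed = 1L) {
  stopifnot(length(classes) >= 3, !anyDuplicated(classes))
  subtypes_per_class <- rep_len(subtypes_per_class, length(classes))
  ord <- order(classes)
  classes <- classes[ord]
  subtypes_per_class <- subtypes_per_class[ord]
  if (n_d_candidate > 0 && length(classes) < 4) {
    stop("d-candidate columns need at least 4 classes (2 conserved + 2 varying)")
  }
  n_subtypes <- sum(subtypes_per_class)
  seqs_per_subtype <- rep_len(seqs_per_subtype, n_subtypes)
  if (n_invariant + n_distinctive + n_d_candidate > n_columns) {
    stop("planted column counts exceed n_columns")
  }
  if (gap_rate < 0 || gap_rate >= 1) stop("gap_rate must be in [0, 1)")
  if (!is.null(distinctive_split)) {
    if (!setequal(names(distinctive_split), classes) ||
        sum(distinctive_split) != n_distinctive) {
      stop("distinctive_split must name every class and sum to n_distinctive")
    }
  }
  structure(
    list(classes = classes, subtypes_per_class = subtypes_per_class,
         seqs_per_subtype = seqs_per_subtype, n_columns = n_columns,
         n_invariant = n_invariant, n_distinctive = n_distinctive,
         n_d_candidate = n_d_candidate,
         distinctive_split = distinctive_split, gap_rate = gap_rate,
         alphabet = alphabet, seed = as.integer(seed)),
    class = "alignment_spec"
  )
}

#' Generate a synthetic alignment with recorded ground truth
#'
#' @param spec an [alignment_spec()], or an explicit per-column `plan` set on
#'   it (see Details in the package vignette).
#' @return List: `aln` (an [msa]), `truth` (tibble: column, category,
#'   distinct_class, eta_symbol, delta_symbols, variation_category,
#'   d_extra_class).
#' @export
generate_alignment <- function(spec) {
  stopifnot(inherits(spec, "alignment_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  classes <- spec$classes
  # metadata scaffold
  subtype_labels <- unlist(lapply(seq_along(classes), function(i) {
    paste0(classes[i], "_st", seq_len(spec$subtypes_per_class[i]))
  }))
  subtype_class <- rep(classes, spec$subtypes_per_class)
  meta <- tibble::tibble(
    id = character(0), species = character(0), class = character(0),
    subtype = character(0), analysis_set = logical(0))
  for (k in seq_along(subtype_labels)) {
    n <- spec$seqs_per_subtype[k]
    meta <- dplyr::bind_rows(meta, tibble::tibble(
      id = paste0(subtype_labels[k], "_sp", seq_len(n)),
      species = paste0("species", seq_len(n)),
      class = subtype_class[k], subtype = subtype_labels[k],
      analysis_set = TRUE))
  }
  fam <- meta$class
  subtype <- meta$subtype
  n_seq <- nrow(meta)

  # per-column plan
  cats <- c(rep("invariant", spec$n_invariant),
            rep("distinctive", spec$n_distinctive),
            rep("d_candidate", spec$n_d_candidate))
  cats <- c(cats, rep("free", spec$n_columns - length(cats)))
  cats <- sample(cats)
  dist_class <- if (!is.null(spec$distinctive_split)) {
    rep(names(spec$distinctive_split), spec$distinctive_split)
  } else {
    rep(classes, length.out = spec$n_distinctive)
  }
  dist_class <- sample(dist_class)
  vcats <- c("conserved_delta", "subtype_variable", "single_subtype")

  ab <- spec$alphabet
  symbols <- names(ab$groups)
  aa <- matrix(GAP, nrow = n_seq, ncol = spec$n_columns,
               dimnames = list(meta$id, NULL))
  truth <- tibble::tibble(
    column = seq_len(spec$n_columns), category = cats,
    distinct_class = NA_character_, eta_symbol = NA_character_,
    delta_symbols = NA_character_, variation_category = NA_character_,
    d_extra_class = NA_character_)

  di <- 0
  for (j in seq_len(spec$n_columns)) {
    if (cats[j] == "invariant") {
      sym <- sample(symbols, 1)
      aa[, j] <- sample_group_letters(ab, sym, n_seq)
      truth$eta_symbol[j] <- sym
    } else if (cats[j] == "distinctive") {
      di <- di + 1
      C <- dist_class[di]
      n_sub_C <- spec$subtypes_per_class[match(C, classes)]
      vc_ok <- if (n_sub_C >= 2) vcats else "conserved_delta"
      vc <- sample(vc_ok, 1)
      plant <- plant_distinctive(ab, symbols, fam, subtype, C, vc)
      aa[, j] <- plant$letters
      truth$distinct_class[j] <- C
      truth$eta_symbol[j] <- plant$eta
      truth$delta_symbols[j] <- paste(sort(plant$delta), collapse = ",")
      truth$variation_category[j] <- vc
    } else if (cats[j] == "d_candidate") {
      D <- sample(classes, 1)
      X <- sample(setdiff(classes, D), 1)
      plant <- plant_d_candidate(ab, symbols, fam, D, X)
      aa[, j] <- plant$letters
      truth$distinct_class[j] <- D
      truth$d_extra_class[j] <- X
      truth$eta_symbol[j] <- plant$eta
      truth$delta_symbols[j] <- paste(sort(plant$delta), collapse = ",")
    } else {
      aa[, j] <- plant_free(ab, fam, classes)
    }
  }

  if (spec$gap_rate > 0) {
    gaps <- matrix(stats::runif(length(aa)) < spec$gap_rate, nrow = n_seq)
    aa[gaps] <- GAP
  }

  seqs <- stats::setNames(apply(aa, 1, paste, collapse = ""), meta$id)
  list(aln = msa(seqs, meta), truth = truth)
}

# letters drawn uniformly from one symbol group
sample_group_letters <- function(ab, sym, n) {
  letters <- ab$groups[[sym]]
  sample(letters, n, replace = TRUE)
}

plant_distinctive <- function(ab, symbols, fam, subtype, C, vc) {
  eta <- sample(symbols, 1)
  in_c <- fam == C
  letters <- character(length(fam))
  letters[!in_c] <- sample_group_letters(ab, eta, sum(!in_c))
  pool <- setdiff(symbols, eta)
  if (vc == "conserved_delta") {
    delta <- sample(pool, 1)
    letters[in_c] <- sample_group_letters(ab, delta, sum(in_c))
  } else if (vc == "single_subtype") {
    st <- sample(unique(subtype[in_c]), 1)
    delta <- sample(pool, 1)
    carrier <- in_c & subtype == st
    letters[carrier] <- sample_group_letters(ab, delta, sum(carrier))
    letters[in_c & !carrier] <- sample_group_letters(ab, eta, sum(in_c & !carrier))
  } else { # subtype_variable: two subtypes carry two different distinct values
    sts <- sample(unique(subtype[in_c]), 2)
    delta <- sample(pool, 2)
    c1 <- in_c & subtype == sts[1]
    c2 <- in_c & subtype == sts[2]
    letters[c1] <- sample_group_letters(ab, delta[1], sum(c1))
    letters[c2] <- sample_group_letters(ab, delta[2], sum(c2))
    rest <- in_c & !c1 & !c2
    letters[rest] <- sample_group_letters(ab, eta, sum(rest))
    delta <- delta
  }
  list(letters = letters, eta = eta, delta = delta)
}

# conserved in the two classes outside {D, X}; one deviating sequence in each
# of D and X, so the column is "other" to the sequence-only classifier but a
# valid d-site candidate anchored on class D
plant_d_candidate <- function(ab, symbols, fam, D, X) {
  eta <- sample(symbols, 1)
  letters <- sample_group_letters(ab, eta, length(fam))
  pool <- setdiff(symbols, eta)
  dD <- sample(pool, 1)
  dX <- sample(pool, 1)
  iD <- sample(which(fam == D), 1)
  iX <- sample(which(fam == X), 1)
  letters[iD] <- sample(ab$groups[[dD]], 1)
  letters[iX] <- sample(ab$groups[[dX]], 1)
  list(letters = letters, eta = eta, delta = dD)
}

# i.i.d. uniform letters, rejection-sampled to classify as "other"
plant_free <- function(ab, fam, classes, max_tries = 1000) {
  for (t in seq_len(max_tries)) {
    letters <- sample(AA_LETTERS, length(fam), replace = TRUE)
    sym <- unname(ab$map[letters])
    v <- classify_column(sym, fam, classes, ab$gap_symbol)
    if (v$category == "other") return(letters)
  }
  stop("could not draw a free (non-invariant, non-distinctive) column; ",
       "alignment too small for uniform free columns")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Append a tracking-only ortholog series with staged acquisition
#'
#' Creates one tracking-only sequence per organism for the given class,
#' planting distinct (delta) values at each planted distinctive site from a
#' chosen acquisition rank onward — so first-appearance ranks and
#' delta-to-eta reversions are known ground truth for
#' [acquisition_summary()].
#'
#' @param gen a [generate_alignment()] result.
#' @param class_label class whose distinctive sites are tracked.
#' @param organisms tibble with `organism`, `rank` (1 = earliest-diverging).
#' @param acquisition tibble with `column`, `stage_rank` (first rank carrying
#'   delta) and optional `revert_rank` (rank from which the value reverts to
#'   eta); columns must be planted distinctive sites of `class_label`.
#'   Unlisted distinctive columns carry eta in all organisms.
#' @param seed integer seed.
#' @return List: `aln` (msa including the new tracking records), `orthologs`
#'   (tibble: id, organism, rank), `truth` (tibble: organism, rank, column,
#'   status).
#' @export
generate_ortholog_series <- function(gen, class_label, organisms, acquisition,
                                     seed = 1L) {
  truth <- gen$truth
  aln <- gen$aln
  sites <- truth[truth$category == "distinctive" &
                   truth$distinct_class == class_label, ]
  bad <- setdiff(acquisition$column, sites$column)
  if (length(bad) > 0) {
    stop("acquisition names non-distinctive columns: ", paste(bad, collapse = ", "))
  }
  if (!"revert_rank" %in% names(acquisition)) acquisition$revert_rank <- NA_integer_

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  ab <- aa_alphabet("reduced15")
  n_col <- aln$n_columns
  new_seqs <- character(0)
  status_rows <- list()
  for (k in seq_len(nrow(organisms))) {
    org <- organisms$organism[k]; rk <- organisms$rank[k]
    # background: copy a class row, then overwrite the tracked sites
    letters <- aln$aa[analysis_ids(aln, class_label)[1], ]
    for (s in seq_len(nrow(sites))) {
      col <- sites$column[s]
      acq <- acquisition[acquisition$column == col, ]
      has_delta <- nrow(acq) == 1 && rk >= acq$stage_rank &&
        (is.na(acq$revert_rank) || rk < acq$revert_rank)
      sym <- if (has_delta) strsplit(sites$delta_symbols[s], ",")[[1]][1]
             else sites$eta_symbol[s]
      letters[col] <- sample(ab$groups[[sym]], 1)
      status_rows[[length(status_rows) + 1]] <- tibble::tibble(
        organism = org, rank = rk, column = col,
        status = if (has_delta) "delta" else "eta")
    }
    new_seqs[paste0(class_label, "_", org)] <- paste(letters, collapse = "")
  }

  all_seqs <- c(stats::setNames(apply(aln$aa, 1, paste, collapse = ""),
                                aln$meta$id), new_seqs)
  new_meta <- dplyr::bind_rows(
    aln$meta,
    tibble::tibble(id = names(new_seqs), species = organisms$organism,
                   class = class_label,
                   subtype = paste0(class_label, "_tracking"),
                   analysis_set = FALSE))
  list(
    aln = msa(all_seqs, new_meta),
    orthologs = tibble::tibble(id = names(new_seqs),
                               organism = organisms$organism,
                               rank = organisms$rank),
    truth = dplyr::bind_rows(status_rows)
  )
}

#' Generate a toy structure realizing planted contacts
#'
#' Writes a standard PDB file whose chain A instantiates one residue per
#' non-gap position of a chosen alignment row (so the real structure reader
#' and column-mapping path are exercised end to end). Residues sit on a
#' widely spaced grid (no incidental contacts); each planted contact pair is
#' realized with an exact minimum heavy-atom distance by axis-aligned
#' placement. An optional partner chain B is placed far away except at
#' planted interface contacts.
#'
#' @param aln an [msa].
#' @param row_id alignment row giving residue identities.
#' @param path output PDB path.
#' @param contacts tibble with `column_a`, `column_b`, `distance`: residue of
#'   `column_b` is moved to exactly `distance` Angstrom (min heavy-atom) from
#'   the residue of `column_a`. A column may appear several times as
#'   `column_a` but at most once overall as `column_b`, and never as both.
#' @param interface tibble with `column`, `distance`: a partner-chain (B)
#'   residue is placed at exactly `distance` from the receptor residue of
#'   `column`.
#' @param n_partner number of partner-chain residues (>= planted interface
#'   contacts); the rest stay > 100 Angstrom away.
#' @param spacing Angstrom between consecutive residues (default 30; must
#'   exceed twice any planted distance).
#' @param seed integer seed for the sub-Angstrom jitter on non-planted
#'   residue positions.
#' @return List: `path`, `residues` (tibble: column, chain, resno),
#'   `planted` (the contact tables with realized distances).
#' @export
generate_structure <- function(aln, row_id, path,
                               contacts = NULL, interface = NULL,
                               n_partner = 0, spacing = 30, seed = 1L) {
  row <- aln$aa[row_id, ]
  cols <- which(row != GAP)
  n_res <- length(cols)
  if (n_res == 0) stop("row is all gaps")
  contacts <- contacts %||% tibble::tibble(column_a = integer(0),
                                           column_b = integer(0),
                                           distance = numeric(0))
  interface <- interface %||% tibble::tibble(column = integer(0),
                                             distance = numeric(0))
  check_contact_plan(contacts, interface, cols, spacing)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # chain A: base positions on an x/z grid (keeps coordinates inside the
  # fixed-width PDB field), mild rounded jitter in y
  grid_w <- 20L
  ix <- (seq_len(n_res) - 1L) %% grid_w
  iz <- (seq_len(n_res) - 1L) %/% grid_w
  base <- cbind(x = ix * spacing,
                y = round(stats::runif(n_res, -0.5, 0.5), 3),
                z = iz * spacing)
  if (max(base) + spacing > 9999) stop("structure too large for PDB fields")
  res_of_col <- stats::setNames(seq_len(n_res), cols)

  # residue b of a contact pair: first atom exactly `distance` along +y from
  # residue a's first atom; remaining atoms stacked further along +y, so the
  # pair's minimum heavy-atom distance is exactly the planted value
  moved <- rep(FALSE, n_res)
  for (k in seq_len(nrow(contacts))) {
    ia <- res_of_col[[as.character(contacts$column_a[k])]]
    ib <- res_of_col[[as.character(contacts$column_b[k])]]
    base[ib, ] <- base[ia, ] + c(0, contacts$distance[k], 0)
    moved[ib] <- TRUE
  }

  atoms_a <- residue_atoms(base, moved, axis = "y")

  # chain B: far plane at z = 1000 unless planted at an interface contact
  atoms_b <- NULL
  if (n_partner > 0) {
    if (nrow(interface) > n_partner) stop("more interface contacts than partner residues")
    base_b <- cbind(x = (seq_len(n_partner) - 1) * spacing, y = 0, z = 1000)
    moved_b <- rep(FALSE, n_partner)
    for (k in seq_len(nrow(interface))) {
      ia <- res_of_col[[as.character(interface$column[k])]]
      base_b[k, ] <- base[ia, ] + c(0, 0, interface$distance[k])
      moved_b[k] <- TRUE
    }
    atoms_b <- residue_atoms(base_b, moved_b, axis = "z")
  } else if (nrow(interface) > 0) {
    stop("interface contacts planted but n_partner is 0")
  }

  resid_a <- bio3d::aa123(row[cols])
  write_toy_pdb(path, atoms_a, atoms_b, resid_a)

  list(
    path = path,
    residues = tibble::tibble(column = cols, chain = "A",
                              resno = seq_len(n_res)),
    planted = list(contacts = contacts, interface = interface)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_contact_plan <- function(contacts, interface, cols, spacing) {
  allc <- c(contacts$column_a, contacts$column_b, interface$column)
  bad <- setdiff(allc, cols)
  if (length(bad) > 0) stop("contact plan names gapped/unknown columns: ",
                            paste(bad, collapse = ", "))
  d <- c(contacts$distance, interface$distance)
  if (any(d <= 0)) stop("planted distances must be positive")
  if (any(d >= spacing / 2)) {
    stop("planted distance >= spacing/2 would create incidental contacts")
  }
  if (anyDuplicated(contacts$column_b)) {
    stop("a column may be moved (column_b) at most once")
  }
  if (length(intersect(contacts$column_a, contacts$column_b)) > 0) {
    stop("a column cannot be both anchor (column_a) and moved (column_b)")
  }
  if (anyDuplicated(interface$column)) {
    stop("at most one planted interface contact per receptor column")
  }
}

# 3 heavy atoms per residue: first at the base position, the rest stacked
# 0.9 and 1.8 Angstrom along `axis` for moved residues (away from the contact
# partner) or along x for line residues
residue_atoms <- function(base, moved, axis) {
  n <- nrow(base)
  off <- matrix(0, 3, 3, dimnames = list(NULL, c("x", "y", "z")))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ax <- if (moved[i]) axis else "x"
    o <- off
    o[, ax] <- c(0, 0.9, 1.8)
    xyz <- sweep(o, 2, base[i, ], "+")
    out[[i]] <- cbind(resno = i, xyz)
  }
  do.call(rbind, out)
}

write_toy_pdb <- function(path, atoms_a, atoms_b, resid_a) {
  elety <- c("N", "CA", "CB")
  lines <- character(0)
  serial <- 0
  emit <- function(at, chain, resid_fun) {
    res <- character(nrow(at))
    for (i in seq_len(nrow(at))) {
      serial <<- serial + 1
      rn <- as.integer(at[i, "resno"])
      res[i] <- sprintf(
        "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
        serial, elety[((i - 1) %% 3) + 1], resid_fun(rn), chain, rn,
        at[i, "x"], at[i, "y"], at[i, "z"], 1.0, 0.0,
        substr(elety[((i - 1) %% 3) + 1], 1, 1))
    }
    res
  }
  lines <- c(lines, emit(atoms_a, "A", function(rn) resid_a[rn]))
  if (!is.null(atoms_b)) {
    lines <- c(lines, "TER",
               emit(atoms_b, "B", function(rn) "GLY"))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
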