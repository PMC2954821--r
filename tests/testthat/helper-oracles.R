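# Independent oracles and small fixture builders shared across tests.

# Brute-force mutual information (bits) between symbol value and a two-family
# label, written directly from the defining sum — independent of the package
# implementation.
mi_brute <- function(syms_a, syms_b) {
  syms <- union(syms_a, syms_b)
  n_a <- length(syms_a); n_b <- length(syms_b); n <- n_a + n_b
  total <- 0
  for (x in syms) {
    for (fam in 1:2) {
      cnt <- if (fam == 1) sum(syms_a == x) else sum(syms_b == x)
      if (cnt == 0) next
      p_xy <- cnt / n
      p_x <- (sum(syms_a == x) + sum(syms_b == x)) / n
      p_y <- if (fam == 1) n_a / n else n_b / n
      total <- total + p_xy * log2(p_xy / (p_x * p_y))
    }
  }
  total
}

# Exhaustive all-pairs minimum distance between two residues of a structure.
min_dist_brute <- function(structure, key_a, key_b) {
  at <- structure$atoms
  a <- at[at$res_key == key_a, c("x", "y", "z")]
  b <- at[at$res_key == key_b, c("x", "y", "z")]
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((as.numeric(a[i, ]) - as.numeric(b[j, ]))^2))
      best <- min(best, d)
    }
  }
  best
}

# Build a small msa from per-class sequence lists:
#   make_msa(A = c("AC-", "ACA"), B = "ACG")
# ids are <class><index>, subtypes default to one per class unless
# `subtypes` gives a parallel list of labels.
make_msa <- function(..., subtypes = NULL, tracking = NULL) {
  per_class <- list(...)
  seqs <- character(0); meta <- NULL
  for (cl in names(per_class)) {
    s <- per_class[[cl]]
    ids <- paste0(cl, seq_along(s))
    st <- if (!is.null(subtypes) && !is.null(subtypes[[cl]])) {
      rep_len(subtypes[[cl]], length(s))
    } else paste0(cl, "_st1")
    seqs[ids] <- s
    meta <- rbind(meta, data.frame(id = ids, species = "sp", class = cl,
                                   subtype = st, analysis_set = TRUE))
  }
  if (!is.null(tracking)) {
    for (cl in names(tracking)) {
      s <- tracking[[cl]]
      ids <- paste0(cl, "_trk", seq_along(s))
      seqs[ids] <- s
      meta <- rbind(meta, data.frame(id = ids, species = "sp", class = cl,
                                     subtype = paste0(cl, "_trk"),
                                     analysis_set = FALSE))
    }
  }
  msa(seqs, meta)
}

# Write an alignment + metadata into a temp dir; returns the two paths.
write_fixture_alignment <- function(aln, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fa <- file.path(dir, "aln.fasta")
  md <- file.path(dir, "meta.tsv")
  write_alignment(aln, fa, md)
  c(fasta = fa, metadata = md)
}

# Small study-like spec used by several tests; cheap but covers all planted
# categories and subtype structure.
small_spec <- function(seed, n_columns = 40, gap_rate = 0) {
  alignment_spec(
    classes = c("Gio", "Gq", "Gs", "G12"),
    subtypes_per_class = c(3, 2, 2, 2),
    seqs_per_subtype = 2,
    n_columns = n_columns,
    n_invariant = round(0.25 * n_columns),
    n_distinctive = 8,
    n_d_candidate = 2,
    gap_rate = gap_rate,
    seed = seed
  )
}

# Truth category as the sequence-only classifier must see it (d-candidates
# and free columns are "other" before structural rescue).
truth_seq_category <- function(truth) {
  ifelse(truth$category %in% c("d_candidate", "free"), "other", truth$category)
}
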