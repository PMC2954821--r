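#!/usr/bin/env Rscript
# Stage 1: build the study inputs. A seeded synthetic alignment at the scale
# of a curated mammalian G-alpha analysis set (58 sequences, 4 classes, 14
# subtypes, 380 columns; 106 invariant / 59 distinctive / 16 d-candidate
# planted columns), a staged ortholog series for signature tracking, and toy
# structures realizing the planted contacts and two effector-like interfaces.
suppressPackageStartupMessages({library(specsites); library(tibble)})

seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- alignment_spec(
  classes = c("Gio", "Gq", "Gs", "G12"),
  subtypes_per_class = c(7, 3, 2, 2),
  seqs_per_subtype = c(rep(4L, 12), 5L, 5L),
  n_columns = 380, n_invariant = 106, n_distinctive = 59,
  distinctive_split = c(Gio = 14, Gq = 10, Gs = 16, G12 = 19),
  n_d_candidate = 16, gap_rate = 0, seed = seed)
gen <- run_simulate(spec, out)
truth <- gen$truth
cat("alignment:", sum(gen$aln$meta$analysis_set), "analysis-set sequences x",
    gen$aln$n_columns, "columns ->", file.path(out, "alignment.fasta"), "\n")

# ortholog series for G(q) signature tracking: two early acquisitions (one
# later reverting), one mid-metazoan, one vertebrate-only
sites_gq <- truth$column[truth$category == "distinctive" &
                           truth$distinct_class == "Gq"]
organisms <- tibble(
  organism = c("marine_sponge", "freshwater_sponge", "worm", "fly",
               "sea_urchin", "frog", "human"),
  rank = 1:7)
acq_plan <- tibble(column = sites_gq[1:4], stage_rank = c(1L, 1L, 3L, 6L),
                   revert_rank = c(NA, 5L, NA, NA))
series <- generate_ortholog_series(gen, "Gq", organisms, acq_plan,
                                   seed = seed + 4L)
write_alignment(series$aln, file.path(out, "alignment_with_orthologs.fasta"),
                file.path(out, "metadata_with_orthologs.tsv"))
readr::write_tsv(series$orthologs, file.path(out, "lineage.tsv"))
readr::write_tsv(acq_plan, file.path(out, "acquisition_plan.tsv"))
cat("orthologs:", nrow(series$orthologs), "tracking sequences planted\n")

# toy active-state structure: every planted d-candidate at 4.2 A from its
# nearest same-class distinctive anchor
dc <- truth$column[truth$category == "d_candidate"]
anchor_of <- vapply(dc, function(cc) {
  D <- truth$distinct_class[truth$column == cc]
  cand <- truth$column[truth$category == "distinctive" &
                         truth$distinct_class == D]
  cand[which.min(abs(cand - cc))]
}, 0L)
row1 <- analysis_ids(gen$aln)[1]
st <- generate_structure(
  gen$aln, row1, file.path(out, "toy_active.pdb"),
  contacts = tibble(column_a = anchor_of, column_b = dc, distance = 4.2),
  seed = seed + 1L)
readr::write_tsv(tibble(column_a = anchor_of, column_b = dc, distance = 4.2),
                 file.path(out, "planted_contacts.tsv"))
cat("structure:", file.path(out, "toy_active.pdb"), "with", length(dc),
    "planted sub-5A contacts\n")

# two effector-like complexes: a small core-dominated interface and a large
# half-core interface (sizes 15 and 30; cores 12 and 15)
pick <- function(cat, n, class = NULL) {
  keep <- truth$category == cat
  if (!is.null(class)) {
    keep <- keep & !is.na(truth$distinct_class) & truth$distinct_class == class
  }
  sort(setdiff(truth$column[keep], dc))[seq_len(n)]
}
plans <- list(
  grk2_like = c(pick("invariant", 8), pick("distinctive", 4, "Gq"),
                pick("free", 3)),
  p63_like = c(pick("invariant", 10), pick("distinctive", 5, "Gq"),
               pick("free", 15)))
for (nm in names(plans)) {
  cols <- plans[[nm]]
  generate_structure(
    gen$aln, row1, file.path(out, paste0("toy_", nm, ".pdb")),
    interface = tibble(column = cols,
                       distance = rep_len(c(3.0, 3.4, 3.8), length(cols))),
    n_partner = length(cols) + 2, seed = seed + match(nm, names(plans)) + 1L)
  readr::write_tsv(tibble(column = cols),
                   file.path(out, paste0("interface_plan_", nm, ".tsv")))
  cat("complex:", nm, "-", length(cols), "planted interface residues\n")
}
cat("row mapped onto chain A:", row1, "\n")
writeLines(row1, file.path(out, "structure_row.txt"))
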