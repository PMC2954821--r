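#' Run the column classification stage and write its reports
#'
#' Computes the six pairwise mutual-information scores per column, classifies
#' every column, and writes the stage outputs into `out_dir`: the site table
#' (`sites.tsv`), the per-pair MI table (`mi_pairs.tsv`), an annotated
#' alignment text (`annotated_alignment.txt`, one-letter category codes above
#' each alignment block) and a machine-readable summary (`summary.json`).
#'
#' @param aln an [msa].
#' @param out_dir output directory (created if needed).
#' @param alphabet an [aa_alphabet].
#' @param reference_id optional reference row for residue-number labels.
#' @param n_classes forwarded to [pairwise_scan()].
#' @return The site table, invisibly; files are the product.
#' @export
run_classify <- function(aln, out_dir, alphabet = aa_alphabet("reduced15"),
                         reference_id = NULL, n_classes = 4) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scan <- pairwise_scan(aln, alphabet, n_classes)
  sites <- classify_sites(aln, alphabet, scan, n_classes)

  readr::write_tsv(scan, file.path(out_dir, "mi_pairs.tsv"), progress = FALSE)
  readr::write_tsv(site_table_tsv(sites, aln, reference_id),
                   file.path(out_dir, "sites.tsv"), progress = FALSE)
  writeLines(annotate_alignment(aln, sites),
             file.path(out_dir, "annotated_alignment.txt"))

  summ <- summarize_sites(sites)
  summ$alphabet <- alphabet$name
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(sites)
}

# flatten list columns for the TSV rendering of a site table
site_table_tsv <- function(sites, aln, reference_id = NULL) {
  out <- sites
  out$delta_values <- vapply(sites$delta, function(d) {
    if (nrow(d) == 0) return(NA_character_)
    paste(sprintf("%s:%s:%s", d$symbol, d$letters,
                  vapply(d$carriers, paste, "", collapse = "|")),
          collapse = ";")
  }, "")
  out$delta <- NULL
  if (!is.null(reference_id)) {
    refmap <- column_to_reference(aln, reference_id)
    out <- dplyr::mutate(out,
      ref_residue = ref_label(refmap, aln, out$column), .after = "column")
  }
  out
}

# Fig-3-style text rendering: category code line above each alignment block
annotate_alignment <- function(aln, sites, width = 60) {
  code <- c(invariant = "*", distinctive = NA, d = "d", other = ".")
  percol <- ifelse(sites$category == "distinctive",
                   substr(sites$distinct_class, 1, 1),
                   code[sites$category])
  ids <- aln$meta$id
  idw <- max(nchar(ids)) + 2
  lines <- character(0)
  for (start in seq(1, aln$n_columns, by = width)) {
    end <- min(start + width - 1, aln$n_columns)
    lines <- c(lines,
               paste0(formatC("", width = idw),
                      paste(percol[start:end], collapse = "")))
    for (id in ids) {
      lines <- c(lines,
                 paste0(formatC(id, width = -idw),
                        paste(aln$aa[id, start:end], collapse = "")))
    }
    lines <- c(lines, "")
  }
  lines
}

#' Run the structural d-site stage and write its reports
#'
#' @param aln an [msa].
#' @param sites a [classify_sites()] table.
#' @param structure a `structure_model` (see [read_structure()]).
#' @param row_id alignment row mapped onto `chain`.
#' @param chain receptor chain id.
#' @param out_dir output directory.
#' @param alphabet the [aa_alphabet] used for `sites`.
#' @param cutoff neighbor cutoff in Angstrom (default 5.0, strict `<`).
#' @return List with `d_sites` and the updated `sites`, invisibly.
#' @export
run_dsites <- function(aln, sites, structure, row_id, chain, out_dir,
                       alphabet = aa_alphabet("reduced15"), cutoff = 5.0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  map <- map_columns_to_structure(aln, row_id, structure, chain)
  d <- find_d_sites(aln, sites, structure, map, alphabet, cutoff)
  updated <- apply_d_sites(sites, d)

  dtsv <- d
  dtsv$anchor_columns <- vapply(d$anchor_columns, paste, "", collapse = ",")
  dtsv$carriers <- vapply(d$carriers, paste, "", collapse = ",")
  readr::write_tsv(dtsv, file.path(out_dir, "d_sites.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(structure = structure$id, chain = chain, cutoff = cutoff,
         n_d_sites = nrow(d), columns = d$column),
    file.path(out_dir, "d_sites_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(d_sites = d, sites = updated))
}

#' Run the interface-composition stage and write its reports
#'
#' @inheritParams run_dsites
#' @param partner_chains partner chain ids.
#' @param cutoff interface cutoff in Angstrom (default 4.0, strict `<`).
#' @param focal_class forwarded to [interface_composition()].
#' @return The `interface_report`, invisibly.
#' @export
run_interface <- function(aln, sites, structure, row_id, chain,
                          partner_chains, out_dir,
                          cutoff = 4.0, focal_class = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  map <- map_columns_to_structure(aln, row_id, structure, chain)
  rep <- interface_composition(structure, map, chain, partner_chains,
                               sites, cutoff, focal_class)
  readr::write_tsv(rep$residues, file.path(out_dir, "interface_residues.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    rep[c("structure_id", "receptor_chain", "partner_chains", "cutoff",
          "size", "counts", "core_fraction_percent")],
    file.path(out_dir, "interface_summary.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(rep)
}

#' Run the signature stage and write its reports
#'
#' @param aln an [msa].
#' @param sites a site table.
#' @param class_label class whose signature to extract.
#' @param out_dir output directory.
#' @param ids sequences to tabulate (default all).
#' @param alphabet the [aa_alphabet] used for `sites`.
#' @param lineage optional lineage tibble (`id`, `organism`, `rank`)
#'   triggering the acquisition summary.
#' @return List with `signature` and (optionally) `acquisition`, invisibly.
#' @export
run_signatures <- function(aln, sites, class_label, out_dir, ids = NULL,
                           alphabet = aa_alphabet("reduced15"),
                           lineage = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sig <- extract_signature(aln, sites, class_label, ids, alphabet)
  wide <- tidyr::pivot_wider(
    sig$table, id_cols = "id",
    names_from = "signature_index", values_from = "residue",
    names_prefix = "site_")
  wide$signature <- signature_strings(sig)[wide$id]
  readr::write_tsv(wide, file.path(out_dir,
                                   paste0("signature_", class_label, ".tsv")),
                   progress = FALSE)
  status_codes <- c(delta = "D", eta = "H", other = "O", missing = "M")
  codes <- tidyr::pivot_wider(
    dplyr::mutate(sig$table, code = status_codes[.data$status]),
    id_cols = "id", names_from = "signature_index", values_from = "code",
    names_prefix = "site_")
  readr::write_tsv(codes, file.path(out_dir,
                                    paste0("signature_", class_label,
                                           "_status.tsv")),
                   progress = FALSE)
  out <- list(signature = sig)
  if (!is.null(lineage)) {
    acq <- acquisition_summary(sig, lineage)
    readr::write_tsv(acq$per_organism,
                     file.path(out_dir, paste0("acquisition_", class_label,
                                               "_organisms.tsv")),
                     progress = FALSE)
    readr::write_tsv(acq$per_site,
                     file.path(out_dir, paste0("acquisition_", class_label,
                                               "_sites.tsv")),
                     progress = FALSE)
    out$acquisition <- acq
  }
  invisible(out)
}

#' Run the synthetic-data stage and write its outputs
#'
#' @param spec an [alignment_spec()].
#' @param out_dir output directory; receives `alignment.fasta`,
#'   `metadata.tsv`, `truth.tsv`.
#' @return The [generate_alignment()] result, invisibly.
#' @export
run_simulate <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_alignment(spec)
  write_alignment(gen$aln, file.path(out_dir, "alignment.fasta"),
                  file.path(out_dir, "metadata.tsv"))
  readr::write_tsv(gen$truth, file.path(out_dir, "truth.tsv"),
                   progress = FALSE)
  invisible(gen)
}
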