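#' Read a classified multiple sequence alignment
#'
#' Loads an aligned FASTA together with a sidecar metadata TSV that assigns
#' every sequence a species, a class (family), a subtype and an analysis-set
#' flag. Class and subtype assignments are curation and are therefore never
#' inferred from FASTA headers. Records whose class is outside
#' `analysis_filter` are retained but flagged tracking-only, so they take no
#' part in column statistics yet can still be threaded through signature
#' tables.
#'
#' @param fasta_path aligned FASTA; gap character `-`.
#' @param metadata_path TSV with header
#'   `id  species  class  subtype  analysis_set` (analysis_set is
#'   TRUE/FALSE). Every FASTA id must be present.
#' @param analysis_filter optional character vector of class labels; records
#'   with other classes are demoted to tracking-only. `NULL` keeps the
#'   metadata's own `analysis_set` flags.
#' @param mask_ambiguous if TRUE, ambiguous residue letters (B, Z, X, U, O,
#'   J) are converted to gaps instead of raising an error.
#' @return An object of class `msa`: a list with `aa` (character matrix,
#'   rows = sequence ids, columns = alignment columns), `meta` (tibble of
#'   per-record metadata) and `n_columns`.
#' @export
read_alignment <- function(fasta_path, metadata_path, analysis_filter = NULL,
                           mask_ambiguous = FALSE) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  meta <- readr::read_tsv(metadata_path,
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  need <- c("id", "species", "class", "subtype", "analysis_set")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  meta$analysis_set <- toupper(meta$analysis_set) %in% c("TRUE", "T", "1", "YES")
  new_msa(stats::setNames(as.character(seqs), ids),
          meta[need], analysis_filter, mask_ambiguous)
}

#' Build an alignment from in-memory sequences
#'
#' Programmatic constructor used by the synthetic generator and by tests;
#' applies exactly the same validation as [read_alignment()].
#'
#' @param sequences named character vector of aligned sequences.
#' @param meta tibble/data.frame with columns id, species, class, subtype,
#'   analysis_set (logical).
#' @inheritParams read_alignment
#' @return An `msa`.
#' @export
msa <- function(sequences, meta, analysis_filter = NULL,
                mask_ambiguous = FALSE) {
  new_msa(sequences, meta, analysis_filter, mask_ambiguous)
}

AMBIGUOUS <- c("B", "Z", "X", "U", "O", "J")

new_msa <- function(sequences, meta, analysis_filter, mask_ambiguous) {
  ids <- names(sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) stop("sequences must be named by id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) stop("duplicate sequence ids: ", paste(dup, collapse = ", "))

  meta <- tibble::as_tibble(meta)
  if (!is.logical(meta$analysis_set)) meta$analysis_set <- as.logical(meta$analysis_set)
  missing_meta <- setdiff(ids, meta$id)
  if (length(missing_meta) > 0) {
    stop("ids absent from metadata: ", paste(missing_meta, collapse = ", "))
  }
  meta <- meta[match(ids, meta$id), ]

  lens <- nchar(sequences)
  n_columns <- lens[[1]]
  if (any(lens != n_columns)) {
    bad <- ids[lens != n_columns]
    stop("aligned length mismatch for: ", paste(bad, collapse = ", "))
  }
  if (n_columns < 1) stop("alignment has zero columns")

  aa <- matrix(unlist(strsplit(toupper(sequences), "", fixed = TRUE), use.names = FALSE),
               nrow = length(ids), byrow = TRUE,
               dimnames = list(ids, NULL))
  amb <- aa %in% AMBIGUOUS
  if (any(amb)) {
    if (mask_ambiguous) {
      aa[amb] <- GAP
    } else {
      stop("ambiguous residue letters (", paste(unique(aa[amb]), collapse = ","),
           ") present; use mask_ambiguous = TRUE to convert them to gaps")
    }
  }
  bad <- !(aa %in% c(AA_LETTERS, GAP))
  if (any(bad)) {
    stop("invalid residue letters: ", paste(unique(aa[bad]), collapse = ", "))
  }

  if (!is.null(analysis_filter)) {
    unknown <- setdiff(analysis_filter, meta$class)
    if (length(unknown) > 0) {
      stop("analysis_filter names unknown classes: ", paste(unknown, collapse = ", "))
    }
    meta$analysis_set <- meta$analysis_set & meta$class %in% analysis_filter
  }
  if (length(unique(meta$class[meta$analysis_set])) < 2) {
    stop("analysis set must span at least 2 classes")
  }

  structure(list(aa = aa, meta = meta, n_columns = n_columns), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa> ", nrow(x$aa), " sequences x ", x$n_columns, " columns; ",
      sum(x$meta$analysis_set), " in analysis set (classes: ",
      paste(sort(unique(x$meta$class[x$meta$analysis_set])), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Ids of analysis-set records, optionally per class
#' @param aln an `msa`.
#' @param class_label optional class to restrict to.
#' @return Character vector of ids in alignment order.
#' @export
analysis_ids <- function(aln, class_label = NULL) {
  keep <- aln$meta$analysis_set
  if (!is.null(class_label)) keep <- keep & aln$meta$class == class_label
  aln$meta$id[keep]
}

#' Write an alignment and its metadata back to disk
#'
#' @param aln an `msa`.
#' @param fasta_path output FASTA path.
#' @param metadata_path optional output TSV path.
#' @return `fasta_path`, invisibly.
#' @export
write_alignment <- function(aln, fasta_path, metadata_path = NULL) {
  seqs <- Biostrings::AAStringSet(apply(aln$aa, 1, paste, collapse = ""))
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(metadata_path)) {
    meta <- aln$meta
    meta$analysis_set <- ifelse(meta$analysis_set, "TRUE", "FALSE")
    readr::write_tsv(meta, metadata_path, progress = FALSE)
  }
  invisible(fasta_path)
}

#' Map alignment columns to residue numbers of a reference sequence
#'
#' Residue numbers are 1-based ungapped positions within the named reference
#' row, so sites can be reported in the field's usual "residue 260" style.
#' Columns where the reference carries a gap are absent from the mapping.
#'
#' @param aln an `msa`.
#' @param reference_id id of the reference row.
#' @return A list of class `column_ref_map` with `reference_id`,
#'   `col_to_res` (named integer vector: names are columns) and `res_to_col`
#'   (named integer vector: names are residue numbers).
#' @export
column_to_reference <- function(aln, reference_id) {
  if (!reference_id %in% aln$meta$id) {
    stop("reference id not in alignment: ", reference_id)
  }
  row <- aln$aa[reference_id, ]
  cols <- which(row != GAP)
  res <- seq_along(cols)
  structure(
    list(reference_id = reference_id,
         col_to_res = stats::setNames(res, cols),
         res_to_col = stats::setNames(cols, res)),
    class = "column_ref_map"
  )
}

# column -> "REFID:X123"-style label, NA-safe; used in output tables
ref_label <- function(refmap, aln, columns) {
  out <- rep(NA_character_, length(columns))
  key <- as.character(columns)
  hit <- key %in% names(refmap$col_to_res)
  resno <- refmap$col_to_res[key[hit]]
  letter <- aln$aa[refmap$reference_id, columns[hit]]
  out[hit] <- paste0(letter, resno)
  out
}
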