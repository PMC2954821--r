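#' Extract a class signature table
#'
#' A class's signature sequence is the concatenation of its distinctive-site
#' residues in N-to-C order, with everything between the sites removed; it
#' compresses what distinguishes the class into a short comparable string.
#' For each requested sequence (analysis-set or tracking-only), the residue
#' at every signature site is reported together with a status: `delta` when
#' its symbol is one of the site's distinct values, `eta` when it equals the
#' conserved value of the other classes, `missing` for a gap, and `other`
#' for a symbol that is neither — the situation non-mammalian orthologs
#' routinely present, since site definitions come from the analysis set
#' only.
#'
#' @param aln an [msa].
#' @param sites a [classify_sites()] table.
#' @param class_label the class whose signature to extract.
#' @param ids sequences to tabulate (default: all records).
#' @param alphabet the [aa_alphabet] the sites were called with.
#' @return List of class `signature_table`: `class_label`, `sites` (tibble:
#'   signature_index, column, eta_symbol, delta_symbols) and `table`
#'   (long tibble: id, signature_index, column, residue, status).
#' @export
extract_signature <- function(aln, sites, class_label, ids = NULL,
                              alphabet = aa_alphabet("reduced15")) {
  ssites <- sites[sites$category == "distinctive" &
                    !is.na(sites$distinct_class) &
                    sites$distinct_class == class_label, ]
  if (nrow(ssites) == 0) {
    warning("class ", class_label, " has no distinctive sites; empty signature")
  }
  ssites <- ssites[order(ssites$column), ]
  if (is.null(ids)) ids <- aln$meta$id
  miss <- setdiff(ids, aln$meta$id)
  if (length(miss) > 0) stop("unknown ids: ", paste(miss, collapse = ", "))

  site_info <- tibble::tibble(
    signature_index = ssites$signature_index,
    column = ssites$column,
    eta_symbol = ssites$eta_symbol,
    delta_symbols = ssites$delta_symbols
  )
  rows <- vector("list", nrow(ssites))
  for (k in seq_len(nrow(ssites))) {
    col <- ssites$column[k]
    res <- aln$aa[ids, col]
    sym <- encode_letters(res, alphabet)
    dset <- ssites$delta[[k]]$symbol
    status <- ifelse(res == GAP, "missing",
              ifelse(sym %in% dset, "delta",
              ifelse(sym == ssites$eta_symbol[k], "eta", "other")))
    rows[[k]] <- tibble::tibble(
      id = ids, signature_index = ssites$signature_index[k],
      column = col, residue = unname(res), status = unname(status)
    )
  }
  structure(
    list(class_label = class_label, sites = site_info,
         table = dplyr::bind_rows(rows)),
    class = "signature_table"
  )
}

#' Signature strings, one per sequence
#'
#' @param sig a [extract_signature()] result.
#' @return Named character vector: concatenated residues at the signature
#'   sites in index order, per sequence.
#' @export
signature_strings <- function(sig) {
  tab <- sig$table[order(sig$table$id, sig$table$signature_index), ]
  vapply(split(tab$residue, tab$id), paste, "", collapse = "")
}

#' Track acquisition of distinct values across a lineage ranking
#'
#' Follows when each signature site first acquired a distinct (delta) value
#' over a user-supplied organism ordering — early-diverging taxa first. No
#' phylogeny is inferred: "first appearance" is rank order over the supplied
#' taxa, and equally-ranked organisms are interchangeable. A site is flagged
#' as a *reversion* when a delta value witnessed at an earlier rank gives
#' way to the eta value at a later rank — the unusual delta-to-eta
#' direction.
#'
#' @param sig a [extract_signature()] result covering one representative
#'   sequence per organism.
#' @param lineage tibble with columns `id`, `organism`, `rank` (smaller rank
#'   = earlier-diverging); every id must be present in `sig$table` and vice
#'   versa.
#' @return List of class `acquisition_summary`: `class_label`, `per_organism`
#'   (tibble: organism, rank, n_delta), `per_site` (tibble: signature_index,
#'   column, first_delta_rank, first_delta_organism, reversion).
#' @export
acquisition_summary <- function(sig, lineage) {
  stopifnot(inherits(sig, "signature_table"))
  need <- c("id", "organism", "rank")
  if (!all(need %in% names(lineage))) {
    stop("lineage needs columns: ", paste(need, collapse = ", "))
  }
  tab_ids <- unique(sig$table$id)
  if (!setequal(tab_ids, lineage$id)) {
    stop("lineage ids and signature ids differ")
  }
  tab <- dplyr::left_join(sig$table, lineage, by = "id")

  per_org <- tab |>
    dplyr::group_by(.data$organism, .data$rank) |>
    dplyr::summarise(n_delta = sum(.data$status == "delta"), .groups = "drop") |>
    dplyr::arrange(.data$rank)

  per_site <- tab |>
    dplyr::group_by(.data$signature_index, .data$column) |>
    dplyr::summarise(
      first_delta_rank = if (any(.data$status == "delta"))
        min(.data$rank[.data$status == "delta"]) else NA_integer_,
      first_delta_organism = if (any(.data$status == "delta"))
        .data$organism[.data$status == "delta"][
          which.min(.data$rank[.data$status == "delta"])] else NA_character_,
      reversion = any(.data$status == "delta") &&
        any(.data$status == "eta" &
              .data$rank > min(.data$rank[.data$status == "delta"])),
      .groups = "drop") |>
    dplyr::arrange(.data$signature_index)

  structure(
    list(class_label = sig$class_label, per_organism = per_org,
         per_site = per_site),
    class = "acquisition_summary"
  )
}
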