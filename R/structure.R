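#' Read a coordinate file into a structure model
#'
#' Accepts PDB and mmCIF files. Only model 1 is kept; for alternate-location
#' atoms only the highest-occupancy conformer is retained; hydrogens are
#' dropped, so all distance queries are heavy-atom distances (the cutoff
#' semantics the crystal structures support — they carry no hydrogens).
#' HETATM records (waters, ions, nucleotide analogs) are excluded: contact
#' and interface queries concern protein residues.
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file.
#' @param structure_id id stored on the model (default: file base name).
#' @return Object of class `structure_model`: list with `id` and `atoms`, a
#'   tibble with columns chain, resno, insert, resid, elety, x, y, z, o and
#'   `res_key` (chain|resno|insert).
#' @export
read_structure <- function(path, structure_id = NULL) {
  if (is.null(structure_id)) {
    structure_id <- sub("\\.(pdb|ent|cif)(\\.gz)?$", "", basename(path),
                        ignore.case = TRUE)
  }
  is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- if (is_cif) bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
         else bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- tibble::as_tibble(pdb$atom)
  at$.idx <- seq_len(nrow(at))
  at <- at[at$type == "ATOM", ]
  # hydrogen filter: element symbol when present, else atom-name convention
  elesy <- at$elesy
  if (all(is.na(elesy)) || is.null(elesy)) {
    is_h <- grepl("^[0-9]*H", trimws(at$elety))
  } else {
    is_h <- !is.na(elesy) & trimws(elesy) %in% c("H", "D")
    is_h[is.na(elesy)] <- grepl("^[0-9]*H", trimws(at$elety[is.na(elesy)]))
  }
  at <- at[!is_h, ]
  if (nrow(at) == 0) stop("no heavy protein atoms in ", path)
  at$insert <- ifelse(is.na(at$insert), "", at$insert)
  if (is.null(at$o)) at$o <- 1
  at$o[is.na(at$o)] <- 1

  # alternate locations: keep the highest-occupancy conformer per atom slot
  alt <- if (!is.null(at$alt)) ifelse(is.na(at$alt), "", at$alt) else ""
  if (any(alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    ord <- order(key, -at$o)
    at <- at[ord, ][!duplicated(key[ord]), ]
    at <- at[order(at$.idx), ]
  }

  atoms <- tibble::tibble(
    chain = at$chain, resno = at$resno, insert = at$insert,
    resid = at$resid, elety = at$elety,
    x = at$x, y = at$y, z = at$z, o = at$o,
    res_key = paste(at$chain, at$resno, at$insert, sep = "|")
  )
  structure(list(id = structure_id, atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model>", x$id, "-", nrow(x$atoms), "heavy atoms,",
      length(unique(x$atoms$res_key)), "residues, chains:",
      paste(sort(unique(x$atoms$chain)), collapse = ", "), "\n")
  invisible(x)
}

#' Residues of a structure, in file order
#'
#' @param structure a `structure_model`.
#' @param chain optional chain id filter.
#' @return Tibble: chain, resno, insert, resid, res_key, one row per residue.
#' @export
structure_residues <- function(structure, chain = NULL) {
  at <- structure$atoms
  if (!is.null(chain)) at <- at[at$chain %in% chain, ]
  at[!duplicated(at$res_key), c("chain", "resno", "insert", "resid", "res_key")]
}

#' Minimum heavy-atom distance between two residues
#'
#' The contact distance used throughout: the minimum over all heavy-atom
#' pairs of the Euclidean distance, in Angstrom. Symmetric and non-negative.
#'
#' @param structure a `structure_model`.
#' @param res_a,res_b residue keys (`"chain|resno|insert"`, see
#'   [structure_residues()]).
#' @return Distance in Angstrom.
#' @export
min_residue_distance <- function(structure, res_a, res_b) {
  xa <- res_coords(structure, res_a)
  xb <- res_coords(structure, res_b)
  min_xyz_distance(xa, xb)
}

res_coords <- function(structure, res_key) {
  at <- structure$atoms[structure$atoms$res_key == res_key, ]
  if (nrow(at) == 0) stop("residue has no coordinates: ", res_key)
  as.matrix(at[, c("x", "y", "z")])
}

# min distance between two coordinate matrices (rows = atoms); differences
# are formed directly to avoid catastrophic cancellation at large coordinates
min_xyz_distance <- function(xa, xb) {
  best <- Inf
  for (i in seq_len(nrow(xa))) {
    d2 <- (xb[, 1] - xa[i, 1])^2 + (xb[, 2] - xa[i, 2])^2 +
      (xb[, 3] - xa[i, 3])^2
    best <- min(best, d2)
  }
  sqrt(best)
}

#' Map alignment columns onto structure residues of one chain
#'
#' Pairwise-aligns the chain's observed one-letter sequence against the
#' (ungapped) alignment row, then composes the two coordinate systems. Strict
#' one-letter mismatches are tolerated but counted and reported — the
#' structures of interest include chimeric rows — and unmodeled residues are
#' simply unmapped.
#'
#' @param aln an [msa].
#' @param row_id alignment row to map.
#' @param structure a `structure_model`.
#' @param chain chain id within the structure.
#' @param min_coverage hard-error threshold: if fewer than this fraction of
#'   the row's residues map, the chain is probably the wrong one (default
#'   0.5).
#' @return Tibble of class `column_residue_map`: column, res_key, resno,
#'   insert, resid, row_letter, struct_letter, match (strict-letter);
#'   attribute `mismatch_rate`.
#' @export
map_columns_to_structure <- function(aln, row_id, structure, chain,
                                     min_coverage = 0.5) {
  if (!row_id %in% aln$meta$id) stop("row not in alignment: ", row_id)
  res <- structure_residues(structure, chain)
  if (nrow(res) == 0) stop("chain not in structure: ", chain)

  row <- aln$aa[row_id, ]
  cols <- which(row != GAP)
  row_seq <- paste(row[cols], collapse = "")
  struct_letters <- one_letter(res$resid)
  struct_seq <- paste(struct_letters, collapse = "")

  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(row_seq), Biostrings::AAString(struct_seq),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]

  ip <- 0L; is_ <- 0L
  map_row <- integer(0); map_res <- integer(0)
  for (k in seq_along(ap)) {
    if (ap[k] != "-") ip <- ip + 1L
    if (as_[k] != "-") is_ <- is_ + 1L
    if (ap[k] != "-" && as_[k] != "-") {
      map_row <- c(map_row, ip)
      map_res <- c(map_res, is_)
    }
  }
  if (length(map_row) < min_coverage * length(cols)) {
    stop("only ", length(map_row), " of ", length(cols), " residues of row '",
         row_id, "' map to chain ", chain, " — likely the wrong chain")
  }
  out <- tibble::tibble(
    column = cols[map_row],
    res_key = res$res_key[map_res],
    resno = res$resno[map_res],
    insert = res$insert[map_res],
    resid = res$resid[map_res],
    row_letter = row[cols[map_row]],
    struct_letter = struct_letters[map_res]
  )
  out$match <- out$row_letter == out$struct_letter
  mm <- 1 - mean(out$match)
  if (mm > 0) {
    message("column-structure map ", structure$id, ":", chain, " has ",
            sum(!out$match), " strict-letter mismatches (",
            sprintf("%.1f%%", 100 * mm), ") — chimeric or engineered row?")
  }
  attr(out, "mismatch_rate") <- mm
  class(out) <- c("column_residue_map", class(out))
  out
}

one_letter <- function(resid) {
  out <- bio3d::aa321(resid)
  out[is.na(out) | out == ""] <- "X"
  out
}

#' Discover d sites: structural neighbors of class-distinctive sites
#'
#' A second tier of distinctive sites that the strict eta criterion misses
#' because a second class also diverged. A column labeled *other* is rescued
#' as a *d site* when (i) a residue mapped to it lies strictly within
#' `cutoff` of a residue mapped to at least one distinctive (delta) column,
#' (ii) one non-gap symbol is conserved in every analysis-set sequence of at
#' least two classes, (iii) non-eta variation occurs in the anchoring site's
#' distinct class and (iv) variation is confined to that class plus at most
#' one additional class. With more than two varying classes no residue could
#' confidently be called the conserved value.
#'
#' @param aln an [msa].
#' @param sites a [classify_sites()] table.
#' @param structure a `structure_model`.
#' @param map a [map_columns_to_structure()] result covering the distinctive
#'   columns of interest.
#' @param alphabet the [aa_alphabet] used for `sites`.
#' @param cutoff contact cutoff in Angstrom, strict `<` (default 5.0).
#' @return Tibble, one row per d site: column, anchor_columns (list),
#'   min_distance, eta_symbol, conserved_classes, varying_classes,
#'   carriers (list).
#' @export
find_d_sites <- function(aln, sites, structure, map, alphabet, cutoff = 5.0) {
  delta_cols <- sites$column[sites$category == "distinctive"]
  anchor_map <- map[map$column %in% delta_cols, ]
  if (nrow(anchor_map) == 0) stop("no distinctive columns are mapped to the structure")

  cand_map <- map[map$column %in% sites$column[sites$category == "other"], ]
  if (nrow(cand_map) == 0) return(empty_d_table())

  ids <- analysis_ids(aln)
  sym <- encode_matrix(aln, alphabet, ids)
  fam <- aln$meta$class[match(ids, aln$meta$id)]
  classes <- sort(unique(fam))
  gap <- alphabet$gap_symbol
  anchor_class <- sites$distinct_class[match(anchor_map$column, sites$column)]

  anchor_xyz <- lapply(anchor_map$res_key, res_coords, structure = structure)

  rows <- list()
  for (k in seq_len(nrow(cand_map))) {
    xc <- res_coords(structure, cand_map$res_key[k])
    dists <- vapply(anchor_xyz, min_xyz_distance, 0, xa = xc)
    near <- which(dists < cutoff)
    if (length(near) == 0) next

    s <- sym[, cand_map$column[k]]
    verdict <- d_site_verdict(s, fam, classes, unique(anchor_class[near]), gap)
    if (is.null(verdict)) next

    rows[[length(rows) + 1]] <- tibble::tibble(
      column = cand_map$column[k],
      anchor_columns = list(anchor_map$column[near]),
      min_distance = min(dists[near]),
      eta_symbol = verdict$eta,
      conserved_classes = paste(verdict$conserved, collapse = ","),
      varying_classes = paste(verdict$varying, collapse = ","),
      carriers = list(ids[s != verdict$eta & s != gap])
    )
  }
  if (length(rows) == 0) return(empty_d_table())
  dplyr::bind_rows(rows)
}

empty_d_table <- function() {
  tibble::tibble(column = integer(0), anchor_columns = list(),
                 min_distance = numeric(0), eta_symbol = character(0),
                 conserved_classes = character(0),
                 varying_classes = character(0), carriers = list())
}

# symbol-level d-site test against a set of candidate anchor classes
d_site_verdict <- function(s, fam, classes, anchor_classes, gap) {
  # candidate eta symbols: fully conserved (non-gap) in >= 2 classes
  for (eta in unique(s[s != gap])) {
    conserved <- classes[vapply(classes, function(C) all(s[fam == C] == eta),
                                TRUE)]
    if (length(conserved) < 2) next
    varying <- setdiff(classes, conserved)
    for (D in anchor_classes) {
      if (!D %in% varying) next           # variation must occur in the anchor class
      sD <- s[fam == D]
      if (!any(sD != eta & sD != gap)) next
      if (length(varying) > 2) next       # distinct class plus at most one more
      return(list(eta = eta, conserved = conserved, varying = varying))
    }
  }
  NULL
}

#' Fold d-site calls back into the site table
#'
#' Only columns currently labeled `other` are ever reassigned; invariant and
#' distinctive verdicts are untouched.
#'
#' @param sites a [classify_sites()] table.
#' @param d_sites a [find_d_sites()] table.
#' @return The updated site table.
#' @export
apply_d_sites <- function(sites, d_sites) {
  sel <- sites$column %in% d_sites$column & sites$category == "other"
  sites$category[sel] <- "d"
  sites$eta_symbol[sel] <-
    d_sites$eta_symbol[match(sites$column[sel], d_sites$column)]
  sites
}

#' Composition of a protein-protein interface by site category
#'
#' The interface is the set of receptor-chain residues with any heavy atom
#' strictly within `cutoff` of any heavy atom of the partner chains. Each
#' interface residue is assigned its alignment column's site category via
#' the column map; unmapped interface residues count as `other` (and are
#' reported). The core fraction — the share of the interface carried by
#' invariant or class-distinctive sites — distinguishes interfaces built by
#' modifying parental functionality from interfaces recruited de novo.
#'
#' @param structure a `structure_model`.
#' @param map a [map_columns_to_structure()] result for the receptor chain.
#' @param receptor_chain,partner_chains chain ids; must be disjoint.
#' @param sites a site table ([classify_sites()], after [apply_d_sites()] if
#'   d sites are wanted in the breakdown).
#' @param cutoff interface cutoff in Angstrom, strict `<` (default 4.0).
#' @param focal_class if given, only distinctive sites of this class count
#'   toward `distinctive` (others fall into `other`), matching per-class
#'   interface readouts.
#' @return List of class `interface_report`: `structure_id`, `receptor_chain`,
#'   `partner_chains`, `cutoff`, `residues` (tibble: res_key, resno, insert,
#'   resid, column, category, min_partner_distance), `counts` (invariant,
#'   distinctive, d, other), `size`, `core_fraction_percent`.
#' @export
interface_composition <- function(structure, map, receptor_chain,
                                  partner_chains, sites, cutoff = 4.0,
                                  focal_class = NULL) {
  if (length(partner_chains) == 0) stop("empty partner selection")
  if (receptor_chain %in% partner_chains) {
    stop("receptor chain cannot be among partner chains")
  }
  at <- structure$atoms
  chains <- unique(at$chain)
  missing <- setdiff(c(receptor_chain, partner_chains), chains)
  if (length(missing) > 0) stop("chains not in structure: ",
                                paste(missing, collapse = ", "))

  partner_xyz <- as.matrix(at[at$chain %in% partner_chains, c("x", "y", "z")])
  rec <- structure_residues(structure, receptor_chain)

  mind <- vapply(rec$res_key, function(k) {
    min_xyz_distance(res_coords(structure, k), partner_xyz)
  }, 0)
  iface <- rec[mind < cutoff, ]
  iface$min_partner_distance <- mind[mind < cutoff]

  iface$column <- map$column[match(iface$res_key, map$res_key)]
  cat_of <- sites$category[match(iface$column, sites$column)]
  dclass <- sites$distinct_class[match(iface$column, sites$column)]
  cat_of[is.na(cat_of)] <- "other"
  if (!is.null(focal_class)) {
    cat_of[cat_of == "distinctive" & (is.na(dclass) | dclass != focal_class)] <- "other"
  }
  iface$category <- cat_of
  n_unmapped <- sum(is.na(iface$column))
  if (n_unmapped > 0) {
    message(n_unmapped, " interface residue(s) not mapped to an alignment column; counted as 'other'")
  }

  counts <- table(factor(iface$category,
                         levels = c("invariant", "distinctive", "d", "other")))
  size <- nrow(iface)
  core <- if (size > 0) {
    100 * (counts[["invariant"]] + counts[["distinctive"]]) / size
  } else NA_real_
  structure(
    list(structure_id = structure$id, receptor_chain = receptor_chain,
         partner_chains = partner_chains, cutoff = cutoff,
         residues = iface,
         counts = as.list(stats::setNames(as.integer(counts), names(counts))),
         size = size, core_fraction_percent = core),
    class = "interface_report"
  )
}

#' @export
print.interface_report <- function(x, ...) {
  cat("<interface_report> ", x$structure_id, " chain ", x$receptor_chain,
      " vs {", paste(x$partner_chains, collapse = ","), "} at <",
      x$cutoff, " A: ", x$size, " residues, core ",
      ifelse(is.na(x$core_fraction_percent), "NA",
             sprintf("%.1f%%", x$core_fraction_percent)), "\n", sep = "")
  invisible(x)
}
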