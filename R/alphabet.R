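#' Amino-acid alphabets for column statistics
#'
#' All column statistics (mutual information, invariance, eta/delta calls)
#' run over an encoding of residue letters into symbols. The default
#' `reduced15` alphabet treats residues with similar side chains as
#' identical, merging I=L, F=Y, S=T, K=R and D=E into single values, for a
#' total of 15 residue symbols. `full20` keeps all 20 letters distinct. The
#' gap character is always its own symbol, never merged with any residue
#' group: a gap can therefore break invariance or eta-conservation but never
#' manufacture it.
#'
#' @param name `"reduced15"` or `"full20"`.
#' @return An object of class `aa_alphabet`: a list with `name`, `map` (a
#'   named character vector from the 20 residue letters to group symbols),
#'   `gap_symbol` (always `"-"`), and `groups` (symbol -> letters).
#' @examples
#' ab <- aa_alphabet("reduced15")
#' ab$map[c("K", "R")] # both "KR"
#' @export
aa_alphabet <- function(name = c("reduced15", "full20")) {
  name <- match.arg(name)
  if (name == "full20") {
    map <- stats::setNames(AA_LETTERS, AA_LETTERS)
  } else {
    groups <- list("G", "A", "V", c("I", "L"), "M", "P", c("F", "Y"), "W",
                   c("S", "T"), "N", "Q", "C", c("K", "R"), "H", c("D", "E"))
    map <- character(0)
    for (g in groups) {
      sym <- paste(g, collapse = "")
      map[g] <- sym
    }
    map <- map[AA_LETTERS]
  }
  new_aa_alphabet(name, map)
}

#' The 20 standard amino-acid one-letter codes
#' @keywords internal
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Gap character used throughout
#' @keywords internal
GAP <- "-"

new_aa_alphabet <- function(name, map) {
  stopifnot(setequal(names(map), AA_LETTERS), !anyNA(map))
  if (GAP %in% map) stop("gap symbol must be distinct from all residue symbols")
  groups <- split(names(map), map)
  structure(
    list(name = name, map = map, gap_symbol = GAP, groups = groups),
    class = "aa_alphabet"
  )
}

#' Load a custom alphabet from a two-column TSV
#'
#' The file must have a header row `letter<TAB>group` and one row per
#' residue letter; all 20 letters must be assigned a group.
#'
#' @param path path to the TSV.
#' @param name name stored on the returned alphabet.
#' @return An `aa_alphabet`.
#' @export
read_alphabet <- function(path, name = "custom") {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("letter", "group") %in% names(tab))) {
    stop("alphabet TSV needs columns 'letter' and 'group'")
  }
  missing <- setdiff(AA_LETTERS, tab$letter)
  if (length(missing) > 0) {
    stop("alphabet TSV does not assign letters: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$letter)) stop("duplicate letters in alphabet TSV")
  map <- stats::setNames(tab$group, tab$letter)[AA_LETTERS]
  new_aa_alphabet(name, map)
}

#' @export
print.aa_alphabet <- function(x, ...) {
  cat("<aa_alphabet>", x$name, "-", length(unique(x$map)), "residue symbols\n")
  for (sym in names(x$groups)) {
    cat(" ", sym, ": {", paste(x$groups[[sym]], collapse = ","), "}\n", sep = "")
  }
  invisible(x)
}

#' Encode one alignment column into alphabet symbols
#'
#' @param aln an [alignment][read_alignment].
#' @param column 1-based column index.
#' @param alphabet an [aa_alphabet].
#' @param ids sequence ids to encode (default: all records, in alignment
#'   order). Order of `ids` is preserved in the output.
#' @return Named character vector of symbols, one per selected record; gaps
#'   encode to the alphabet's `gap_symbol`.
#' @export
encode_column <- function(aln, column, alphabet, ids = NULL) {
  stopifnot(inherits(aln, "msa"), inherits(alphabet, "aa_alphabet"))
  if (length(column) != 1 || column < 1 || column > aln$n_columns) {
    stop("column out of range: ", column)
  }
  if (is.null(ids)) ids <- aln$meta$id
  if (length(ids) == 0) stop("empty record subset")
  miss <- setdiff(ids, aln$meta$id)
  if (length(miss) > 0) stop("unknown ids: ", paste(miss, collapse = ", "))
  letters <- aln$aa[ids, column]
  encode_letters(letters, alphabet)
}

# vectorised letter -> symbol encoding; gap passes through as gap_symbol
encode_letters <- function(letters, alphabet) {
  out <- alphabet$map[letters]
  isgap <- letters == GAP
  out[isgap] <- alphabet$gap_symbol
  if (anyNA(out)) {
    bad <- unique(letters[is.na(out) & !isgap])
    stop("letters outside alphabet: ", paste(bad, collapse = ", "))
  }
  stats::setNames(out, names(letters))
}

# whole-alignment symbol matrix (rows = records, preserves dimnames)
encode_matrix <- function(aln, alphabet, ids = NULL) {
  if (is.null(ids)) ids <- aln$meta$id
  m <- aln$aa[ids, , drop = FALSE]
  sym <- alphabet$map[m]
  sym[m == GAP] <- alphabet$gap_symbol
  matrix(sym, nrow = length(ids), dimnames = dimnames(m))
}
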