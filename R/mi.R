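#' Per-column, per-family symbol counts and probabilities
#'
#' The joint distribution behind the column statistic: `P(x, y)` is the
#' probability of finding symbol `x` at this column in a sequence of family
#' `y`, `P(x)` its marginal over families, and `P(y)` the family-size
#' fraction. Counts run over analysis-set sequences only; gaps count as the
#' gap symbol.
#'
#' @param aln an [msa].
#' @param column 1-based column index.
#' @param alphabet an [aa_alphabet].
#' @param classes optional subset of class labels (default: all analysis-set
#'   classes).
#' @return A list of class `column_profile`: `column`, `counts` (integer
#'   matrix symbols x classes), `p_xy`, `p_x`, `p_y`.
#' @export
column_profile <- function(aln, column, alphabet, classes = NULL) {
  meta <- aln$meta
  keep <- meta$analysis_set
  if (!is.null(classes)) keep <- keep & meta$class %in% classes
  ids <- meta$id[keep]
  if (length(ids) == 0) stop("no analysis-set sequences selected")
  syms <- encode_column(aln, column, alphabet, ids)
  fam <- meta$class[keep]
  counts <- table(factor(syms, levels = sort(unique(syms))), fam)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  n <- sum(counts)
  structure(
    list(column = column, counts = counts,
         p_xy = counts / n,
         p_x = rowSums(counts) / n,
         p_y = colSums(counts) / n),
    class = "column_profile"
  )
}

#' Mutual information between symbol value and family label for one pair
#'
#' Computes `I = sum_{x,y} P(x,y) log2( P(x,y) / (P(x) P(y)) )` by direct
#' summation over observed symbols (zero-count terms contribute 0), where
#' the family variable `y` ranges over the two classes of `pair`. The score
#' is normalized to `[0, 1]` by dividing by `H(Y)`, the entropy of the
#' family-label partition in the same log base, which is the tightest
#' universal upper bound on `I`.
#'
#' Whether the score is exactly zero is decided on the integer counts (the
#' two families' symbol count vectors are proportional), never by a float
#' threshold: downstream site classification hinges on the exact zero /
#' nonzero pattern.
#'
#' @param profile a [column_profile] covering (at least) the two classes.
#' @param pair character vector of two class labels.
#' @return A one-row tibble: `column`, `class_a`, `class_b`, `mi` (bits),
#'   `mi_norm`, `is_zero`.
#' @export
mutual_information <- function(profile, pair) {
  stopifnot(inherits(profile, "column_profile"), length(pair) == 2)
  miss <- setdiff(pair, colnames(profile$counts))
  if (length(miss) > 0) stop("profile lacks classes: ", paste(miss, collapse = ", "))
  cnt <- profile$counts[, pair, drop = FALSE]
  nA <- sum(cnt[, 1]); nB <- sum(cnt[, 2])
  if (nA == 0 || nB == 0) stop("empty family in pair: ", paste(pair, collapse = " vs "))

  is_zero <- all(cnt[, 1] * nB == cnt[, 2] * nA)

  n <- nA + nB
  p_xy <- cnt / n
  p_x <- rowSums(cnt) / n
  p_y <- c(nA, nB) / n
  terms <- p_xy * log2(p_xy / outer(p_x, p_y))
  raw <- sum(terms[cnt > 0])
  if (is_zero) raw <- 0
  h_y <- -sum(p_y * log2(p_y))
  tibble::tibble(column = profile$column,
                 class_a = pair[1], class_b = pair[2],
                 mi = raw, mi_norm = if (h_y > 0) raw / h_y else 0,
                 is_zero = is_zero)
}

#' Six pairwise mutual-information calculations per column
#'
#' A single calculation over all families cannot isolate sites where exactly
#' one family diverges, so every column is scored for all pairs of classes
#' (six pairs for the default four-class analysis). The zero / nonzero
#' pattern over the pairs is what identifies invariant and class-distinctive
#' columns.
#'
#' @param aln an [msa].
#' @param alphabet an [aa_alphabet].
#' @param n_classes required number of analysis-set classes (default 4; any
#'   k >= 3 is accepted when passed explicitly).
#' @return Tibble with one row per column x class pair: columns as in
#'   [mutual_information()].
#' @export
pairwise_scan <- function(aln, alphabet, n_classes = 4) {
  classes <- sort(unique(aln$meta$class[aln$meta$analysis_set]))
  if (length(classes) != n_classes) {
    stop("expected ", n_classes, " analysis-set classes, found ",
         length(classes), " (", paste(classes, collapse = ", "), ")")
  }
  if (n_classes < 3) stop("need at least 3 classes to define distinctive sites")
  pairs <- utils::combn(classes, 2)

  sym <- encode_matrix(aln, alphabet, analysis_ids(aln))
  fam <- aln$meta$class[aln$meta$analysis_set]

  res <- vector("list", aln$n_columns)
  for (j in seq_len(aln$n_columns)) {
    prof <- profile_from_symbols(j, sym[, j], fam)
    res[[j]] <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(k) {
      mutual_information(prof, pairs[, k])
    }))
  }
  dplyr::bind_rows(res)
}

# column_profile from an already-encoded symbol vector
profile_from_symbols <- function(column, syms, fam) {
  counts <- table(factor(syms, levels = sort(unique(syms))), fam)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  n <- sum(counts)
  structure(
    list(column = column, counts = counts, p_xy = counts / n,
         p_x = rowSums(counts) / n, p_y = colSums(counts) / n),
    class = "column_profile"
  )
}

#' Classify every column as invariant, class-distinctive or other
#'
#' A column is *invariant* when all analysis-set sequences carry one single
#' non-gap symbol. It is *distinctive for class C* when the analysis-set
#' sequences of the remaining classes all share one non-gap symbol (the
#' non-distinct value, eta) and at least one sequence of C carries a
#' different non-gap symbol (a distinct value, delta); eta may also occur
#' within C, so a site can stay ancestral-like in part of the class. Gaps in
#' any non-distinct class disqualify eta-conservation; gaps inside the
#' distinct class are ignored for delta detection (a gap is neither eta nor
#' delta). Everything else is *other* (structure-based d-site rescue happens
#' later, see [find_d_sites()]).
#'
#' Equivalently, in mutual-information terms: invariant columns have exactly
#' zero MI in all class pairs; distinctive columns have exactly zero MI in
#' every pair not involving the distinct class and nonzero MI in every pair
#' involving it. The symbol-level definition above is the one implemented;
#' the consistency with the MI pattern is a tested property.
#'
#' @param aln an [msa].
#' @param alphabet an [aa_alphabet]; invariance and eta-conservation are
#'   evaluated on this alphabet's symbols.
#' @param scan optional result of [pairwise_scan()] whose per-pair normalized
#'   scores are merged into the output table (recomputed when `NULL`).
#' @param n_classes forwarded to [pairwise_scan()].
#' @return Tibble (class `site_table`), one row per column: `column`,
#'   `category` (invariant / distinctive / other), `distinct_class`,
#'   `eta_symbol`, `eta_letters`, `delta` (list column of per-site tibbles:
#'   symbol, letters, carrier ids), `delta_symbols`, `variation_category`,
#'   `signature_index`, plus `mi_norm_<A>.<B>` score columns.
#' @export
classify_sites <- function(aln, alphabet, scan = NULL, n_classes = 4) {
  if (is.null(scan)) scan <- pairwise_scan(aln, alphabet, n_classes)
  ids <- analysis_ids(aln)
  sym <- encode_matrix(aln, alphabet, ids)
  fam <- aln$meta$class[match(ids, aln$meta$id)]
  subtype <- aln$meta$subtype[match(ids, aln$meta$id)]
  classes <- sort(unique(fam))
  gap <- alphabet$gap_symbol

  rows <- vector("list", aln$n_columns)
  for (j in seq_len(aln$n_columns)) {
    s <- sym[, j]
    verdict <- classify_column(s, fam, classes, gap)
    row <- tibble::tibble(
      column = j, category = verdict$category,
      distinct_class = verdict$distinct_class,
      eta_symbol = verdict$eta_symbol,
      eta_letters = NA_character_,
      delta = list(tibble::tibble(symbol = character(0),
                                  letters = character(0),
                                  carriers = list())),
      delta_symbols = NA_character_,
      variation_category = NA_character_
    )
    if (verdict$category == "invariant") {
      row$eta_symbol <- verdict$eta_symbol
      row$eta_letters <- collapse_letters(aln$aa[ids, j])
    } else if (verdict$category == "distinctive") {
      C <- verdict$distinct_class
      in_c <- fam == C
      row$eta_letters <- collapse_letters(aln$aa[ids[!in_c], j])
      dl <- delta_values(s[in_c], aln$aa[ids[in_c], j], ids[in_c],
                         verdict$eta_symbol, gap)
      row$delta <- list(dl)
      row$delta_symbols <- paste(dl$symbol, collapse = ",")
      row$variation_category <- variation_category_impl(
        s[in_c], subtype[in_c], verdict$eta_symbol, gap)
    }
    rows[[j]] <- row
  }
  out <- dplyr::bind_rows(rows)

  out$signature_index <- NA_integer_
  for (C in classes) {
    sel <- which(out$category == "distinctive" & out$distinct_class == C)
    out$signature_index[sel] <- seq_along(sel)
  }

  miw <- tidyr::pivot_wider(
    scan,
    id_cols = "column",
    names_from = c("class_a", "class_b"),
    values_from = "mi_norm",
    names_glue = "mi_norm_{class_a}.{class_b}"
  )
  out <- dplyr::left_join(out, miw, by = "column")
  class(out) <- c("site_table", class(out))
  out
}

# one column's verdict from symbols + family labels
classify_column <- function(s, fam, classes, gap) {
  nongap <- s != gap
  if (all(nongap) && length(unique(s)) == 1) {
    return(list(category = "invariant", distinct_class = NA_character_,
                eta_symbol = s[[1]]))
  }
  for (C in classes) {
    others <- s[fam != C]
    if (any(others == gap)) next
    u <- unique(others)
    if (length(u) != 1) next
    eta <- u
    inC <- s[fam == C]
    if (any(inC != eta & inC != gap)) {
      return(list(category = "distinctive", distinct_class = C,
                  eta_symbol = eta))
    }
  }
  list(category = "other", distinct_class = NA_character_,
       eta_symbol = NA_character_)
}

# distinct values within the distinct class: symbol, observed letters, carriers
delta_values <- function(s_c, letters_c, ids_c, eta, gap) {
  is_delta <- s_c != eta & s_c != gap
  d <- split(seq_along(s_c)[is_delta], s_c[is_delta])
  tibble::tibble(
    symbol = names(d),
    letters = vapply(d, function(ix) collapse_letters(letters_c[ix]), ""),
    carriers = lapply(d, function(ix) ids_c[ix])
  )
}

collapse_letters <- function(letters) {
  paste(sort(unique(letters[letters != GAP])), collapse = ",")
}

#' Subtype-variation category of a distinctive site
#'
#' Distinctive sites fall into three evolutionary patterns: the distinct
#' value may be one single symbol conserved across all subtypes of the class
#' (`conserved_delta`); the non-eta symbols may be confined to a single
#' subtype (`single_subtype`); or the class may show broader subtype
#' variation (`subtype_variable`). Gap positions inside the distinct class
#' carry no residue identity and are left out of the assessment.
#'
#' @param site one row of a [classify_sites()] table (or anything with
#'   `column`, `category`, `distinct_class`, `eta_symbol`).
#' @param aln the [msa] the table was computed from.
#' @param alphabet the [aa_alphabet] used.
#' @return One of `"conserved_delta"`, `"subtype_variable"`,
#'   `"single_subtype"`.
#' @export
variation_category <- function(site, aln, alphabet) {
  if (!identical(site$category, "distinctive")) {
    stop("variation category is only defined for distinctive sites")
  }
  ids <- analysis_ids(aln, site$distinct_class)
  s <- encode_column(aln, site$column, alphabet, ids)
  subtype <- aln$meta$subtype[match(ids, aln$meta$id)]
  variation_category_impl(s, subtype, site$eta_symbol, alphabet$gap_symbol)
}

variation_category_impl <- function(s_c, subtype_c, eta, gap) {
  keep <- s_c != gap
  s <- s_c[keep]; subtype <- subtype_c[keep]
  non_eta <- s != eta
  if (all(non_eta) && length(unique(s)) == 1) return("conserved_delta")
  if (length(unique(subtype[non_eta])) == 1) return("single_subtype")
  "subtype_variable"
}

#' Per-category and per-class site summary
#'
#' @param sites a [classify_sites()] table (possibly after
#'   [apply_d_sites()]).
#' @return A list: `n_columns`, `counts` (named: invariant, distinctive, d,
#'   other), `distinctive_by_class`, `variation_split`.
#' @export
summarize_sites <- function(sites) {
  counts <- table(factor(sites$category,
                         levels = c("invariant", "distinctive", "d", "other")))
  dist <- sites[sites$category == "distinctive", ]
  list(
    n_columns = nrow(sites),
    counts = as.list(as.integer(counts) |> stats::setNames(names(counts))),
    distinctive_by_class = as.list(table(dist$distinct_class)),
    variation_split = as.list(table(factor(dist$variation_category,
      levels = c("conserved_delta", "subtype_variable", "single_subtype"))))
  )
}
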