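# Custom hypothesis-matrix contrast coding over the 12 design cells.

#' The 12 design cells of the agreement experiment
#'
#' The experiment crosses grammaticality (match/mismatch) and head-noun
#' gender (feminine/masculine) with three agreeing elements (modifying
#' adjective, predicative adjective, verb).  Agreement type and lexical
#' category are deterministic functions of the element: only the modifying
#' adjective instantiates phrase-internal agreement (concord), and only the
#' verb is of verbal lexical category.
#'
#' @return A data.frame with one row per cell and columns `element`,
#'   `grammaticality`, `gender`, `agr_type`, `lex_cat` and a canonical
#'   `cell` label (`element.grammaticality.gender`).
#' @export
design_cells <- function() {
  cells <- expand.grid(
    gender = c("feminine", "masculine"),
    grammaticality = c("match", "mismatch"),
    element = c("modAdj", "predAdj", "verb"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  cells <- cells[, c("element", "grammaticality", "gender")]
  cells$agr_type <- ifelse(cells$element == "modAdj", "internal", "external")
  cells$lex_cat <- ifelse(cells$element == "verb", "verb", "adjective")
  cells$cell <- cell_label(cells)
  cells
}

cell_label <- function(df) {
  paste(df$element, df$grammaticality, df$gender, sep = ".")
}

#' Build a hypothesis matrix from named comparisons
#'
#' Each comparison is a named list entry and is either a simple averaged
#' difference, `list(high = cells, low = cells)`, read as
#' `mean(high) - mean(low)`, or a difference of differences,
#' `list(inner = list(high=, low=), outer = list(high=, low=))`, read as
#' the inner difference within the outer `high` cells minus the inner
#' difference within the outer `low` cells.  Cell sets must be disjoint
#' within a comparison.  Weights are scaled so that applying a row to the
#' vector of cell means yields a difference of (averaged) condition means.
#'
#' @param comparisons named list of comparisons (see Details).
#' @param cells data.frame of design cells, by default [design_cells()].
#' @return A numeric matrix of class `hypothesis_matrix`, rows = comparison
#'   labels, columns = cell labels; every row sums to zero.
#' @export
build_hypothesis_matrix <- function(comparisons, cells = design_cells()) {
  stopifnot(is.list(comparisons), length(comparisons) > 0)
  if (is.null(names(comparisons)) || any(names(comparisons) == "")) {
    stop("every comparison must be named")
  }
  H <- matrix(0, nrow = length(comparisons), ncol = nrow(cells),
              dimnames = list(names(comparisons), cells$cell))
  for (nm in names(comparisons)) {
    H[nm, ] <- comparison_weights(comparisons[[nm]], cells$cell, nm)
  }
  structure(H, class = c("hypothesis_matrix", "matrix"))
}

comparison_weights <- function(cmp, all_cells, label) {
  w <- stats::setNames(numeric(length(all_cells)), all_cells)
  half <- function(cells, sign, scale) {
    bad <- setdiff(cells, all_cells)
    if (length(bad) > 0) {
      stop(sprintf("comparison '%s' references unknown cells: %s",
                   label, paste(bad, collapse = ", ")))
    }
    w[cells] <<- w[cells] + sign * scale / length(cells)
  }
  if (!is.null(cmp$inner)) {
    # difference of differences: inner contrast nested in outer high vs low
    for (outer_side in c(1, -1)) {
      outer_cells <- if (outer_side > 0) cmp$outer$high else cmp$outer$low
      for (inner_side in c(1, -1)) {
        inner_cells <- if (inner_side > 0) cmp$inner$high else cmp$inner$low
        sel <- intersect(outer_cells, inner_cells)
        if (length(sel) == 0) {
          stop(sprintf("comparison '%s': empty cell intersection", label))
        }
        half(sel, outer_side * inner_side, 1)
      }
    }
    if (length(intersect(cmp$inner$high, cmp$inner$low)) > 0 ||
        length(intersect(cmp$outer$high, cmp$outer$low)) > 0) {
      stop(sprintf("comparison '%s': overlapping cell sets", label))
    }
  } else {
    if (length(intersect(cmp$high, cmp$low)) > 0) {
      stop(sprintf("comparison '%s': overlapping cell sets", label))
    }
    half(cmp$high, +1, 1)
    half(cmp$low, -1, 1)
  }
  if (abs(sum(w)) > 1e-12) {
    stop(sprintf("comparison '%s': weights do not sum to zero", label))
  }
  w
}

#' The study's default hypothesis matrix
#'
#' Eight named comparisons over the 12 cells: main effects of
#' grammaticality (`Gram` = mismatch - match), gender (`Gen` = masculine -
#' feminine), agreement type (`AgrType` = internal - external), lexical
#' category (`LexCat` = verb - adjective), the two grammaticality
#' interactions (`GramxAgrType`, `GramxLexCat`), and the gender differences
#' of those interactions (`GramxGenxAgrType`, `GramxGenxLexCat`).  The
#' `GramxGen` two-way term is omitted by default, matching the predictor
#' set of the reported models; set `include_gram_gen = TRUE` to add it.
#'
#' Sign conventions: positive `Gram` is a mismatch penalty; negative
#' `AgrType` means external-agreement cells are read more slowly; negative
#' `LexCat` means adjective cells are read more slowly than verb cells;
#' positive `GramxAgrType` means the mismatch penalty is larger under
#' internal agreement.
#'
#' @param include_gram_gen add the grammaticality-by-gender two-way row.
#' @return a `hypothesis_matrix` (rows = effects, columns = 12 cells).
#' @export
default_hypothesis_matrix <- function(include_gram_gen = FALSE) {
  cl <- design_cells()
  pick <- function(...) {
    keep <- rep(TRUE, nrow(cl))
    sel <- list(...)
    for (f in names(sel)) keep <- keep & cl[[f]] %in% sel[[f]]
    cl$cell[keep]
  }
  gram <- list(high = pick(grammaticality = "mismatch"),
               low = pick(grammaticality = "match"))
  gen <- list(high = pick(gender = "masculine"),
              low = pick(gender = "feminine"))
  cmp <- list(
    Gram = gram,
    Gen = gen,
    AgrType = list(high = pick(agr_type = "internal"),
                   low = pick(agr_type = "external")),
    LexCat = list(high = pick(lex_cat = "verb"),
                  low = pick(lex_cat = "adjective")),
    GramxAgrType = list(
      inner = gram,
      outer = list(high = pick(agr_type = "internal"),
                   low = pick(agr_type = "external"))),
    GramxLexCat = list(
      inner = gram,
      outer = list(high = pick(lex_cat = "verb"),
                   low = pick(lex_cat = "adjective"))),
    GramxGenxAgrType = NULL,  # filled below from the two-way rows
    GramxGenxLexCat = NULL
  )
  if (include_gram_gen) {
    cmp <- append(cmp, list(GramxGen = list(inner = gram, outer = gen)),
                  after = 2)
  }
  cmp$GramxGenxAgrType <- NULL
  cmp$GramxGenxLexCat <- NULL
  H <- build_hypothesis_matrix(cmp, cl)
  # three-way rows: the gender (masculine - feminine) difference of the
  # corresponding two-way rows
  three_way <- function(two_way_row) {
    w <- H[two_way_row, ]
    masc <- cl$gender == "masculine"
    out <- numeric(length(w))
    out[masc] <- 2 * w[masc]
    out[!masc] <- -2 * w[!masc]
    out
  }
  H2 <- rbind(H,
              GramxGenxAgrType = three_way("GramxAgrType"),
              GramxGenxLexCat = three_way("GramxLexCat"))
  structure(H2, class = c("hypothesis_matrix", "matrix"))
}

#' Convert a hypothesis matrix to a contrast (coding) matrix
#'
#' Augments the hypothesis matrix with an intercept row of equal weights
#' (unless one is present) and returns its Moore-Penrose generalized
#' inverse, with rows labeled by cells and columns by effects.  Mapping a
#' coefficient vector through the contrast matrix to cell means and back
#' through the hypothesis weights is the identity on the comparison space.
#'
#' @param H a `hypothesis_matrix` (rows = effects, columns = cells).
#' @param tol relative tolerance for the rank check.
#' @return matrix of class `contrast_matrix` (cells x effects) with the
#'   augmented hypothesis matrix stored in attribute `hypothesis`.
#' @export
hypothesis_to_contrast <- function(H, tol = 1e-10) {
  stopifnot(is.matrix(H))
  if (!"(Intercept)" %in% rownames(H)) {
    H <- rbind("(Intercept)" = rep(1 / ncol(H), ncol(H)), H)
  }
  qrH <- qr(t(H), tol = tol)
  if (qrH$rank < nrow(H)) {
    dep <- rownames(H)[qrH$pivot[seq(qrH$rank + 1, nrow(H))]]
    stop("hypothesis matrix is rank deficient; linearly dependent rows: ",
         paste(dep, collapse = ", "))
  }
  X <- MASS::ginv(H)
  dimnames(X) <- list(colnames(H), rownames(H))
  rt <- H %*% X
  if (max(abs(rt - diag(nrow(H)))) > 1e-8) {
    stop("generalized inverse round trip failed")  # numerically degenerate H
  }
  structure(X, class = c("contrast_matrix", "matrix"), hypothesis = H)
}

#' @export
print.hypothesis_matrix <- function(x, digits = 3, ...) {
  cat("Hypothesis matrix:", nrow(x), "comparisons over", ncol(x), "cells\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' @export
print.contrast_matrix <- function(x, digits = 3, ...) {
  cat("Contrast matrix:", nrow(x), "cells x", ncol(x), "predictors\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Attach contrast-coded predictors to a measures table
#'
#' Looks up each row's design cell in the contrast matrix and appends one
#' numeric predictor column per non-intercept effect.  Predictors whose
#' value is a function of the agreeing element alone (constant within item)
#' are flagged as between-item in the `between_item` attribute; these are
#' the columns excluded from by-item random slopes.
#'
#' @param measures data.frame with factor columns `grammaticality`,
#'   `gender`, `element`.
#' @param X a `contrast_matrix` from [hypothesis_to_contrast()].
#' @return `measures` with predictor columns appended; attributes
#'   `predictors` (character) and `between_item` (logical, named).
#' @export
attach_contrasts <- function(measures, X) {
  stopifnot(inherits(X, "contrast_matrix"))
  need <- c("grammaticality", "gender", "element")
  miss <- setdiff(need, names(measures))
  if (length(miss) > 0) stop("measures lacks columns: ", paste(miss, collapse = ", "))
  lab <- cell_label(measures)
  unknown <- setdiff(unique(lab), rownames(X))
  if (length(unknown) > 0) {
    stop("design cells absent from contrast matrix: ",
         paste(unknown, collapse = ", "))
  }
  eff <- setdiff(colnames(X), "(Intercept)")
  pred <- X[lab, eff, drop = FALSE]
  rownames(pred) <- NULL
  out <- cbind(measures, as.data.frame(pred))
  cl <- design_cells()
  between <- vapply(eff, function(e) {
    # between-item iff the column is determined by the element factor alone
    all(tapply(X[cl$cell, e], cl$element, function(v) diff(range(v)) < 1e-12))
  }, logical(1))
  attr(out, "predictors") <- eff
  attr(out, "between_item") <- between
  out
}
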