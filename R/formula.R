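#' Parse molecular formula strings into element counts
#'
#' Parses Hill-notation (or any-order) molecular formula strings such as
#' `"C10H15N2O8P"` into per-element counts. Each element symbol may be
#' followed by an optional positive integer count; an omitted count means 1.
#' Only elements present in [element_masses()] are accepted.
#'
#' @param x Character vector of formula strings.
#' @return A tibble with one row per input formula: column `formula` holding
#'   the canonical Hill-notation string (C first, H second, remaining elements
#'   alphabetical) and one integer column per element (`C`, `H`, `N`, `Na`,
#'   `O`, `P`, `S`).
#' @examples
#' parse_formula(c("C10H15N2O8P", "C6H9NOS"))
#' @seealso [format_formula()], [formula_mass()], [formula_dbe()]
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x))
  known <- names(.element_mass_vector())
  counts <- matrix(0L, nrow = length(x), ncol = length(known),
                   dimnames = list(NULL, known))
  for (i in seq_along(x)) {
    s <- x[i]
    if (is.na(s) || !nzchar(s)) {
      next # empty formula: all-zero counts
    }
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s, perl = TRUE)[[1]]
    tokens <- regmatches(s, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(s)) {
      pos <- setdiff(seq_len(nchar(s)),
                     unlist(mapply(seq, m, m + attr(m, "match.length") - 1L,
                                   SIMPLIFY = FALSE)))
      stop("malformed formula '", s, "': unparseable text at position ",
           min(pos), call. = FALSE)
    }
    sym <- sub("[0-9]*$", "", tokens)
    n <- sub("^[A-Za-z]+", "", tokens)
    bad <- !sym %in% known
    if (any(bad)) {
      stop("unknown element symbol '", sym[bad][1], "' in formula '", s, "'",
           call. = FALSE)
    }
    cnt <- ifelse(n == "", 1L, suppressWarnings(as.integer(n)))
    if (anyNA(cnt) || any(cnt < 1)) {
      stop("malformed count in formula '", s, "'", call. = FALSE)
    }
    for (j in seq_along(sym)) {
      counts[i, sym[j]] <- counts[i, sym[j]] + cnt[j]
    }
  }
  out <- tibble::as_tibble(counts)
  tibble::add_column(out, formula = format_formula(out), .before = 1)
}

#' Format element counts as canonical Hill-notation strings
#'
#' @param counts A data frame with one integer column per element symbol
#'   (extra non-element columns are ignored), as produced by [parse_formula()].
#' @return Character vector of canonical formula strings; the empty formula
#'   formats as `""`. Zero counts are omitted, count 1 is implicit.
#' @examples
#' format_formula(data.frame(C = 6, H = 9, N = 1, O = 1, S = 1))
#' @export
format_formula <- function(counts) {
  known <- names(.element_mass_vector())
  syms <- .hill_order(intersect(names(counts), known))
  mat <- as.matrix(counts[syms])
  apply(mat, 1, function(r) {
    keep <- which(r > 0)
    paste0(syms[keep], ifelse(r[keep] == 1, "", r[keep]), collapse = "")
  })
}

#' Monoisotopic mass of molecular formulas
#'
#' Sum of count times monoisotopic atomic mass over all elements, reproducible
#' to 1e-6 Da (atomic masses are tabulated to >= 6 decimals).
#'
#' @param x Character vector of formula strings, or a counts data frame from
#'   [parse_formula()].
#' @return Numeric vector of neutral monoisotopic masses in Da; the empty
#'   formula has mass 0.
#' @examples
#' formula_mass("C17H20N4O6") # riboflavin, 376.13828 Da
#' @export
formula_mass <- function(x) {
  counts <- if (is.character(x)) parse_formula(x) else x
  masses <- .element_mass_vector()
  syms <- intersect(names(counts), names(masses))
  as.numeric(as.matrix(counts[syms]) %*% masses[syms])
}

#' Double-bond equivalents (rings plus double bonds) of CHNOSP formulas
#'
#' Uses the standard convention for neutral molecules: trivalent N and P
#' contribute +1/2 each, divalent O and S contribute 0, so
#' `DBE = 1 + C - H/2 + (N + P)/2`. Non-integer values indicate an
#' odd-electron or charged composition (the even-electron "nitrogen rule"
#' for neutral molecules).
#'
#' @inheritParams formula_mass
#' @return Numeric vector of DBE values (may be half-integer).
#' @examples
#' formula_dbe("C17H20N4O6") # 10
#' @export
formula_dbe <- function(x) {
  counts <- if (is.character(x)) parse_formula(x) else x
  extra <- setdiff(names(.element_mass_vector()), c("C", "H", "N", "O", "S", "P"))
  for (el in intersect(extra, names(counts))) {
    if (any(counts[[el]] > 0)) {
      stop("DBE is defined here for CHNOSP formulas only; found element '",
           el, "'", call. = FALSE)
    }
  }
  get0 <- function(el) if (el %in% names(counts)) counts[[el]] else 0L
  1 + get0("C") - get0("H") / 2 + (get0("N") + get0("P")) / 2
}

#' Test whether one formula is an elementwise subformula of another
#'
#' A fragment composition is consistent with a precursor if every element
#' count of the fragment is at most the parent's count; the implied neutral
#' loss is the elementwise difference. Used to validate proposed fragment
#' compositions against their isolated precursor.
#'
#' @param fragment,parent Character vectors of formula strings (recycled to a
#'   common length).
#' @return For `is_subformula()`, a logical vector. For `neutral_loss()`, the
#'   canonical formula string of parent minus fragment, or `NA` where the
#'   fragment is not a subformula (`""` for an empty loss).
#' @examples
#' is_subformula("C4H4NS", "C6H9NOS") # TRUE
#' neutral_loss("C4H4NS", "C6H9NOS")  # "C2H5O"
#' @export
is_subformula <- function(fragment, parent) {
  n <- max(length(fragment), length(parent))
  fc <- parse_formula(rep_len(fragment, n))
  pc <- parse_formula(rep_len(parent, n))
  syms <- names(.element_mass_vector())
  rowSums(as.matrix(fc[syms]) > as.matrix(pc[syms])) == 0
}

#' @rdname is_subformula
#' @export
neutral_loss <- function(fragment, parent) {
  n <- max(length(fragment), length(parent))
  fc <- parse_formula(rep_len(fragment, n))
  pc <- parse_formula(rep_len(parent, n))
  syms <- names(.element_mass_vector())
  diff <- as.matrix(pc[syms]) - as.matrix(fc[syms])
  ok <- rowSums(diff < 0) == 0
  out <- rep(NA_character_, n)
  if (any(ok)) {
    out[ok] <- format_formula(tibble::as_tibble(diff[ok, , drop = FALSE]))
  }
  out
}
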