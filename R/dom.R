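#' Load an environmental DOM formula set
#'
#' DOM (dissolved organic matter) formula sets are consumed as plain text,
#' one Hill-notation formula per line, `#`-prefixed comments allowed.
#' Formulas are canonicalized and deduplicated (set semantics). The two
#' packaged sets, `"mesocosm"` and `"north_sea"`, are synthetic
#' reconstructions from the presence flags of the packaged metabolite
#' database (the underlying FT-ICR-MS datasets are not deposited).
#'
#' @param name_or_path `"mesocosm"`, `"north_sea"`, or a path to a formula
#'   list file.
#' @return Character vector of canonical formula strings.
#' @examples
#' length(dom_set("mesocosm")) # 19
#' @export
dom_set <- function(name_or_path) {
  packaged <- c(mesocosm = "dom_mesocosm.tsv", north_sea = "dom_north_sea.tsv")
  path <- if (name_or_path %in% names(packaged)) {
    system.file("extdata", packaged[[name_or_path]], package = "exometab",
                mustWork = TRUE)
  } else {
    name_or_path
  }
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  unique(parse_formula(lines)$formula)
}

#' Screen identified metabolites against a DOM formula set
#'
#' Marks each matched metabolite record present iff its canonical formula is
#' a member of the DOM set. Presence is formula-level only: FT-ICR-MS
#' intensities are relative, so no intensity comparison across instruments is
#' attempted.
#'
#' @param matches A match tibble from [match_formulas()].
#' @param dom Character vector of DOM formulas from [dom_set()].
#' @return `matches` with an added logical column `present`.
#' @export
screen_dom <- function(matches, dom) {
  dplyr::mutate(matches, present = .data$formula %in% dom)
}

#' Overlap between per-strain exometabolomes and a DOM formula set
#'
#' Counts the DOM-present formulas in the union of both strains' identified
#' sets and per strain, with the intersection. The inclusion-exclusion
#' identity is recomputed and reported (`consistent`), not silently enforced.
#'
#' @param formulas_a,formulas_b Distinct identified formulas per strain.
#' @param dom Character vector of DOM formulas.
#' @return A one-row tibble: `n_total`, `n_a`, `n_b`, `n_both`, `consistent`.
#' @examples
#' dom_overlap(c("C6H9NOS", "C8H9NO3"), "C8H9NO3", dom_set("mesocosm"))
#' @export
dom_overlap <- function(formulas_a, formulas_b, dom) {
  in_a <- intersect(unique(formulas_a), dom)
  in_b <- intersect(unique(formulas_b), dom)
  n_total <- length(union(in_a, in_b))
  n_both <- length(intersect(in_a, in_b))
  tibble::tibble(n_total = n_total, n_a = length(in_a), n_b = length(in_b),
                 n_both = n_both,
                 consistent = n_total == length(in_a) + length(in_b) - n_both)
}
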