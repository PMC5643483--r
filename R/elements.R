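# Atomic constants are loaded once from a delimited resource so that tests can
# pin the exact values behind every mass computed by the package.

.exometab_env <- new.env(parent = emptyenv())

#' Monoisotopic element masses used throughout the package
#'
#' Returns the package's immutable table of monoisotopic atomic masses (IUPAC
#' values, C = 12 by definition) together with the proton and electron masses
#' used for ion/neutral conversion. The table is read once per session from
#' the delimited resource shipped with the package.
#'
#' @return A tibble with columns `symbol` and `monoisotopic_mass` (Da).
#' @examples
#' element_masses()
#' @export
element_masses <- function() {
  if (is.null(.exometab_env$elements)) {
    path <- system.file("extdata", "element_masses.tsv", package = "exometab",
                        mustWork = TRUE)
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    stopifnot(all(c("symbol", "monoisotopic_mass") %in% names(tab)),
              all(tab$monoisotopic_mass > 0),
              tab$monoisotopic_mass[tab$symbol == "C"] == 12)
    .exometab_env$elements <- tab
  }
  .exometab_env$elements
}

# named mass lookup for chemical elements only (no proton/electron rows)
.element_mass_vector <- function() {
  tab <- element_masses()
  keep <- !tab$symbol %in% c("proton", "electron")
  stats::setNames(tab$monoisotopic_mass[keep], tab$symbol[keep])
}

#' @rdname element_masses
#' @export
proton_mass <- function() {
  tab <- element_masses()
  tab$monoisotopic_mass[tab$symbol == "proton"]
}

# element order used for canonical (Hill) formatting: C, H, then alphabetical
.hill_order <- function(symbols) {
  rest <- sort(setdiff(symbols, c("C", "H")))
  intersect(c("C", "H", rest), symbols)
}
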