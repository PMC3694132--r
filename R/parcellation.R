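#' Bundled 116-region anatomical parcellation table
#'
#' Returns the node table used as the default ordering for whole-brain
#' analyses: 90 cerebral regions (45 bilateral pairs) followed by 26
#' cerebellar regions (9 bilateral hemispheric lobules and 8 midline vermis
#' lobules), after the Automated Anatomical Labeling (AAL) atlas. Only the
#' label table is shipped; no atlas image is read or required.
#'
#' @return A data.frame with columns `index`, `label`, `abbrev`,
#'   `hemisphere` (`"L"`, `"R"`, or `"M"` for midline), `name`, and
#'   `division` (`"cerebrum"` or `"cerebellum"`), one row per region in
#'   canonical order.
#' @examples
#' regions <- aal_regions()
#' nrow(regions)  # 116
#' @export
aal_regions <- function() {
  path <- system.file("extdata", "aal116.tsv", package = "modnet",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Canonical node labels of the bundled parcellation
#'
#' @return Character vector of the 116 region labels in canonical order.
#' @export
aal_labels <- function() aal_regions()$label
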