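# Packaged atlas resources.

#' AAL atlas region labels
#'
#' The 116 region names of the AAL parcellation in atlas order (odd
#' indices left hemisphere, even right; cerebellar regions and vermis
#' last). Matrix files using this parcellation should carry these labels
#' in their header.
#'
#' @return Character vector of length 116.
#' @examples
#' head(aal116_labels())
#' @export
aal116_labels <- function() {
  path <- system.file("extdata", "aal116_labels.txt", package = "connmtpc",
                      mustWork = TRUE)
  lines <- trimws(sub("#.*$", "", readLines(path)))
  lines[nzchar(lines)]
}

#' Packaged rich-club node set
#'
#' The high-degree hub regions (bilateral superior frontal and superior
#' parietal cortices, precuneus, hippocampus, putamen, thalamus) as a
#' [subnetwork_definition()] over the AAL-116 parcellation. The underlying
#' node-set file (`extdata/rich_club_aal.txt`) is plain text and editable.
#'
#' @return A [subnetwork_definition()] named `"rich_club"`.
#' @export
rich_club_definition <- function() {
  path <- system.file("extdata", "rich_club_aal.txt", package = "connmtpc",
                      mustWork = TRUE)
  read_node_set(path, aal116_labels(), name = "rich_club")
}
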