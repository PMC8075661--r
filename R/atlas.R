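## Atlas lookup table handling. The bundled default is a 246-region table
## following the Brainnetome parcellation scheme (210 cortical subregions in
## bilateral pairs plus 36 subcortical nuclei) with standard subregion
## abbreviations; MNI coordinates are optional columns and are only needed
## for visualization export.

#' Load an atlas lookup table
#'
#' @param path TSV with at least columns `index`, `abbreviation`,
#'   `description`; optional `lobe` and MNI coordinates `x`, `y`, `z`.
#'   Defaults to the bundled 246-region table.
#' @return validated data.frame of class `atlas_table`.
#' @export
load_atlas <- function(path = system.file("extdata", "brainnetome_246.tsv",
                                          package = "dfcpattern")) {
  at <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE)
  need <- c("index", "abbreviation", "description")
  missing <- setdiff(need, names(at))
  if (length(missing))
    stop("atlas is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(at$index)) stop("duplicate atlas indices")
  if (!identical(as.integer(at$index), seq_len(nrow(at))))
    stop("atlas indices must be contiguous from 1")
  class(at) <- c("atlas_table", "data.frame")
  at
}

#' Look up region labels by index
#'
#' @param atlas an [load_atlas()] table.
#' @param index 1-based region indices.
#' @return character vector of abbreviations.
#' @export
atlas_labels <- function(atlas, index) {
  stopifnot(inherits(atlas, "atlas_table"))
  if (any(index < 1 | index > nrow(atlas)))
    stop("region index out of range 1..", nrow(atlas))
  atlas$abbreviation[index]
}
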