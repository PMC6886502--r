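#' Canonical shoot-apex domain order
#'
#' The ten microdissected domains of the maize shoot apex, in the fixed
#' order used throughout the package. This order is the tie-break order for
#' argmax domain assignment and the column order of every profile matrix.
#'
#' @return Character vector of the 10 domain labels.
#' @export
apex_domains <- function() {
  c("meristem", "Tip", "P0", "P1", "P2", "P3",
    "L1", "L2", "internode", "vasculature")
}

#' Ontogeny tissue subset used for profile clustering
#'
#' The meristem-to-P3 developmental series over which dynamically expressed
#' genes are selected and clustered.
#'
#' @return Character vector of 6 domain labels.
#' @export
ontogeny_tissues <- function() {
  c("meristem", "Tip", "P0", "P1", "P2", "P3")
}

# internal: ordered leaf ontogeny used for monotone-archetype calls
.leaf_series <- function() c("Tip", "P0", "P1", "P2", "P3")
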