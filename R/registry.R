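# Scoring schemes and the marker registry.
#
# Six semi-quantitative scoring schemes cover the panel:
#   binary_alteration      0/1 presence of a (genetically driven) alteration,
#                          one consensus call per tumor
#   quartile_0to3          0-3 by fraction of positive tumor cells
#                          (0, <10%, 10-49%, 50-90%+)
#   triad_0to2             0 negative / 1 mixed / 2 completely positive cores
#   quad_intensity_0to3    0 negative, 1 focal weak, 2 diffuse weak or focal
#                          intense, 3 diffuse intense
#   basal_1to2             1 basal-level vs 2 diffuse intense expression
#                          (markers never completely negative)
#   proliferation_fraction continuous positive-cell fraction in [0,1]

.SCHEMES <- list(
  binary_alteration = list(values = c(0, 1), min = 0, max = 1,
                           aggregation = "single_consensus"),
  quartile_0to3 = list(values = 0:3, min = 0, max = 3,
                       aggregation = "mean_of_cores"),
  triad_0to2 = list(values = 0:2, min = 0, max = 2,
                    aggregation = "mean_of_cores"),
  quad_intensity_0to3 = list(values = 0:3, min = 0, max = 3,
                             aggregation = "mean_of_cores"),
  basal_1to2 = list(values = c(1, 2), min = 1, max = 2,
                    aggregation = "mean_of_cores"),
  proliferation_fraction = list(values = NULL, min = 0, max = 1,
                                aggregation = "fraction")
)

#' Scoring scheme lookup
#'
#' @param scheme scheme identifier (see Details of [defaultMarkerRegistry()]).
#' @return list with \code{values} (allowed raw levels; NULL for the
#'   continuous proliferation fraction), \code{min}, \code{max} (theoretical
#'   range) and \code{aggregation} (\code{mean_of_cores},
#'   \code{single_consensus} or \code{fraction}).
#' @export
schemeInfo <- function(scheme) {
  info <- .SCHEMES[[scheme]]
  if (is.null(info)) stop("unknown scoring scheme: ", scheme)
  info
}

#' Names of the available scoring schemes
#' @return character vector of scheme identifiers.
#' @export
schemeNames <- function() names(.SCHEMES)

.checkRegistry <- function(reg) {
  need <- c("name", "scheme", "designated_subclass", "is_genetic", "excluded")
  miss <- setdiff(need, colnames(reg))
  if (length(miss))
    stop("registry lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(reg$name))
    stop("duplicate marker names in registry")
  bad <- setdiff(reg$scheme, schemeNames())
  if (length(bad))
    stop("unknown scheme(s) in registry: ", paste(bad, collapse = ", "))
  consensus <- vapply(reg$scheme,
                      function(s) schemeInfo(s)$aggregation, "") == "single_consensus"
  if (any(reg$scheme == "binary_alteration" & !consensus))
    stop("binary_alteration markers must aggregate by single consensus")
  reg
}

#' Read a marker registry from YAML
#'
#' The registry assigns each marker its scoring scheme, pre-designated
#' subclass, genetic flag (exempt from standardization) and exclusion flag.
#'
#' @param path path to a YAML file with a top-level \code{markers} list.
#' @return data frame with columns \code{name}, \code{scheme},
#'   \code{designated_subclass}, \code{is_genetic}, \code{excluded}.
#' @export
readMarkerRegistry <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$markers)) stop("registry file has no 'markers' entry: ", path)
  reg <- do.call(rbind, lapply(doc$markers, function(m)
    data.frame(name = m$name, scheme = m$scheme,
               designated_subclass = m$designated_subclass,
               is_genetic = isTRUE(m$is_genetic),
               excluded = isTRUE(m$excluded),
               stringsAsFactors = FALSE)))
  .checkRegistry(reg)
}

#' The default 24-marker registry
#'
#' The shipped panel: 23 protein markers (IHC/IF) plus EGFR FISH status, with
#' the scoring scheme tailored to each marker's staining pattern. The four
#' markers reflecting genetic abnormalities (IDH1_R132H, EGFR, EGFRvIII,
#' EGFR_FISH) are flagged \code{is_genetic} and are passed through
#' standardization unchanged. DLL3 ships with \code{excluded = TRUE}: it shows
#' no differential staining and is dropped before any expression analysis.
#'
#' @return registry data frame (see [readMarkerRegistry()]).
#' @examples
#' reg <- defaultMarkerRegistry()
#' table(reg$designated_subclass)
#' @export
defaultMarkerRegistry <- function() {
  path <- system.file("extdata", "marker_registry.yaml", package = "gbmsub",
                      mustWork = TRUE)
  readMarkerRegistry(path)
}

# theoretical range of a marker's scheme, used for min-max standardization
schemeRange <- function(scheme) {
  info <- schemeInfo(scheme)
  c(info$min, info$max)
}
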