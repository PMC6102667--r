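example_catalog <- function() {
  data.frame(
    name = c("thaliana", "budding_yeast", "drosophila",
             "motif_chain", "motif_cycle", "motif_star"),
    nodes = c(15L, 12L, 17L, 3L, 3L, 4L),
    source = c(
      "Chaos et al. (2006) J Plant Growth Regul 25:278-289",
      "Li et al. (2004) PNAS 101:4781-4786",
      "Albert & Othmer (2003) J Theor Biol 223:1-18",
      rep("synthetic motif, in the style of Gates & Rocha (2016)", 3L)),
    description = c(
      "Arabidopsis thaliana floral organ specification GRN",
      "Budding yeast cell-cycle regulatory network",
      "Drosophila segment polarity GRN (simplified, single cell)",
      "Linear chain x1 -> x2 -> x3 with self-sustaining source",
      "3-node rotation: each node copies its predecessor",
      "Self-sustaining hub copied by three leaves"),
    stringsAsFactors = FALSE)
}

#' Load a packaged example Boolean network
#'
#' Transcriptions of classic regulatory network models, shipped as cnet files:
#' the *Arabidopsis thaliana* floral organ GRN (15 nodes; in this model TFL1
#' turns on iff LFY = 0, EMF1 = 1 and AP1 = 0, and the network has exactly 10
#' synchronous attractors), the budding yeast cell cycle, the simplified
#' *Drosophila* segment polarity network, and small synthetic control motifs.
#' See [example_manifest()] for sources.
#'
#' @param name One of the names listed by [example_manifest()].
#' @return A [boolean_network()].
#' @examples
#' net <- load_example("thaliana")
#' @export
load_example <- function(name) {
  cat_ <- example_catalog()
  if (!is.character(name) || length(name) != 1L || !name %in% cat_$name) {
    stop("unknown example '", paste(name, collapse = ","),
         "'; available: ", paste(cat_$name, collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".cnet"), package = "bncana",
                      mustWork = TRUE)
  parse_cnet(path)
}

#' Catalog of packaged example networks
#'
#' @return A data frame with columns `name`, `nodes`, `source`, `description`.
#' @export
example_manifest <- function() example_catalog()
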