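# Built-in diet-domain catalog.
#
# Gene families repeatedly implicated in detoxification, chemosensation and
# digestion across insect diet studies, keyed by Pfam accession.  The catalog
# drives diet flagging of genes and ortho-groups.

DIET_CATALOG <- list(
  # detoxification
  "Cytochrome P450"                 = "PF00067",
  "Glutathione S-transferase"       = "PF00043",
  "Carboxylesterase"                = "PF00135",
  "ATP-binding cassette transporter" = "PF00005",
  # chemosensory
  "Ionotropic receptor"             = "PF00060",
  "Gustatory receptor"              = c("PF06151", "PF08395"),
  "Odorant receptor"                = c("PF13853", "PF02949"),
  "Odorant-binding protein"         = "PF01395",
  "Chemosensory protein"            = "PF03392",
  "Sensory neuron membrane protein" = "PF01130",
  # digestion
  "Serine protease"                 = "PF00089",
  "Serpin"                          = "PF00079",
  "Carboxypeptidase"                = "PF00246",
  "Aspartic protease"               = "PF00026",
  "Lipase"                          = c("PF00151", "PF01764", "PF06350",
                                        "PF04083", "PF01734", "PF00657",
                                        "PF13472"),
  "Alpha amylase"                   = "PF00128",
  "Thioredoxin"                     = "PF00085",
  "CUB"                             = "PF00431",
  "Ptu family"                      = "PF08117"
)

#' Diet-related Pfam domain catalog
#'
#' Returns the built-in catalog of diet-related gene families as a tibble
#' mapping family terms (cytochrome P450, serine protease, odorant receptor,
#' ...) to Pfam accessions.  The families cover three functional groups:
#' detoxification, chemosensory perception and digestion.  A gene carrying any
#' catalog domain is flagged diet-related by [flag_diet_genes()].
#'
#' @return A tibble with columns `term` (family name), `group`
#'   (`detoxification` / `chemosensory` / `digestion`) and `accession`
#'   (Pfam accession, `PF` + 5 digits), one row per accession.
#' @examples
#' diet_catalog()
#' @export
diet_catalog <- function() {
  groups <- c(rep("detoxification", 4L), rep("chemosensory", 6L),
              rep("digestion", 9L))
  tibble(
    term = rep(names(DIET_CATALOG), lengths(DIET_CATALOG)),
    group = rep(groups, lengths(DIET_CATALOG)),
    accession = unlist(DIET_CATALOG, use.names = FALSE)
  )
}
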