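#' Reference population panel
#'
#' The 26 population samples of the Phase 3 reference panel of the 1000
#' Genomes Project, with sample sizes and continental super-group
#' assignments. Allele-frequency tables produced and consumed by this
#' package carry one column per panel, labeled by the 3-letter code.
#'
#' @return A data.frame with columns `label` (3-letter code), `description`,
#'   `sample_size` and `super_group` (one of AFR, AMR, EAS, EUR, SAS);
#'   exactly 26 rows.
#' @examples
#' panel <- population_panel()
#' table(panel$super_group)
#' @export
population_panel <- function() {
  df <- data.frame(
    label = c("ACB", "ESN", "GWD", "LWK", "MSL", "ASW", "YRI",
              "CLM", "MXL", "PEL", "PUR",
              "CDX", "CHB", "JPT", "KHV", "CHS",
              "GBR", "FIN", "IBS", "TSI", "CEU",
              "BEB", "GIH", "ITU", "PJL", "STU"),
    description = c(
      "African Caribbean in Barbados",
      "Esan in Nigeria",
      "Gambian in Western Division, Mandinka",
      "Luhya in Webuye, Kenya",
      "Mende in Sierra Leone",
      "People with African Ancestry in Southwest USA",
      "Yoruba in Ibadan, Nigeria",
      "Colombians in Medellin, Colombia",
      "People with Mexican Ancestry in Los Angeles, CA, USA",
      "Peruvians in Lima, Peru",
      "Puerto Ricans in Puerto Rico",
      "Chinese Dai in Xishuangbanna, China",
      "Han Chinese in Beijing, China",
      "Japanese in Tokyo, Japan",
      "Kinh in Ho Chi Minh City, Vietnam",
      "Southern Han Chinese",
      "British in England and Scotland",
      "Finnish in Finland",
      "Iberian Populations in Spain",
      "Toscani in Italia",
      "Utah residents (CEPH) with Northern and Western European ancestry",
      "Bengali in Bangladesh",
      "Gujarati Indians in Houston, TX, USA",
      "Indian Telugu in the UK",
      "Punjabi in Lahore, Pakistan",
      "Sri Lankan Tamil in the UK"),
    sample_size = c(96L, 99L, 113L, 99L, 85L, 61L, 108L,
                    94L, 64L, 85L, 104L,
                    93L, 103L, 104L, 99L, 105L,
                    91L, 99L, 107L, 107L, 99L,
                    86L, 103L, 102L, 96L, 102L),
    super_group = c(rep("AFR", 7), rep("AMR", 4), rep("EAS", 5),
                    rep("EUR", 5), rep("SAS", 5)),
    stringsAsFactors = FALSE)
  class(df) <- c("pgx_population_panel", "data.frame")
  df
}

#' Panel labels belonging to a super-group
#'
#' @param panel a data.frame as returned by [population_panel()].
#' @param group super-group code, e.g. `"EUR"` or `"AFR"`.
#' @return character vector of 3-letter panel labels.
#' @export
panel_labels <- function(panel = population_panel(), group = NULL) {
  if (is.null(group)) return(panel$label)
  if (!all(group %in% panel$super_group))
    stop_invalid("unknown super-group: ", paste(setdiff(group, panel$super_group), collapse = ", "))
  panel$label[panel$super_group %in% group]
}
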