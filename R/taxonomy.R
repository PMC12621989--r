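#' Bilateral white matter tract taxonomy
#'
#' The 30 bilateral (left/right paired) tracts covered by the asymmetry
#' charts, spanning association pathways (including a limbic subdivision)
#' and projection pathways (with thalamic and striatal subdivisions), as
#' delineated by the TractSeg bundle definitions. Midline commissural
#' structures are excluded because they have no hemispheric pair.
#'
#' @return A data frame with 30 rows and columns `acronym`, `full_name`,
#'   `pathway` (`"association"` or `"projection"`) and `subcategory`
#'   (`"association"`, `"limbic"`, `"thalamic"`, `"striatal"` or
#'   `"projection"`).
#' @examples
#' tx <- tract_taxonomy()
#' nrow(tx)                      # 30
#' tx[tx$acronym == "AF", ]
#' table(tx$pathway)
#' @export
tract_taxonomy <- function() {
  tx <- rbind(
    data.frame(
      acronym = c("AF", "MLF", "IFO", "ILF", "SLF_I", "SLF_II", "SLF_III"),
      full_name = c(
        "Arcuate Fasciculus", "Middle Longitudinal Fasciculus",
        "Inferior Fronto-Occipital Fasciculus", "Inferior Longitudinal Fasciculus",
        "Superior Longitudinal Fasciculus I", "Superior Longitudinal Fasciculus II",
        "Superior Longitudinal Fasciculus III"
      ),
      pathway = "association", subcategory = "association"
    ),
    data.frame(
      acronym = c("CG", "UF", "FX"),
      full_name = c("Cingulum Bundle", "Uncinate Fasciculus", "Fornix"),
      pathway = "association", subcategory = "limbic"
    ),
    data.frame(
      acronym = c("T_PREF", "T_PREM", "T_PREC", "T_POSTC", "T_PAR", "T_OCC", "ATR"),
      full_name = c(
        "Thalamo-prefrontal", "Thalamo-premotor", "Thalamo-precentral",
        "Thalamo-postcentral", "Thalamo-parietal", "Thalamo-occipital",
        "Anterior Thalamic Radiation"
      ),
      pathway = "projection", subcategory = "thalamic"
    ),
    data.frame(
      acronym = c("ST_FO", "ST_PREF", "ST_PREM", "ST_PREC", "ST_POSTC", "ST_PAR", "ST_OCC"),
      full_name = c(
        "Striato-fronto-orbital", "Striato-prefrontal", "Striato-premotor",
        "Striato-precentral", "Striato-postcentral", "Striato-parietal",
        "Striato-occipital"
      ),
      pathway = "projection", subcategory = "striatal"
    ),
    data.frame(
      acronym = c("CST", "FPT", "ICP", "OR", "POPT", "SCP"),
      full_name = c(
        "Corticospinal Tract", "Frontal Pontine Tract",
        "Inferior Cerebellar Peduncle", "Optic Radiation",
        "Parieto-Occipital Pontine Tract", "Superior Cerebellar Peduncle"
      ),
      pathway = "projection", subcategory = "projection"
    )
  )
  rownames(tx) <- NULL
  tx
}
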