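#' Vascular territory reference table
#'
#' The nine vascular supply territories used throughout the package:
#' anterior (ACA), middle (MCA) and posterior (PCA) cerebral artery
#' territories coded separately per hemisphere, the left and right
#' cerebellum, and the brainstem (midline, no laterality). Each territory
#' carries a fixed side, compartment (supra-/infratentorial) and
#' circulation (anterior/posterior) assignment: ACA and MCA belong to the
#' anterior circulation, PCA, cerebellum and brainstem to the posterior
#' circulation; cerebellum and brainstem are infratentorial, the rest
#' supratentorial.
#'
#' @return A data.frame with one row per territory and columns
#'   `territory` (display name), `column` (cohort-file count column),
#'   `side` (`"left"`, `"right"`, `"midline"`), `compartment`
#'   (`"supratentorial"`, `"infratentorial"`) and `circulation`
#'   (`"anterior"`, `"posterior"`).
#' @examples
#' territory_info()
#' @export
territory_info <- function() {
  .territories
}

.territories <- data.frame(
  territory = c("ACA-left", "ACA-right", "MCA-left", "MCA-right",
                "PCA-left", "PCA-right", "Cerebellum-left",
                "Cerebellum-right", "Brainstem"),
  column = c("n_aca_l", "n_aca_r", "n_mca_l", "n_mca_r",
             "n_pca_l", "n_pca_r", "n_cereb_l", "n_cereb_r",
             "n_brainstem"),
  side = c("left", "right", "left", "right", "left", "right",
           "left", "right", "midline"),
  compartment = c(rep("supratentorial", 6), rep("infratentorial", 3)),
  circulation = c(rep("anterior", 4), rep("posterior", 5)),
  stringsAsFactors = FALSE
)

#' Cohort-file column names for the territory lesion counts
#'
#' @return Character vector of the nine count columns, in canonical order.
#' @export
territory_columns <- function() {
  .territories$column
}
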