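# Reagent cost sheet for the UMI-ligation TCR library preparation protocol.

#' Per-sample reagent costs of the library preparation protocol
#'
#' The itemised consumable costs (pounds sterling, UCL pricing) of preparing
#' one TCR amplicon library with the UMI-ligation protocol, excluding
#' sequencing. Useful for budgeting multi-sample studies.
#'
#' @return A data.frame with columns `reagent` and `cost_gbp`.
#' @export
library_prep_costs <- function() {
  read.csv(system.file("extdata", "library_prep_costs.csv",
                       package = "umitcr", mustWork = TRUE),
           stringsAsFactors = FALSE)
}

#' Total per-sample library cost, rounded to the nearest pound
#'
#' @return Integer cost in GBP.
#' @export
library_prep_cost_per_sample <- function() {
  round(sum(library_prep_costs()$cost_gbp))
}
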