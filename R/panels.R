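#' Study accession and genotype panels
#'
#' ID panels of the fourwing saltbush host-screening system. The sequencing
#' panel holds the 31 accessions genotyped at the ITS locus; the evaluation
#' panel holds the 17 cutting-propagated genotypes measured for agronomic,
#' leaf-morphology and chlorophyll-fluorescence traits. IDs combine the
#' historical parasitism status (`P` = previously parasitised by the
#' broomrape, `NP` = not parasitised; a fixed label, not a measured outcome)
#' with the row-column planting position.
#'
#' @return A data frame with columns `id` and `group` (`"P"`/`"NP"`).
#' @examples
#' table(sequencing_panel()$group)
#' @export
sequencing_panel <- function() {
  p <- c("1.2", "1.8", "2.22", "3.1", "3.3", "3.7", "3.8", "4.2", "4.4",
         "9.17", "9.18", "7.18", "7.19", "7.7", "10.14", "4.13", "3.18",
         "5.15")
  np <- c("1.6", "1.7", "1.10", "1.11", "1.12", "1.24", "2.2", "2.14",
          "2.20", "2.23", "2.24", "3.4", "3.13")
  data.frame(id = c(paste0("P", p), paste0("NP", np)),
             group = rep(c("P", "NP"), c(length(p), length(np))),
             stringsAsFactors = FALSE)
}

#' @rdname sequencing_panel
#' @export
evaluation_panel <- function() {
  p <- c("1.2", "1.8", "3.1", "3.3", "3.7", "3.8", "4.2")
  np <- c("1.7", "1.11", "1.12", "1.24", "2.2", "2.20", "2.23", "2.24",
          "3.4", "3.13")
  data.frame(id = c(paste0("P", p), paste0("NP", np)),
             group = rep(c("P", "NP"), c(length(p), length(np))),
             stringsAsFactors = FALSE)
}
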