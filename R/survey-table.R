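# Published per-survey summary table bundled with the package.

#' Per-survey trawl counts and species occurrence table
#'
#' The published summary of the 14 research-vessel surveys (1995--2006, 2011,
#' 2015): number of trawl stations per survey and the percentage occurrence
#' of the eight study species in the trawls. Species codes: S_aur
#' (*Sardinella aurita*), S_mad (*S. maderensis*), C_chr (*Chloroscombrus
#' chrysurus*), D_rho (*Caranx rhonchus*), B_aur (*Brachydeuterus auritus*),
#' S_dor (*Selene dorsalis*), T_tre (*Trachurus trecae*), S_gua (*Sphyraena
#' guachancho*).
#'
#' @return data frame with columns `year`, `n_trawls`, and one occurrence
#'   column (%) per species.
#' @export
survey_trawl_table <- function() {
  utils::read.csv(system.file("extdata", "nansen_trawl_table.csv",
                              package = "pelagicshift"))
}

#' Aggregate statistics of the survey table
#'
#' Recomputes the totals the published table prints: the total number of
#' trawl stations, the mean per-survey station count, and the mean occurrence
#' of each species across surveys.
#'
#' @param table the table from [survey_trawl_table()].
#' @return list with `total_trawls`, `mean_trawls`, and named vector
#'   `mean_occurrence` (%).
#' @export
survey_table_summary <- function(table = survey_trawl_table()) {
  occ <- setdiff(names(table), c("year", "n_trawls"))
  list(total_trawls = sum(table$n_trawls),
       mean_trawls = mean(table$n_trawls),
       mean_occurrence = vapply(table[occ], mean, 0.0))
}
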