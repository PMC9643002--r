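#' Reference whole-hippocampus connectivity strengths
#'
#' The published bilateral SIFT2-weight sums (group means over ten
#' subjects, with standard errors and the two percentage-of-connections
#' columns) for the twenty non-MTL cortical areas of the HCPMMP most
#' strongly connected with the whole hippocampus.  Shipped as a
#' plain-text table; used to check the percentage arithmetic of
#' [percent_columns()] against printed values.
#'
#' @return data frame with columns `area`, `location`, `mean_weight`,
#'   `sem`, `percent_all`, `percent_excl_mtl`.
#' @export
reference_connectivity_table <- function() {
  path <- system.file("extdata", "hippocampus_cortical_weights.tsv",
                      package = "hippotrack")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Recompute the reference percentage columns from printed weights
#'
#' The percentage columns of the reference table are defined against
#' grand totals over all (and all non-MTL) cortical parcels, which are
#' not printed themselves; each row's weight/percent pair implies them.
#' This recovers both grand totals by least squares over all rows
#' (`T = sum(v p) / sum(p^2)` with `p` as fractions) and recomputes
#' every percentage cell from the printed weights.
#'
#' @param table a data frame as from [reference_connectivity_table()].
#' @return the table with columns `recomputed_percent_all`,
#'   `recomputed_percent_excl_mtl` appended, and the implied totals in
#'   attributes `total_all` and `total_excl_mtl`.
#' @export
recompute_reference_percents <- function(table = reference_connectivity_table()) {
  v <- table$mean_weight
  p_all <- table$percent_all / 100
  p_ex <- table$percent_excl_mtl / 100
  total_all <- sum(v * p_all) / sum(p_all^2)
  total_ex <- sum(v * p_ex) / sum(p_ex^2)
  table$recomputed_percent_all <- round(100 * v / total_all, 2)
  table$recomputed_percent_excl_mtl <- round(100 * v / total_ex, 2)
  attr(table, "total_all") <- total_all
  attr(table, "total_excl_mtl") <- total_ex
  table
}
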