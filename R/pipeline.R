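#' Run the full hippocampal tractography pipeline on a phantom
#'
#' End-to-end analysis mirroring the tailored hippocampus pipeline:
#' build (or accept) a phantom; compute the m5TT amendment; generate a
#' whole-volume tractogram on the unamended 5TT (WM-proportional
#' seeding) and a hippocampus-seeded tractogram on the m5TT; fit
#' SIFT2-style weights on the combined tractogram; extract the
#' hippocampus tractogram (streamlines with a hippocampal endpoint);
#' split the long axis into thirds; build the weight-sum connectivity
#' table with percentage columns; and compute per-parcel
#' hippocampus-restricted endpoint density maps on a super-resolved
#' grid.
#'
#' @param phantom a `hippo_phantom` (or a [phantom_config()] to build).
#' @param n_whole whole-volume streamline count, default 20000.
#' @param n_hippo hippocampus-seeded streamline count, default 5000.
#' @param params a [tracking_params()]; its `seed` is ignored in favour
#'   of `seed`.
#' @param lambda SIFT2-style regularisation, default 0.01.
#' @param edm_factor super-resolution factor for endpoint maps,
#'   default 5.
#' @param seed integer master seed; sub-seeds are derived for the two
#'   tracking stages.
#' @param output_dir optional directory; when given, tractograms (.tck),
#'   weights, the connectivity table (TSV) and NIfTI maps are written
#'   there.
#' @return list with the phantom, tractograms, weights, hippocampus
#'   subset, regions, connectivity table and per-parcel EDMs.
#' @export
run_pipeline <- function(phantom = phantom_config(), n_whole = 20000,
                         n_hippo = 5000, params = tracking_params(),
                         lambda = 0.01, edm_factor = 5, seed = 1,
                         output_dir = NULL) {
  if (inherits(phantom, "phantom_config")) phantom <- build_phantom(phantom)
  stopifnot(inherits(phantom, "hippo_phantom"))
  m5 <- amend_to_m5tt(phantom$t5, phantom$hippocampus_mask,
                      phantom$config$inferior_axis)
  p_whole <- params; p_whole$seed <- as.integer(seed) * 2L + 1L
  p_hippo <- params; p_hippo$seed <- as.integer(seed) * 2L + 2L
  tg_whole <- generate_tractogram(n_whole, phantom$fod, phantom$t5, p_whole,
                                  seeding = "wm_proportional")
  tg_hippo <- generate_tractogram(n_hippo, phantom$fod, m5, p_hippo,
                                  seeding = "mask",
                                  mask = phantom$hippocampus_mask)
  combined <- combine_tractograms(tg_whole, tg_hippo)
  system <- build_density_system(combined, phantom$fod, m5)
  weights <- fit_weights(system, lambda = lambda)
  sub <- extract_endpoint_subset(combined, weights,
                                 phantom$hippocampus_mask)
  regions <- split_thirds(phantom$hippocampus_mask, phantom$long_axis)
  table <- build_connectivity_table(sub$tractogram, sub$weights,
                                    phantom$parcellation, regions)
  table <- percent_columns(table)
  fg <- fine_grid(phantom$grid, edm_factor)
  parcels <- table$parcel
  other_lab <- parcel_of_other_endpoint(sub$tractogram,
                                        phantom$parcellation, regions)
  edms <- lapply(parcels, function(lab) {
    keep <- other_lab == lab
    tg <- sub$tractogram
    tg$streamlines <- tg$streamlines[keep]
    endpoint_density_map(tg, fg, restrict = phantom$hippocampus_mask)
  })
  names(edms) <- table$name
  out <- list(phantom = phantom, m5tt = m5, whole = tg_whole,
              hippo = tg_hippo, combined = combined, weights = weights,
              hippocampus_tractogram = sub$tractogram,
              hippocampus_weights = sub$weights, regions = regions,
              table = table, edms = edms, fine_grid = fg, seed = seed)
  if (!is.null(output_dir)) write_pipeline_outputs(out, output_dir)
  out
}

# label of the non-hippocampal endpoint per streamline (0 if unassigned
# or both endpoints hippocampal)
parcel_of_other_endpoint <- function(tractogram, parcellation, regions) {
  inm <- endpoint_in_mask(tractogram, regions$whole)
  ep <- streamline_endpoints(tractogram)
  first <- ep[seq(1L, nrow(ep), by = 2L), , drop = FALSE]
  last <- ep[seq(2L, nrow(ep), by = 2L), , drop = FALSE]
  n <- length(tractogram)
  lab <- integer(n)
  single <- which(!inm$both & inm$any)
  if (length(single)) {
    oth <- matrix(0, length(single), 3)
    hf <- inm$first[single]
    oth[hf, ] <- last[single[hf], ]
    oth[!hf, ] <- first[single[!hf], ]
    lab[single] <- assign_parcel(oth, parcellation)
  }
  lab
}

write_pipeline_outputs <- function(res, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- c(tool = "hippotrack", seed = as.character(res$seed))
  write_tck(res$hippocampus_tractogram,
            file.path(output_dir, "hippocampus.tck"), prov)
  write_weights(res$hippocampus_weights,
                file.path(output_dir, "hippocampus_weights.txt"))
  tab <- res$table
  attrs <- attributes(tab)
  meta <- sprintf(
    "# intra_hippocampal=%.10g dropped_weight=%.10g total_weight=%.10g",
    attrs$intra_hippocampal, attrs$dropped_weight, attrs$total_weight)
  con <- file(file.path(output_dir, "connectivity.tsv"), "w")
  writeLines(meta, con)
  write.table(format(as.data.frame(tab), digits = 12), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  close(con)
  write_volume(res$phantom$t5$data, res$phantom$grid,
               file.path(output_dir, "t5.nii.gz"))
  write_volume(res$m5tt$data, res$phantom$grid,
               file.path(output_dir, "m5tt.nii.gz"))
  for (nm in names(res$edms))
    write_volume(res$edms[[nm]]$data, res$edms[[nm]]$grid,
                 file.path(output_dir, sprintf("edm_%s.nii.gz", nm)))
  invisible(output_dir)
}
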