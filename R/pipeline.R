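#' Full 2D-versus-3D comparison on a simulated neuropil
#'
#' Runs the complete study design on synthetic ground truth: generate a
#' spine population, place it in a tissue block, section the block into
#' virtual micrographs, then estimate synapse density by the 2D
#' size-frequency method and the direct 3D count, and assemble the
#' morphometric comparison (summary tables, converted sizes, rank
#' correlations).
#'
#' Defaults mirror the reference sampling design: a 190 um^3 block
#' (10 x 10 x 1.9 um) at 2 synapses/um^3, sectioned into 75 micrograph
#' fields totalling about 1900 um^2, slabs 65 nm thick.
#'
#' @param seed Integer seed driving every random stage (sub-stage seeds are
#'   derived from it).
#' @param true_density Simulated synapse density, per um^3.
#' @param extent Block extent `(Lx, Ly, Lz)`, um.
#' @param n_micrographs Number of virtual micrograph fields.
#' @param field_size Field edge length, um; default sized so the total
#'   examined area is `target_area`.
#' @param target_area Total examined area when `field_size` is `NULL`, um^2.
#' @param thickness Slab thickness, um.
#' @param params Generator configuration, [spine_params()].
#' @param criteria Sectioning criteria, [section_criteria()].
#' @return A list of class `"spine_comparison"`: `neuropil`, `sections`,
#'   `density` (list of three [density_estimate()]s: `sf_2d`, `count_3d`,
#'   `count_3d_all`), `tables` (`profiles_2d`, `spines_3d`), `summary`
#'   (stacked summary rows for SAL, PSD_L, head areas/volumes in both
#'   domains, SAS, SAL_S, PSD_S), and `correlations` (Spearman rho for
#'   SAL~PSD_L in 2D and SAS~volume in 3D).
#' @examples
#' \donttest{
#' cmp <- run_comparison(seed = 1)
#' cmp$density$sf_2d
#' }
#' @export
run_comparison <- function(seed,
                           true_density = 2,
                           extent = c(10, 10, 1.9),
                           n_micrographs = 75,
                           field_size = NULL,
                           target_area = 1900,
                           thickness = 0.065,
                           params = spine_params(),
                           criteria = section_criteria()) {
  if (is.null(field_size)) field_size <- sqrt(target_area / n_micrographs)
  n <- round(true_density * prod(extent))

  pop <- generate_population(n, params, seed = seed)
  np <- place_in_volume(pop, extent, seed = seed + 1)
  planes <- section_planes(n_micrographs, extent, field_size, thickness,
                           seed = seed + 2)
  sect <- section_volume(np, planes, criteria, seed = seed + 3)

  est2d <- size_frequency_density(sect, mode = criteria$frame_mode)
  est3d <- count_density_3d(np, include_shaft = FALSE)
  est3d_all <- count_density_3d(np, include_shaft = TRUE)

  pr <- sect$profiles
  heads <- np$spines[!np$spines$on_shaft, , drop = FALSE]

  summary <- rbind(
    summarize_values(pr$sal_length_um, "SAL", "um"),
    summarize_values(pr$psd_length_um, "PSD_L", "um"),
    summarize_values(pr$head_area_um2, "head_area_2d", "um^2"),
    summarize_values(volume_to_equivalent_area(heads$head_volume_um3),
                     "head_area_from_3d", "um^2"),
    summarize_values(area_to_equivalent_volume(pr$head_area_um2),
                     "head_volume_from_2d", "um^3"),
    summarize_values(heads$head_volume_um3, "head_volume_3d", "um^3"),
    summarize_values(length_to_disc_area(pr$sal_length_um), "SAL_S", "um^2"),
    summarize_values(length_to_disc_area(pr$psd_length_um), "PSD_S", "um^2"),
    summarize_values(heads$sas_um2, "SAS", "um^2")
  )

  correlations <- c(
    sal_psd_2d = spearman_rho(pr$sal_length_um, pr$psd_length_um),
    sas_volume_3d = spearman_rho(heads$sas_um2, heads$head_volume_um3)
  )

  out <- list(neuropil = np, sections = sect,
              density = list(sf_2d = est2d, count_3d = est3d,
                             count_3d_all = est3d_all),
              tables = list(profiles_2d = pr, spines_3d = np$spines),
              summary = summary, correlations = correlations,
              seed = seed)
  class(out) <- "spine_comparison"
  out
}

#' @export
print.spine_comparison <- function(x, ...) {
  cat("2D vs 3D spine comparison (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  true density      %.3f /um^3\n", x$neuropil$true_density))
  cat(sprintf("  2D size-frequency %.3f /um^3 (Nd = %d over %.0f um^2)\n",
              x$density$sf_2d$na, x$density$sf_2d$n_counted,
              x$density$sf_2d$examined))
  cat(sprintf("  3D count (spines) %.3f /um^3; with shafts %.3f /um^3\n",
              x$density$count_3d$na, x$density$count_3d_all$na))
  cat(sprintf("  Spearman SAL~PSD_L = %.2f, SAS~V = %.2f\n",
              x$correlations[["sal_psd_2d"]],
              x$correlations[["sas_volume_3d"]]))
  cat("  summary table in $summary\n")
  invisible(x)
}
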