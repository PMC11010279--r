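#' Write the scenario comparison report
#'
#' Writes the table produced by [run_comparison()] twice: a JSON file with
#' full-precision values, and a human-readable CSV rounded at the reporting
#' boundary only (2 decimals for money and QALY totals, 3 for incremental
#' QALYs).
#'
#' @param report Data frame from [run_comparison()].
#' @param path_csv,path_json Output paths (either may be `NULL` to skip).
#' @return Invisibly, the report.
#' @export
write_report <- function(report, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_json))
    jsonlite::write_json(report, path_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  if (!is.null(path_csv)) {
    rounded <- report
    money <- c("costs_intervention", "costs_comparator", "delta_costs",
               "inmb", "icer")
    qaly2 <- c("qalys_intervention", "qalys_comparator")
    rounded[money] <- lapply(rounded[money], round, digits = 2)
    rounded[qaly2] <- lapply(rounded[qaly2], round, digits = 2)
    rounded$delta_qalys <- round(rounded$delta_qalys, 3)
    utils::write.csv(rounded, path_csv, row.names = FALSE, na = "")
  }
  invisible(report)
}

#' Cost-effectiveness plane with the confidence ellipse
#'
#' Scatter of the PSA draws on the (dQALY, dCost) plane with the
#' willingness-to-pay line through the origin and, optionally, the
#' bivariate-normal confidence ellipse.
#'
#' @param draws A `psa_draws` object.
#' @param threshold Willingness-to-pay threshold drawn as a line (GBP per
#'   QALY); `NULL` to omit.
#' @param ellipse Coverage of the ellipse to overlay (default 0.95); `NULL`
#'   to omit.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(draws, threshold = 20000, ellipse = 0.95) {
  df <- draws$draws
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = delta_qalys, y = delta_costs)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6, colour = "grey30") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental costs (£)") +
    ggplot2::theme_minimal()
  if (!is.null(threshold))
    gg <- gg + ggplot2::geom_abline(slope = threshold, intercept = 0,
                                    linetype = "dashed", colour = "grey50")
  if (!is.null(ellipse)) {
    ep <- as.data.frame(ellipse_points(confidence_ellipse(draws, ellipse)))
    names(ep) <- c("delta_qalys", "delta_costs")
    gg <- gg + ggplot2::geom_path(data = ep, colour = "steelblue",
                                  linewidth = 0.7)
  }
  gg
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param ceac_df Data frame from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_df) {
  ggplot2::ggplot(ceac_df, ggplot2::aes(x = threshold, y = probability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay threshold (£/QALY)",
                  y = "Probability cost-effective") +
    ggplot2::theme_minimal()
}

#' Write a run manifest
#'
#' Every command writes exactly one JSON manifest alongside its outputs,
#' recording the command, its inputs, the seed, the package version, a
#' timestamp and the paths written.
#'
#' @param out_dir Output directory.
#' @param command Command name.
#' @param inputs Named list describing inputs (config paths, flags, ...).
#' @param seed Seed used (or `NULL`).
#' @param outputs Character vector of files written.
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(out_dir, command, inputs, seed, outputs) {
  manifest <- list(
    command = command,
    inputs = inputs,
    seed = seed,
    package = "starcea",
    version = as.character(utils::packageVersion("starcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
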