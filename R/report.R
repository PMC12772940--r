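# Reporting layer: machine-readable JSON/CSV reports, figures, and the
# helpers behind the command-line interface (inst/cli/retrodict).

#' Read a patient descriptor from a YAML/JSON file
#'
#' Fields: `age`, `weight`, `height`, `sex`, `eGFR`, optional
#' `pregnancy_week`, optional `comedications` (list of tags).
#'
#' @param path YAML (or JSON, a YAML subset) file path.
#' @return A `patient`.
#' @export
parse_patient <- function(path) {
  if (!file.exists(path)) .stop_schema("patient file not found: %s", path)
  raw <- yaml::read_yaml(path)
  patient(age = raw$age, weight = raw$weight, height = raw$height,
          sex = raw$sex %||% "male", eGFR = raw$eGFR %||% 90,
          pregnancy_week = raw$pregnancy_week,
          comedications = unlist(raw$comedications) %||% character())
}

.curves_frame <- function(an) {
  cur <- an$curves
  df <- data.frame(concentration = cur$grid, marginal = cur$marginal)
  for (i in seq_along(cur$bits))
    df[[paste0("w", cur$bits[i])]] <- cur$posteriors[i, ]
  df
}

.report_list <- function(an, assessment = NULL) {
  th <- an$thresholds
  rep <- list(
    package_version = as.character(utils::packageVersion("retrodict")),
    spec_hash = spec_hash(an$spec),
    drug = an$spec$drug_name,
    seed = an$settings$seed,
    settings = unclass(an$settings),
    regimen = an$regimen,
    n_considered = an$scenarios$n,
    priors = as.list(setNames(an$scenarios$prior, an$scenarios$bits)),
    thresholds = th$thresholds,
    partition = th$partition,
    degenerate = th$degenerate,
    retrodiction = list(label = an$retrodiction$label,
                        cutoff = an$retrodiction$cutoff,
                        max_posterior = as.list(an$retrodiction$max_posterior)))
  if (!is.null(assessment))
    rep$assessment <- list(
      observed = assessment$observed,
      undefined = assessment$undefined,
      posterior = if (assessment$undefined) NULL
                  else as.list(assessment$posterior),
      most_likely = assessment$most_likely,
      advice = assessment$advice)
  rep
}

.open_figure <- function(path, width = 7, height = 5) {
  if (grepl("[.]png$", path) && capabilities("png"))
    grDevices::png(path, width = width, height = height, units = "in", res = 150)
  else {
    path <- sub("[.]png$", ".pdf", path)
    grDevices::pdf(path, width = width, height = height)
  }
  path
}

#' Plot posterior probability curves
#'
#' One curve per scenario against the trough concentration, with vertical
#' dashed lines at the discrimination thresholds.
#'
#' @param an An `adherence_analysis`.
#' @return A ggplot object.
#' @export
plot_posterior_curves <- function(an) {
  df <- .curves_frame(an)
  long <- do.call(rbind, lapply(an$curves$bits, function(b) data.frame(
    concentration = df$concentration, scenario = paste0("w", b),
    posterior = df[[paste0("w", b)]])))
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$concentration,
                                           y = .data$posterior,
                                           colour = .data$scenario)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "trough concentration (mg/L)",
                  y = "posterior probability",
                  title = sprintf("%s %g mg q%gh - last %d dose(s)",
                                  an$spec$drug_name, an$regimen$dose,
                                  an$regimen$interval, an$scenarios$n)) +
    ggplot2::theme_minimal()
  if (nrow(an$thresholds$thresholds))
    gg <- gg + ggplot2::geom_vline(xintercept = an$thresholds$thresholds$crossing,
                                   linetype = "dashed", colour = "grey40")
  gg
}

#' Plot a sensitivity sweep
#'
#' @param sw A `sweep_result`.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sw) {
  df <- sw$summary
  df$level <- as.numeric(factor(df$level, levels = unique(df$level)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$threshold)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = df$level,
                                labels = as.character(sw$summary$level)) +
    ggplot2::labs(x = sw$factor, y = "lowest discrimination threshold (mg/L)") +
    ggplot2::theme_minimal()
}

#' Write posterior curves, thresholds and a JSON report to disk
#'
#' Produces `<stem>_curves.csv` (grid, marginal, one posterior column per
#' scenario; rows sum to 1 over the scenario columns wherever defined),
#' `<stem>_thresholds.csv`, `<stem>_report.json` and `<stem>_curves.png`
#' (PDF fallback when no PNG device is available). Re-running with the same
#' configuration reproduces the CSV byte-identically.
#'
#' @param an An `adherence_analysis`.
#' @param out_dir Output directory (created if missing).
#' @param stem Filename stem (default `"curves"`).
#' @param plot Also write the figure (default TRUE).
#' @return Named character vector of the files written, invisibly.
#' @export
run_curves <- function(an, out_dir, stem = "curves", plot = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(csv = file.path(out_dir, paste0(stem, "_curves.csv")),
             thresholds = file.path(out_dir, paste0(stem, "_thresholds.csv")),
             json = file.path(out_dir, paste0(stem, "_report.json")))
  write.csv(.curves_frame(an), files["csv"], row.names = FALSE)
  write.csv(an$thresholds$thresholds, files["thresholds"], row.names = FALSE)
  jsonlite::write_json(.report_list(an), files["json"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  if (plot) {
    fig <- .open_figure(file.path(out_dir, paste0(stem, "_curves.png")))
    print(plot_posterior_curves(an))
    grDevices::dev.off()
    files["figure"] <- fig
  }
  invisible(files)
}

#' Write a single-observation adherence assessment report
#'
#' @param an An `adherence_analysis`.
#' @param observed_c Observed TDM concentration, mg/L.
#' @param out_dir Output directory.
#' @param stem Filename stem.
#' @return List with the `assessment` and the files written.
#' @export
run_assess <- function(an, observed_c, out_dir, stem = "assess") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  as_ <- assess(an, observed_c)
  json <- file.path(out_dir, paste0(stem, "_report.json"))
  jsonlite::write_json(.report_list(an, as_), json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(list(assessment = as_, files = c(json = json)))
}

#' Write a sensitivity sweep to CSV/JSON plus a figure
#'
#' @param sw A `sweep_result`.
#' @param out_dir Output directory.
#' @param stem Filename stem (defaults to the factor name).
#' @return Named character vector of files written, invisibly.
#' @export
run_sweep <- function(sw, out_dir, stem = sw$factor) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(csv = file.path(out_dir, paste0(stem, "_sweep.csv")),
             json = file.path(out_dir, paste0(stem, "_sweep.json")))
  write.csv(sw$summary, files["csv"], row.names = FALSE)
  jsonlite::write_json(list(factor = sw$factor,
                            ref_level = sw$ref_level,
                            summary = sw$summary),
                       files["json"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  fig <- .open_figure(file.path(out_dir, paste0(stem, "_sweep.png")))
  print(plot_sweep(sw))
  grDevices::dev.off()
  files["figure"] <- fig
  invisible(files)
}
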