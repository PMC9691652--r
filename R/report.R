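#' Build a run manifest
#'
#' Records what produced a set of artifacts: the configuration file path and
#' its MD5 hash, the seed, the command, the package version and a timestamp.
#' Any artifact can be regenerated from the same configuration content,
#' seed and package version.
#'
#' @param config_path Path of the configuration file used.
#' @param seed Integer seed used.
#' @param command Free-text command label (e.g. `"run"`, `"psa"`).
#' @return A list of class `cea_manifest`.
#' @export
run_manifest <- function(config_path, seed, command) {
  hash <- if (!is.null(config_path) && file.exists(config_path)) {
    unname(tools::md5sum(config_path))
  } else NA_character_
  structure(
    list(config = config_path, config_md5 = hash, seed = as.integer(seed),
         command = command,
         package_version = as.character(packageVersion("mitracea")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "cea_manifest"
  )
}

#' @export
print.cea_manifest <- function(x, ...) {
  cat(sprintf("<cea_manifest> %s (seed %d, mitracea %s)\n  config %s [md5 %s]\n",
              x$command, x$seed, x$package_version, x$config, x$config_md5))
  invisible(x)
}

#' Write a base-case / scenario report to disk
#'
#' Emits the base-case and scenario results in the shape of the published
#' summary table: one CSV row per arm or scenario (currency rounded to whole
#' CNY, QALYs to two decimals) plus a full-precision JSON summary and, when
#' a manifest is given, a JSON manifest alongside.
#'
#' @param cea A `cea_result` from [run_cea()].
#' @param params The matching `cea_parameters`.
#' @param dir Output directory (created if needed).
#' @param scenarios Optional scenario tibble from [scenario_table()].
#' @param manifest Optional `cea_manifest`.
#' @return The report tibble, invisibly.
#' @export
write_cea_report <- function(cea, params, dir, scenarios = NULL, manifest = NULL) {
  stopifnot(inherits(cea, "cea_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  onetime <- sum(params$costs$mitraclip_onetime)
  device <- params$costs$mitraclip_onetime[["device"]]
  arms <- cea$arms
  base_rows <- tibble(
    scenario = "base_case",
    arm = arms$arm,
    device_cost = ifelse(arms$arm == "mitraclip", device, NA_real_),
    overall_onetime_cost = ifelse(arms$arm == "mitraclip", onetime, NA_real_),
    lifetime_cost = arms$lifetime_cost,
    lifetime_qaly = arms$lifetime_qaly,
    delta_cost = ifelse(arms$arm == "mitraclip", cea$comparison$delta_cost, NA_real_),
    delta_qaly = ifelse(arms$arm == "mitraclip", cea$comparison$delta_qaly, NA_real_),
    icer = ifelse(arms$arm == "mitraclip", cea$comparison$icer, NA_real_),
    icer_wtp_ratio = ifelse(arms$arm == "mitraclip",
                            cea$comparison$icer_wtp_ratio, NA_real_)
  )
  rows <- base_rows
  if (!is.null(scenarios)) {
    sc_rows <- tibble(
      scenario = scenarios$scenario,
      arm = "mitraclip",
      device_cost = scenarios$device_cost,
      overall_onetime_cost = scenarios$device_cost + (onetime - device),
      lifetime_cost = scenarios$lifetime_cost,
      lifetime_qaly = scenarios$lifetime_qaly,
      delta_cost = scenarios$delta_cost,
      delta_qaly = scenarios$delta_qaly,
      icer = scenarios$icer,
      icer_wtp_ratio = scenarios$icer_wtp_ratio
    )
    rows <- dplyr::bind_rows(rows, sc_rows)
  }
  rounded <- dplyr::mutate(
    rows,
    dplyr::across(c("device_cost", "overall_onetime_cost", "lifetime_cost",
                    "delta_cost", "icer"), round),
    dplyr::across(c("lifetime_qaly", "delta_qaly"), ~ round(.x, 2)),
    icer_wtp_ratio = round(.data$icer_wtp_ratio, 1)
  )
  utils::write.csv(rounded, file.path(dir, "report.csv"), row.names = FALSE, na = "")
  jsonlite::write_json(
    list(wtp = cea$wtp, rows = rows,
         comparison = as.list(cea$comparison)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (!is.null(manifest)) {
    jsonlite::write_json(unclass(manifest), file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(rows)
}
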