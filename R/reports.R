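# Report emitters: CSV files mirroring the published table layouts (money in
# GBP mln to 1 decimal, counts as integers, percentages to 1 decimal), each
# paired with a full-precision "raw" CSV, plus a JSON run manifest.

fmt_mln <- function(x) round(x / 1e6, 1)
fmt_pct <- function(x) round(100 * x, 1)

#' Write the cost-consequence table to CSV
#'
#' Two files: `<stem>.csv` formatted like the published table (costs in GBP
#' mln, counts rounded to integers, relative differences in percent) and
#' `<stem>_raw.csv` at full precision.
#'
#' @param cca A `bcca_cca` object.
#' @param dir Output directory.
#' @param stem File stem, default `"cost_consequence"`.
#' @return Character vector of the files written, invisibly.
#' @export
write_cca_csv <- function(cca, dir, stem = "cost_consequence") {
  raw <- tidy(cca)
  fmt <- raw |>
    dplyr::mutate(
      nbi = ifelse(block == "costs", fmt_mln(nbi), round_half_up(nbi)),
      hdwle = ifelse(block == "costs", fmt_mln(hdwle), round_half_up(hdwle)),
      abs_diff = ifelse(block == "costs", fmt_mln(abs_diff),
                        sign(abs_diff) * round_half_up(abs(abs_diff))),
      rel_diff = fmt_pct(rel_diff)
    )
  files <- file.path(dir, paste0(stem, c(".csv", "_raw.csv")))
  utils::write.csv(fmt, files[1], row.names = FALSE)
  utils::write.csv(raw, files[2], row.names = FALSE)
  invisible(files)
}

#' Write the budget-impact table to CSV
#'
#' Year rows plus a `Total` row; formatted and raw files as in
#' [write_cca_csv()].
#'
#' @param bi A `bcca_budget` tibble.
#' @param dir Output directory.
#' @param stem File stem.
#' @return Files written, invisibly.
#' @export
write_budget_csv <- function(bi, dir, stem = "budget_impact") {
  total_pop <- attr(bi, "total_population")
  if (is.null(total_pop)) total_pop <- sum(bi$population)
  total <- tibble::tibble(
    year = NA_integer_, population = total_pop,
    cost_nbi = sum(bi$cost_nbi), cost_hdwle = sum(bi$cost_hdwle),
    difference = sum(bi$difference)
  )
  raw <- dplyr::bind_rows(tibble::as_tibble(bi), total)
  fmt <- raw |>
    dplyr::mutate(dplyr::across(c(cost_nbi, cost_hdwle, difference), fmt_mln),
                  year = ifelse(is.na(year), "Total", as.character(year)))
  files <- file.path(dir, paste0(stem, c(".csv", "_raw.csv")))
  utils::write.csv(fmt, files[1], row.names = FALSE)
  utils::write.csv(raw, files[2], row.names = FALSE)
  invisible(files)
}

#' Write the scenario grid to CSV
#' @param scen Tibble from [run_all_scenarios()].
#' @param dir Output directory.
#' @param stem File stem.
#' @return Files written, invisibly.
#' @export
write_scenarios_csv <- function(scen, dir, stem = "scenarios") {
  fmt <- scen |>
    dplyr::mutate(dplyr::across(c(cost_nbi, cost_hdwle, cost_difference), fmt_mln),
                  effect_difference = round_half_up(effect_difference),
                  icer = signif(icer / 1000, 3))
  files <- file.path(dir, paste0(stem, c(".csv", "_raw.csv")))
  utils::write.csv(fmt, files[1], row.names = FALSE)
  utils::write.csv(scen, files[2], row.names = FALSE)
  invisible(files)
}

#' Write the tornado table to CSV
#' @param tor A `bcca_owsa` tibble.
#' @param dir Output directory.
#' @param stem File stem.
#' @return Files written, invisibly.
#' @export
write_owsa_csv <- function(tor, dir, stem = "owsa") {
  files <- file.path(dir, paste0(stem, c(".csv", "_raw.csv")))
  fmt <- tor |>
    tibble::as_tibble() |>
    dplyr::mutate(dplyr::across(c(outcome_low, outcome_high, outcome_base, range),
                                fmt_mln))
  utils::write.csv(fmt, files[1], row.names = FALSE)
  utils::write.csv(tibble::as_tibble(tor), files[2], row.names = FALSE)
  invisible(files)
}

write_manifest <- function(dir, command, files, config = NULL, seed = NULL,
                           scenario = NULL) {
  manifest <- list(
    command = command,
    config = if (is.null(config)) "defaults" else config,
    scenario = scenario,
    seed = seed,
    package_version = as.character(utils::packageVersion("barrettcca")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = basename(files)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Command-line entry point
#'
#' Thin subcommand dispatcher over the package's analysis functions, used by
#' the `inst/cli/barrettcca` wrapper script. Subcommands: `base-case`,
#' `budget-impact`, `scenario`, `owsa`, `microsim`, `validate`. Options:
#' `--config PATH`, `--out DIR`, `--scenario {1..6}`, `--n N`, `--seed S`,
#' `--perspective {nhs,hospital}`.
#'
#' Each run writes its CSV outputs plus a `manifest.json` listing them.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly (0 on success).
#' @export
cca_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: barrettcca <command> [--config PATH] [--out DIR]",
    "       [--scenario N] [--n N] [--seed S] [--perspective nhs|hospital]",
    "commands: base-case | budget-impact | scenario | owsa | microsim | validate",
    sep = "\n")
  fail <- function(...) {
    message(...)
    return(invisible(1L))
  }
  if (length(args) == 0) return(fail(usage))
  cmd <- args[1]
  opts <- list(out = ".", config = NULL, scenario = NULL, n = 10000L,
               seed = 1L, perspective = NULL)
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!key %in% names(opts) || i == length(rest))
      return(fail("bad option: ", rest[i], "\n", usage))
    opts[[key]] <- rest[i + 1]
    i <- i + 2
  }
  params <- tryCatch(load_parameters(opts$config), error = function(e) e)
  if (inherits(params, "error")) return(fail("config error: ", conditionMessage(params)))
  if (!is.null(opts$perspective)) {
    persp <- c(nhs = "NHS", hospital = "hospital")[tolower(opts$perspective)]
    if (is.na(persp)) return(fail("unknown perspective '", opts$perspective, "'"))
    params <- apply_override(params, "economics.perspective", unname(persp))
  }
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)

  files <- switch(cmd,
    "base-case" = {
      cca <- cost_consequence(params)
      write_cca_csv(cca, opts$out)
    },
    "budget-impact" = {
      write_budget_csv(budget_impact(params), opts$out)
    },
    "scenario" = {
      if (is.null(opts$scenario)) return(fail("scenario requires --scenario N"))
      id <- suppressWarnings(as.integer(opts$scenario))
      s <- tryCatch(run_scenario(id, params), error = function(e) e)
      if (inherits(s, "error")) return(fail(conditionMessage(s)))
      write_scenarios_csv(tidy(s), opts$out,
                          stem = paste0("scenario_", id))
    },
    "owsa" = {
      write_owsa_csv(owsa(params), opts$out)
    },
    "microsim" = {
      sim <- simulate_patients(as.integer(opts$n), as.integer(opts$seed), params)
      f1 <- file.path(opts$out, "microsim_patients.csv")
      write_patient_records(sim, f1)
      f2 <- file.path(opts$out, "microsim_summary.csv")
      utils::write.csv(aggregate_patients(sim), f2, row.names = FALSE)
      c(f1, f2)
    },
    "validate" = {
      sim <- simulate_patients(as.integer(opts$n), as.integer(opts$seed), params)
      rep <- validate_against_cohort(sim)
      f1 <- file.path(opts$out, "validation.csv")
      utils::write.csv(rep, f1, row.names = FALSE)
      if (!all(rep$pass)) message("validation FAILED for: ",
                                  paste(rep$statistic[!rep$pass], collapse = ", "))
      f1
    },
    return(fail("unknown command '", cmd, "'\n", usage))
  )
  write_manifest(opts$out, cmd, files, config = opts$config,
                 seed = if (cmd %in% c("microsim", "validate")) opts$seed,
                 scenario = opts$scenario)
  invisible(0L)
}
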