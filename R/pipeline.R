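# Readers/writers for the package's tabular formats and a small driver
# that chains stages with explicit seeds and provenance.

#' Read a refolding time course CSV
#'
#' Columns: `time_min`, `percent_refolded`, optional `error` (percent units).
#'
#' @param path CSV path.
#' @param label Label stored on the result.
#' @return A `refolding_timecourse` (see [normalize_refolding()]).
#' @export
read_timecourse_csv <- function(path, label = basename(path)) {
  df <- utils::read.csv(path)
  normalize_refolding(df, error_col = if ("error" %in% names(df)) "error",
                      label = label)
}

#' Write a time course as CSV (columns time_min, percent_refolded, error)
#'
#' @param tc A `refolding_timecourse`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tc, path) {
  utils::write.csv(
    data.frame(time_min = tc$t, percent_refolded = 100 * (1 - tc$p_nn),
               error = 100 * tc$sigma),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a contact trajectory CSV (columns frame, contacts)
#'
#' @param path CSV path.
#' @return Tibble with `frame` and `contacts`.
#' @export
read_contacts_csv <- function(path) {
  as_tibble(utils::read.csv(path))[, c("frame", "contacts")]
}

#' Write a contact trajectory CSV
#'
#' @param trajectory Tibble with `frame` and `contacts`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts_csv <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory[, c("frame", "contacts")]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a LiP-MS peptide table (TSV)
#'
#' Columns: `protein`, `start`, `end`, `cut_site`, `log2_ratio`,
#' `timepoint`, `significant`.
#'
#' @param path TSV path.
#' @return Peptide tibble.
#' @export
read_peptides_tsv <- function(path) {
  as_tibble(utils::read.delim(path))
}

#' Write a LiP-MS peptide table (TSV)
#'
#' @param peptides Peptide tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptides_tsv <- function(peptides, path) {
  utils::write.table(as.data.frame(peptides), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

PIPELINE_KEYS <- c("stages", "seed", "out_dir", "fit_refolding",
                   "kd_estimate", "entangle")

#' Run selected analysis stages from a configuration
#'
#' A thin driver over the package's functions. The configuration (a list,
#' or the path to a YAML file) names the stages to run and their inputs;
#' unknown keys are rejected, every random operation receives a seed
#' derived from the config's `seed`, and each JSON artifact carries a
#' provenance block (config hash, seed, package version) so identical
#' configs produce byte-identical outputs.
#'
#' Supported stages: `"fit-refolding"` (block `fit_refolding`: `csv`,
#' optional `error_default`), `"kd-estimate"` (block `kd_estimate`: `csvs`,
#' `radius_A`, optional `threshold`), `"entangle"` (block `entangle`:
#' `frame_pdb`, `native_pdb`, optional `cutoff`, `min_separation`).
#'
#' @param config List or YAML path.
#' @return Named list of stage results (also written to `out_dir` as JSON
#'   when `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown)) {
    abort_invalid("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  stages <- config$stages %||% character(0)
  known_stages <- c("fit-refolding", "kd-estimate", "entangle")
  if (!all(stages %in% known_stages)) {
    abort_invalid("unknown stage(s): %s",
                  paste(setdiff(stages, known_stages), collapse = ", "))
  }
  # dependency check up front, before any computation
  for (st in stages) {
    block <- switch(st, "fit-refolding" = "fit_refolding",
                    "kd-estimate" = "kd_estimate", "entangle" = "entangle")
    if (is.null(config[[block]])) {
      abort_invalid("stage %s requested but config block `%s` missing",
                    st, block)
    }
  }
  provenance <- list(config_hash = rlang::hash(config),
                     seed = config$seed %||% NA,
                     package_version = as.character(
                       utils::packageVersion("foldtrap")))
  out <- list(provenance = provenance)
  for (st in stages) {
    res <- switch(
      st,
      "fit-refolding" = {
        tc <- read_timecourse_csv(config$fit_refolding$csv)
        fit <- fit_biexponential(tc)
        fit <- k2_bounds(tc, fit,
                         sigma_default = config$fit_refolding$error_default %||% 0.01)
        as.list(glance(fit))
      },
      "kd-estimate" = {
        trajs <- lapply(config$kd_estimate$csvs, read_contacts_csv)
        est <- kd_replicates(
          trajs, volume = sphere_volume(config$kd_estimate$radius_A),
          threshold = config$kd_estimate$threshold)
        as.list(glance(est))
      },
      "entangle" = {
        nat <- read_calpha_pdb(config$entangle$native_pdb)
        frm <- read_calpha_pdb(config$entangle$frame_pdb)
        map <- native_contacts(nat,
                               cutoff = config$entangle$cutoff %||% 8,
                               min_separation = config$entangle$min_separation %||% 4)
        gm <- g_metric(frm, nat, map)
        list(G = gm$G, n_changed = gm$n_changed, n_contacts = gm$n_contacts)
      })
    out[[st]] <- res
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(
        c(list(provenance = provenance), setNames(list(res), st)),
        file.path(config$out_dir, paste0(gsub("-", "_", st), ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  out
}
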