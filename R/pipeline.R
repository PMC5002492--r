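#' Read a specimen composition table
#'
#' Tidy CSV, one specimen per row: identifier/metadata columns (e.g.
#' \code{id}, \code{tissue}, \code{year}, \code{treatment}, \code{block},
#' \code{yield}) followed by part concentrations in g kg^-1 (columns in
#' \code{mg_parts}, boron by default, in mg kg^-1 and converted on load).
#' The filling value is computed on load when the \code{fv} column is
#' absent.
#'
#' @param path CSV path.
#' @param parts part columns to treat as the composition; defaults to the
#'   guava part set (minus Fv if absent in the file).
#' @param kappa closure scale.
#' @param mg_parts parts reported in mg kg^-1.
#' @param fv filling-value column name.
#' @return data.frame with metadata columns untouched and composition
#'   columns in g kg^-1 including \code{fv}.
#' @export
read_specimens <- function(path, parts = NULL, kappa = 1000, mg_parts = "B",
                           fv = "Fv") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(parts)) parts <- intersect(parts_guava(), names(df))
  measured <- setdiff(parts, fv)
  if (!all(measured %in% names(df)))
    stop("specimen table lacks part column(s): ",
         paste(setdiff(measured, names(df)), collapse = ", "))
  if (fv %in% names(df)) {
    conv <- intersect(measured, mg_parts)
    df[conv] <- df[conv] / 1000
  } else {
    closed <- filling_value(as.matrix(df[measured]), kappa = kappa,
                            mg_parts = mg_parts, fv = fv)
    df[colnames(closed)] <- as.data.frame(closed)
  }
  df
}

#' Pipeline configuration
#'
#' Flat key-value configuration (a YAML file or a named list) for
#' \code{\link{run_pipeline}}. Required keys: \code{specimens} (CSV path).
#' Optional: \code{sbp} (CSV path; default packaged design), \code{kappa},
#' \code{alpha}, \code{n_draws}, \code{cutoff}, \code{folds}, \code{seed},
#' \code{out_dir}, and knn grid vectors \code{k}, \code{p}, \code{kernel}.
#'
#' @param config path to a YAML file or a named list.
#' @return Validated list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(sbp = NULL, kappa = 1000, alpha = 0.05, n_draws = 1e5,
                   cutoff = NULL, folds = 10, seed = 1, out_dir = ".",
                   k = c(5, 10, 15), p = c(2, 4), kernel = "optimal")
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$specimens)) stop("config must name a 'specimens' CSV")
  if (!file.exists(cfg$specimens)) stop("specimens file not found: ", cfg$specimens)
  if (!is.null(cfg$sbp) && !file.exists(cfg$sbp)) stop("SBP file not found: ", cfg$sbp)
  if (cfg$kappa <= 0 || cfg$alpha <= 0 || cfg$alpha >= 1 || cfg$n_draws < 1)
    stop("numeric config fields out of range")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the diagnosis pipeline end to end
#'
#' Reads the specimen table and balance design, computes ilr balances, fits
#' the knn diagnosis, derives TN/TP concentration ranges and critical
#' values, and writes five CSV outputs plus a YAML run manifest to
#' \code{out_dir}: \code{balances.csv}, \code{categories.csv},
#' \code{metrics.csv}, \code{ranges.csv}, \code{critical_values.csv},
#' \code{manifest.yaml}. Outputs are deterministic for a given
#' configuration. Boron is re-reported in mg kg^-1 in the ranges output.
#'
#' @param config a \code{\link{pipeline_config}}, a list, or a YAML path.
#' @return Invisibly, a list with the fitted \code{"cnd"}, the ranges, and
#'   the output paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  sbp <- stage("sbp", if (is.null(config$sbp)) sbp_guava() else read_sbp(config$sbp))
  spec <- stage("read", read_specimens(config$specimens, kappa = config$kappa))
  if (is.null(spec$yield)) stop("pipeline stage 'read' failed: specimens need a 'yield' column")
  basis <- ilr_basis(sbp)
  fit <- stage("diagnose",
    cnd(spec[, basis$parts], spec$yield, sbp = sbp, cutoff = config$cutoff,
        kappa = config$kappa,
        grid = knn_grid(config$k, config$p, config$kernel),
        folds = config$folds, seed = config$seed))
  rng <- stage("ranges",
    concentration_ranges(fit, alpha = config$alpha, n_draws = config$n_draws,
                         seed = config$seed))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(config$out_dir, f)
  wr <- function(df, f) { utils::write.csv(df, pth(f), row.names = FALSE); pth(f) }

  paths <- character()
  paths["balances"] <- wr(data.frame(id = spec$id, fit$balances, check.names = FALSE),
                          "balances.csv")
  paths["categories"] <- wr(data.frame(id = spec$id, yield = spec$yield,
                                       class = fit$classes, predicted = fit$predicted,
                                       category = fit$confusion$category),
                            "categories.csv")
  paths["metrics"] <- wr(data.frame(metric = c(names(fit$metrics), "cv_accuracy",
                                               "cutoff_Mg_ha", "k", "minkowski_p"),
                                    value = c(unname(fit$metrics), fit$cv_accuracy,
                                              fit$cutoff, fit$config$k, fit$config$p)),
                         "metrics.csv")
  rtab <- do.call(rbind, lapply(intersect(c("TN", "TP"), names(rng)), function(g) {
    r <- rng[[g]]
    unit <- ifelse(r$part == "B", "mg_kg", "g_kg")
    sc <- ifelse(unit == "mg_kg", 1000, 1)
    data.frame(group = g, part = r$part, unit = unit,
               min = r$min * sc, mean = r$mean * sc, max = r$max * sc)
  }))
  paths["ranges"] <- wr(rtab, "ranges.csv")
  crit <- rng$critical
  if (is.null(crit)) crit <- data.frame(part = character(), critical = numeric())
  else {
    sc <- ifelse(crit$part == "B", 1000, 1)
    crit$critical <- crit$critical * sc
    crit$unit <- ifelse(crit$part == "B", "mg_kg", "g_kg")
  }
  paths["critical"] <- wr(crit, "critical_values.csv")

  manifest <- list(package = "nutribal",
                   version = as.character(utils::packageVersion("nutribal")),
                   seed = config$seed, kappa = config$kappa,
                   alpha = config$alpha, n_draws = config$n_draws,
                   cutoff = fit$cutoff, folds = config$folds,
                   knn = list(k = fit$config$k, p = fit$config$p,
                              kernel = as.character(fit$config$kernel)),
                   n_specimens = nrow(spec),
                   outputs = as.list(paths))
  yaml::write_yaml(manifest, pth("manifest.yaml"))
  paths["manifest"] <- pth("manifest.yaml")
  invisible(list(fit = fit, ranges = rng, paths = paths))
}

#' Write the specimen table of a synthetic dataset to CSV
#'
#' Foliar and fruit compositions are written in the tidy layout read back by
#' \code{\link{read_specimens}} (boron in mg kg^-1).
#'
#' @param ds an \code{"orchard_dataset"}.
#' @param path output CSV.
#' @export
write_specimens <- function(ds, path) {
  sp <- ds$specimens
  parts <- ds$config$basis$parts
  out <- sp[, c("id", "plot", "block", "treatment", "source", "dose", "year", "yield")]
  comp <- as.matrix(sp[, parts])
  comp[, "B"] <- comp[, "B"] * 1000
  out[, parts] <- comp
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
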