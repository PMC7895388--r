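#' Write a region catalog to JSON and CSV
#'
#' The JSON catalog has one record per region: label, attracting-domain
#' set, symmetric/asymmetric attractor counts, component index, the
#' defining inequality strings of its cells (human-readable, in the
#' dimensionless symbol names), and a representative interior parameter
#' point. The CSV summary has one row per region. Both embed the catalog
#' configuration hash, so reruns with identical settings are byte
#' identical.
#'
#' @param catalog A [decompose_regions()] catalog.
#' @param path Output path (`.json`); the CSV summary replaces the
#'   extension.
#' @return Invisibly, the JSON path.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "region_catalog"))
  pcols <- c("mu", "gamma", "eta", "kappa", "pi", "epsilon", "theta1",
             "theta2")
  recs <- lapply(seq_len(nrow(catalog$regions)), function(i) {
    r <- catalog$regions[i, ]
    cells <- catalog$cells[catalog$cells$region == r$label, , drop = FALSE]
    list(label = r$label,
         attractors = as.integer(strsplit(r$attractors, ",")[[1]]),
         n_symmetric = r$n_symmetric, n_asymmetric = r$n_asymmetric,
         component = r$component,
         defining_cells = lapply(seq_len(nrow(cells)), function(k)
           cell_inequalities(catalog, cells$id[k])),
         representative = as.list(unlist(r[pcols])))
  })
  obj <- list(order = catalog$order,
              n_configurations = nrow(catalog$configurations),
              n_regions = nrow(catalog$regions),
              config_hash = config_hash(catalog$meta[c("pool_n", "pool_seed",
                                                       "log_range",
                                                       "slack_tol")]),
              regions = recs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  csv <- sub("\\.json$", ".csv", path)
  if (identical(csv, path)) csv <- paste0(path, ".csv")
  utils::write.csv(catalog$regions, csv, row.names = FALSE)
  invisible(path)
}

#' Defining inequalities of one catalog cell
#'
#' Expands a cell's zone vector into the strict inequalities between the
#' canonical rational functions and the rescaled thresholds.
#'
#' @param catalog A [decompose_regions()] catalog.
#' @param cell_id Cell id from `catalog$cells`.
#' @return Character vector of inequalities.
#' @export
cell_inequalities <- function(catalog, cell_id) {
  z <- zone_vector(cell_id)
  lo <- if (catalog$order == "theta2_lt_theta1") "theta2" else "theta1"
  hi <- if (catalog$order == "theta2_lt_theta1") "theta1" else "theta2"
  out <- character(0)
  for (k in 1:9) {
    qs <- q_string(q_names[k], catalog$order)
    out <- c(out, switch(z[k] + 1L,
                         sprintf("%s < mu*pi*%s", qs, lo),
                         c(sprintf("mu*pi*%s < %s", lo, qs),
                           sprintf("%s < mu*pi*%s", qs, hi)),
                         sprintf("mu*pi*%s < %s", hi, qs)))
  }
  out
}

#' Write distance statistics of a region graph as JSON
#'
#' @param stats Output of [distance_stats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_stats <- function(stats, path) {
  jsonlite::write_json(stats, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write a density report
#'
#' JSON report (label, exponents, box, seed, counts, proportion) plus a
#' CSV of the per-sample classifications.
#'
#' @param est A [density_study()] result.
#' @param path Output path (`.json`); per-sample CSV replaces the
#'   extension.
#' @return `path`, invisibly.
#' @export
write_density_report <- function(est, path) {
  stopifnot(inherits(est, "density_estimate"))
  obj <- est[c("label", "n_sampled", "n_evaluated", "n_failed", "counts",
               "n_asymmetric_only", "proportion", "exponents", "box",
               "seed")]
  obj$config_hash <- config_hash(obj[c("label", "exponents", "box",
                                       "seed", "n_sampled")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  csv <- sub("\\.json$", ".csv", path)
  if (identical(csv, path)) csv <- paste0(path, ".csv")
  utils::write.csv(est$samples, csv, row.names = FALSE)
  invisible(path)
}

#' Deterministic configuration hash
#'
#' Polynomial rolling hash (base 31, modulus 2^31 - 1, exact in double
#' precision) over the JSON serialization; used to stamp output artifacts
#' with the settings that produced them.
#'
#' @param x Any jsonlite-serializable object.
#' @return Hex string.
#' @export
config_hash <- function(x) {
  bytes <- utf8ToInt(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                                   digits = NA)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
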