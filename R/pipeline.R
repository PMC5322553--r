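#' Run the full association pipeline from one configuration
#'
#' Wires the stages end to end: obtain inputs (either simulated from a
#' `simulate:` block or read from files), optionally call presence from a
#' hit table, optionally remove near-duplicate tips, then fit the
#' phylogenetic GEE and/or the metagenomic frequency-iron correlation.
#' Every run can write a JSON result bundle plus a manifest (config
#' snapshot, input file checksums, package version, seed, timestamps)
#' sufficient to re-run the deterministic stages bit-identically.
#'
#' @param config A named list, or a path to a YAML/JSON config file.
#'   Recognized top-level keys:
#'   \describe{
#'     \item{`seed`}{integer; used for the simulator.}
#'     \item{`simulate`}{list of [sim_config()] arguments; mutually
#'       exclusive with `inputs`.}
#'     \item{`inputs`}{list of file paths: `tree`, `traits`, and optionally
#'       `hits` (+ `genome_status`), `distances`, `sites`.}
#'     \item{`call_presence`}{list: `evalue_threshold` (default 1e-5).}
#'     \item{`dedup`}{list: `divergence_threshold` (default 0.005); needs
#'       `inputs$distances`.}
#'     \item{`gee`}{list passed on: `covariate`, `correlation_mode`,
#'       `categorical`, `tol`, `max_iter`, `p_se`; set to `FALSE` to skip.}
#'     \item{`metafreq`}{list: `target`, `cores`, `blacklist`,
#'       `min_sites`; set to `FALSE` to skip.}
#'   }
#' @param output_dir Optional directory for `results.json`,
#'   `manifest.json` and stage TSV outputs.
#' @return List with elements `gee` (fit report), `metafreq` (per-taxon
#'   correlations and per-site frequencies), `n_tips_used`, `provenance`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- read_config(config)
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- inputs ---------------------------------------------------------
  sites <- NULL; distances <- NULL
  if (!is.null(config$simulate)) {
    ds <- stage("simulate", {
      args <- config$simulate
      args$seed <- args$seed %||% seed
      if (!is.null(args$env_rates)) args$env_rates <- as.matrix(args$env_rates)
      do.call(sim_config, args)
      simulate_dataset(do.call(sim_config, args))
    })
    tree <- ds$tree; traits <- ds$traits; sites <- ds$sites
  } else {
    inp <- config$inputs
    if (is.null(inp$tree) && is.null(inp$sites))
      stop("config must provide either a 'simulate' block or 'inputs'")
    tree <- traits <- NULL
    if (!is.null(inp$tree))
      tree <- stage("read_tree", read_newick(inp$tree))
    if (!is.null(inp$hits)) {
      hits <- stage("read_hits", {
        h <- read_hits(inp$hits)
        if (!is.null(inp$hit_organisms)) {
          map <- utils::read.delim(inp$hit_organisms,
                                   stringsAsFactors = FALSE)
          h$organism_id <- map$organism_id[match(h$subject_id,
                                                 map$subject_id)]
        }
        h
      })
      gs <- stage("read_genome_status", {
        g <- utils::read.delim(inp$genome_status, stringsAsFactors = FALSE)
        stats::setNames(as.logical(g$genome_complete), g$organism_id)
      })
      thr <- (config$call_presence %||% list())$evalue_threshold %||% 1e-5
      traits <- stage("call_presence", call_presence(hits, gs, thr))
      if (!is.null(inp$environment)) {
        env <- utils::read.delim(inp$environment, stringsAsFactors = FALSE)
        i <- match(traits$organism_id, env$organism_id)
        traits$habitat <- env$habitat[i]
        traits$iron_level <- as.integer(env$iron_level[i])
      }
    } else if (!is.null(inp$traits)) {
      traits <- stage("read_traits", read_trait_table(inp$traits))
    }
    if (!is.null(inp$distances))
      distances <- stage("read_distances", read_matrix_tsv(inp$distances))
    if (!is.null(inp$sites))
      sites <- stage("read_sites", read_site_table(inp$sites))
  }

  results <- list()
  # --- dedup ----------------------------------------------------------
  if (!is.null(config$dedup) && !isFALSE(config$dedup) &&
      !is.null(distances)) {
    thr <- config$dedup$divergence_threshold %||% 0.005
    traits <- stage("dedup", dedup_tips(distances, traits, thr))
    results$dedup <- attr(traits, "provenance")$dedup
  }

  # --- gee ------------------------------------------------------------
  if (!isFALSE(config$gee) && !is.null(tree) && !is.null(traits)) {
    g <- config$gee %||% list()
    fit <- stage("gee", {
      des <- gee_design(tree, traits,
                        covariate = g$covariate %||% "iron_level",
                        correlation_mode = g$correlation_mode %||%
                          "correlation",
                        categorical = isTRUE(g$categorical))
      fit_gee(des, max_iter = g$max_iter %||% 100L,
              tol = g$tol %||% 1e-8, p_se = g$p_se %||% "naive")
    })
    results$gee <- jsonlite::fromJSON(gee_report_json(fit))
    results$n_tips_used <- fit$n
    results$gee_fit <- fit
  }

  # --- metafreq -------------------------------------------------------
  if (!isFALSE(config$metafreq) && !is.null(sites)) {
    m <- config$metafreq %||% list()
    mf <- stage("metafreq", {
      prof <- gene_frequency(sites, target = m$target %||% "fld",
                             cores = m$cores %||%
                               c("recA", "rpoB", "gyrB", "psbO"),
                             blacklist = m$blacklist)
      list(profiles = prof,
           correlation = site_correlation(prof,
                                          min_sites = m$min_sites %||% 3L))
    })
    results$metafreq <- list(
      correlation = mf$correlation,
      n_excluded = attr(mf$profiles, "n_excluded"))
    results$metafreq_profiles <- mf$profiles
  }

  results$provenance <- list(seed = seed,
                             version = as.character(
                               utils::packageVersion("phylogee")))

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    ser <- results[setdiff(names(results),
                           c("gee_fit", "metafreq_profiles"))]
    jsonlite::write_json(ser, file.path(output_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    if (!is.null(results$metafreq_profiles))
      utils::write.table(as.data.frame(results$metafreq_profiles),
                         file.path(output_dir, "frequencies.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(config, seed, output_dir)
  }
  results
}

read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path)) jsonlite::fromJSON(path,
                                                  simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

write_manifest <- function(config, seed, output_dir) {
  files <- unlist((config$inputs %||% list()), use.names = TRUE)
  hashes <- if (length(files))
    as.list(tools::md5sum(files[file.exists(files)])) else list()
  manifest <- list(command = "run_pipeline",
                   config = config,
                   input_md5 = hashes,
                   seed = seed,
                   version = as.character(
                     utils::packageVersion("phylogee")),
                   r_version = as.character(getRversion()),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      usetz = TRUE))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
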