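#' Read and validate a pipeline configuration
#'
#' Configurations are YAML with a small, closed schema; unknown keys are
#' rejected before any stage runs so that typos fail fast instead of
#' silently falling back to defaults.
#'
#' Top-level keys: `seed` (integer), `stages` (character vector from
#' `simulate_sites`, `purity_mle`, `simulate_segments`, `purity_amplicon`),
#' `sim` (a block of [sim_config()] parameters), `mle` (block with
#' `grid_step`, `depth_min`, `cap_multiplier`, `cap_mode`), `amplicon`
#' (block with `min_depth`, `human_fraction`), and optional file inputs
#' `sites_tsv` / `segments_tsv` used instead of simulation.
#'
#' @param path YAML file path, or a list already parsed.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  allowed <- c("seed", "stages", "sim", "mle", "amplicon",
               "sites_tsv", "segments_tsv")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$stages <- cfg$stages %||% c("simulate_sites", "purity_mle")
  known_stages <- c("simulate_sites", "purity_mle",
                    "simulate_segments", "purity_amplicon")
  bad <- setdiff(cfg$stages, known_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  check_block <- function(block, allowed_keys, label) {
    extra <- setdiff(names(block), allowed_keys)
    if (length(extra)) {
      stop("unknown key(s) in '", label, "' block: ",
           paste(extra, collapse = ", "))
    }
    block
  }
  cfg$sim <- check_block(cfg$sim %||% list(),
                         names(formals(sim_config)), "sim")
  cfg$mle <- check_block(cfg$mle %||% list(),
                         c("grid_step", "depth_min", "cap_multiplier",
                           "cap_mode"), "mle")
  cfg$amplicon <- check_block(cfg$amplicon %||% list(),
                              c("min_depth", "human_fraction"), "amplicon")
  structure(cfg, class = "pipeline_config")
}

#' Run a configured purity-estimation pipeline
#'
#' Executes the requested stages in dependency order (simulation before
#' estimation) and returns a report bundle embedding the configuration,
#' seed, and package version, so that any report is reproducible from its
#' own metadata. A stage failure aborts with the stage name in the message.
#'
#' @param cfg A [read_pipeline_config()] object, a config list, or a YAML
#'   path.
#' @param out Optional path; when given, the report is also written as
#'   JSON.
#' @return The report list (invisibly when `out` is given).
#' @export
run_pipeline <- function(cfg, out = NULL) {
  if (!inherits(cfg, "pipeline_config")) cfg <- read_pipeline_config(cfg)
  report <- list(
    package = "xenopurity",
    version = as.character(packageVersion("xenopurity")),
    seed = cfg$seed,
    config = unclass(cfg),
    stages = list()
  )
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    report$stages[[name]] <<- res
  }
  sim_cfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))

  for (stage in intersect(c("simulate_sites", "simulate_segments",
                            "purity_mle", "purity_amplicon"), cfg$stages)) {
    switch(stage,
      simulate_sites = run_stage(stage, function() {
        sim <- gen_syngeneic_sites(sim_cfg)
        state$sites <- sim$sites
        list(n_sites = nrow(sim$sites), theta_true = sim$theta_true)
      }),
      simulate_segments = run_stage(stage, function() {
        f <- cfg$amplicon$human_fraction %||% 0.9
        sim <- gen_segment_counts(sim_cfg, human_fraction = f)
        state$segments <- sim$segments
        list(n_segments = nrow(sim$segments),
             human_fraction_true = sim$human_fraction_true)
      }),
      purity_mle = run_stage(stage, function() {
        sites <- state$sites %||% read_variant_sites(cfg$sites_tsv)
        pp <- preprocess_sites(
          sites,
          depth_min = cfg$mle$depth_min %||% 20,
          cap_multiplier = cfg$mle$cap_multiplier %||% 5,
          cap_mode = cfg$mle$cap_mode %||% "rescale"
        )
        est <- estimate_purity(pp, grid_step = cfg$mle$grid_step %||% 0.001)
        list(theta_hat = est$theta_hat,
             n_sites_used = est$n_sites_used,
             n_sites_capped = est$n_sites_capped)
      }),
      purity_amplicon = run_stage(stage, function() {
        segs <- state$segments %||% read_segment_counts(cfg$segments_tsv)
        res <- assay_purity(segs, min_depth = cfg$amplicon$min_depth %||% 100)
        list(purity = res$purity, n_used = res$n_used,
             n_excluded = res$n_excluded)
      })
    )
  }
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}

read_variant_sites <- function(path) {
  if (is.null(path)) stop("no simulated sites and no sites_tsv input")
  x <- read.delim(path, na.strings = ".", stringsAsFactors = FALSE)
  need <- c("genotype_class", "n_H", "n_T")
  if (!all(need %in% names(x))) {
    stop("sites TSV requires columns: ", paste(need, collapse = ", "))
  }
  x
}
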