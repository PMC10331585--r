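#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end demo funnel, with the defaults
#' used throughout the package. Unknown keys are rejected, so configs read
#' from file fail loudly on typos.
#'
#' @param n_drugs compounds in the simulated library (default 100).
#' @param rescue_index indices of the designed true-rescue drugs
#'   (default 1:5).
#' @param rescue_strength rescue effect of the designed drugs (default 1).
#' @param toxicity_prob per-fish death probability for every drug.
#' @param wt_distance_median_m,wt_distance_cv,mo_zero_fraction,
#'   mo_mover_reduction cohort model, see [cohort_params()].
#' @param replicate_count larvae per drug.
#' @param mean_z_threshold,fish_z_threshold,toxic_dead_min behavioral
#'   classification, see [classify_drug()].
#' @param npa_cutoff,npa_variant rescreen scoring, see [rescreen_npa()].
#' @param confidence_cutoff,recurrence_cutoff network filter, see
#'   [build_drug_target_graph()] and [select_hits()].
#' @param unknown_fraction,edge_density,n_targets synthetic annotation
#'   tables, see [network_params()].
#' @param n_embryos_per_drug,n_control_embryos imaging cohort sizes.
#' @param image_shape image frame `c(height, width)` in px. The demo images
#'   default to a coarser pixel grid (1.5 um/px, 150 x 270 px) than the
#'   imaging module's 1 um/px default purely to keep multi-seed runs fast;
#'   the physical geometry (cord band 44 um, WT axons ~110 um) is unchanged.
#' @param image_pixel_size_um demo pixel size (default 1.5).
#' @param cord_top_px,cord_thickness_px cord band geometry in demo pixels.
#' @param image_noise_sd rendering noise sd.
#' @param cellular_z_threshold rescue threshold, see [rescue_call()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_drugs = 100,
                            rescue_index = 1:5,
                            rescue_strength = 1,
                            toxicity_prob = 0,
                            wt_distance_median_m = 1.0,
                            wt_distance_cv = 0.25,
                            mo_zero_fraction = 0.792,
                            mo_mover_reduction = 0.85,
                            replicate_count = 4,
                            mean_z_threshold = 0,
                            fish_z_threshold = -1,
                            toxic_dead_min = 3,
                            npa_cutoff = 50,
                            npa_variant = "standard",
                            confidence_cutoff = 0.7,
                            recurrence_cutoff = 3,
                            unknown_fraction = 0.25,
                            edge_density = 0.1,
                            n_targets = 20,
                            n_embryos_per_drug = 4,
                            n_control_embryos = 8,
                            image_shape = c(150, 270),
                            image_pixel_size_um = 1.5,
                            cord_top_px = 20,
                            cord_thickness_px = 29,
                            image_noise_sd = 150,
                            cellular_z_threshold = -1) {
  stopifnot(n_drugs >= 0, all(rescue_index >= 1),
            all(rescue_index <= max(n_drugs, 1)),
            rescue_strength >= 0, rescue_strength <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from JSON (or YAML)
#'
#' JSON is the native config format. A `.yaml`/`.yml` file is accepted when
#' the optional \pkg{yaml} package is installed. Unknown keys are rejected
#' by [pipeline_config()].
#'
#' @param path config file path.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stage_error("cli", "YAML config requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown) > 0) {
    stage_error("cli", paste0("unknown config key(s): ",
                              paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

# per-drug rescue-strength vector of a configured cohort
design_effects <- function(config) {
  e <- rep(0, config$n_drugs)
  e[config$rescue_index] <- config$rescue_strength
  e
}

#' Run the full screening funnel on synthetic data
#'
#' Executes the complete pipeline: simulate the primary screen, score and
#' classify it, rescreen the hits on an independently seeded disease model
#' and filter by mean NPA, build synthetic drug-target tables for the
#' rescreen hits and apply the recurrence filter, render NMJ images for the
#' favorite and unknown hits (each drug's cellular phenotype follows its
#' designed rescue strength) alongside WT and morphant control embryos,
#' quantify them, and call the final hits on the cellular z-scores. Fully
#' deterministic for a given `seed`.
#'
#' In the demo's annotation design, all annotated rescreen hits share one
#' highly recurrent target (the hits converge on a common receptor), so the
#' favorite/unknown split is controlled by `unknown_fraction` alone.
#'
#' @param config a [pipeline_config()].
#' @param seed master integer seed.
#' @return a `demo_bundle` list: `funnel` (named stage counts),
#'   `design` (designed rescue drug ids), `screen`, `rescreen`, `network`,
#'   `metrics`, `cellular`, `final_hits`, and `seed`.
#' @export
run_demo <- function(config = pipeline_config(), seed = 1) {
  stopifnot(inherits(config, "pipeline_config"))
  effects <- design_effects(config)
  ids <- sprintf("D%04d", seq_len(config$n_drugs))
  design_ids <- ids[config$rescue_index]

  params <- cohort_params(
    n_drugs = config$n_drugs,
    wt_distance_median_m = config$wt_distance_median_m,
    wt_distance_cv = config$wt_distance_cv,
    mo_zero_fraction = config$mo_zero_fraction,
    mo_mover_reduction = config$mo_mover_reduction,
    rescue_strength = effects,
    toxicity_prob = config$toxicity_prob,
    replicate_count = config$replicate_count,
    seed = derive_seed(seed, "demo-screen"))
  tab <- simulate_screen(params)
  scr <- screen_scores(tab, mean_z_threshold = config$mean_z_threshold,
                       fish_z_threshold = config$fish_z_threshold,
                       toxic_dead_min = config$toxic_dead_min)
  hits <- screen_hits(scr)

  empty_bundle <- function(rescreen = NULL, network = NULL, metrics = NULL,
                           cellular = NULL, funnel_extra = c()) {
    funnel <- c(drugs = config$n_drugs, screen_hits = length(hits),
                funnel_extra,
                final_hits = 0L)
    structure(list(funnel = funnel, design = design_ids, screen = scr,
                   rescreen = rescreen, network = network,
                   metrics = metrics, cellular = cellular,
                   final_hits = character(0), seed = seed),
              class = "demo_bundle")
  }
  if (length(hits) == 0) {
    return(empty_bundle(funnel_extra = c(rescreen_hits = 0L,
                                         favorite_hits = 0L,
                                         unknown_hits = 0L, imaged = 0L)))
  }

  retab <- simulate_rescreen(params, hits)
  res <- rescreen_npa(retab, cutoff = config$npa_cutoff,
                      variant = config$npa_variant)
  rescreen_hits <- res$drug_id[res$pass]
  if (length(rescreen_hits) == 0) {
    return(empty_bundle(rescreen = res,
                        funnel_extra = c(rescreen_hits = 0L,
                                         favorite_hits = 0L,
                                         unknown_hits = 0L, imaged = 0L)))
  }

  n_unknown <- floor(config$unknown_fraction * length(rescreen_hits))
  n_known <- length(rescreen_hits) - n_unknown
  spec <- if (n_known > 0) c(ACHR1 = n_known) else integer(0)
  np <- network_params(
    n_hit_drugs = length(rescreen_hits), n_targets = config$n_targets,
    recurrent_target_spec = spec,
    unknown_fraction = config$unknown_fraction,
    edge_density = config$edge_density,
    seed = derive_seed(seed, "demo-network"))
  tables <- simulate_drug_target_tables(np, drug_ids = rescreen_hits)
  graph <- build_drug_target_graph(tables$pairs, tables$edges,
                                   rescreen_hits,
                                   config$confidence_cutoff)
  report <- select_hits(graph, recurrence_cutoff = config$recurrence_cutoff)
  network <- list(tables = tables, graph = graph, report = report)
  proceed <- sort(union(report$favorite_hits, report$unknown_hits))
  if (length(proceed) == 0) {
    return(empty_bundle(rescreen = res, network = network,
                        funnel_extra = c(
                          rescreen_hits = length(rescreen_hits),
                          favorite_hits = 0L, unknown_hits = 0L,
                          imaged = 0L)))
  }

  make_images <- function(label, group, drug_id, effect, n) {
    lapply(seq_len(n), function(k) {
      truth <- phenotype_truth(
        effect, seed = derive_seed(seed, paste0("demo-image-", label, k)),
        shape = config$image_shape,
        pixel_size_um = config$image_pixel_size_um,
        cord_top = config$cord_top_px,
        cord_thickness = config$cord_thickness_px,
        noise_sd = config$image_noise_sd)
      simulate_nmj_image(truth, embryo_id = paste0(label, "-", k),
                         group = group, drug_id = drug_id)$image
    })
  }
  images <- c(
    make_images("wt", "WT_CONTROL", NULL, 1, config$n_control_embryos),
    make_images("mo", "MO_CONTROL", NULL, 0, config$n_control_embryos),
    unlist(lapply(proceed, function(d) {
      make_images(d, "TREATED", d, effects[match(d, ids)],
                  config$n_embryos_per_drug)
    }), recursive = FALSE))
  metrics <- quantify_batch(images)
  cellular <- cellular_scores(metrics,
                              z_threshold = config$cellular_z_threshold)
  final_hits <- sort(cellular$drug_id[cellular$final_hit])

  funnel <- c(drugs = config$n_drugs,
              screen_hits = length(hits),
              rescreen_hits = length(rescreen_hits),
              favorite_hits = length(report$favorite_hits),
              unknown_hits = length(report$unknown_hits),
              imaged = length(proceed),
              final_hits = length(final_hits))
  structure(list(funnel = funnel, design = design_ids, screen = scr,
                 rescreen = res, network = network, metrics = metrics,
                 cellular = cellular, final_hits = final_hits, seed = seed),
            class = "demo_bundle")
}

#' @export
print.demo_bundle <- function(x, ...) {
  cat("demo_bundle (seed ", x$seed, ")\n", sep = "")
  cat("  funnel:", paste(sprintf("%s=%d", names(x$funnel), x$funnel),
                         collapse = " -> "), "\n")
  cat("  final hits:", if (length(x$final_hits) == 0) "(none)"
      else paste(x$final_hits, collapse = ", "), "\n")
  invisible(x)
}

#' Write a demo bundle to disk
#'
#' Emits `funnel.json` (stage counts, design, final hits) and CSV tables for
#' the screen scores, rescreen NPA results, per-embryo metrics and cellular
#' scores under `dir`.
#'
#' @param bundle a `demo_bundle` from [run_demo()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_demo_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "demo_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(funnel = file.path(dir, "funnel.json"))
  jsonlite::write_json(
    list(seed = bundle$seed, funnel = as.list(bundle$funnel),
         design = bundle$design, final_hits = bundle$final_hits),
    paths[["funnel"]], auto_unbox = TRUE, digits = NA)
  tabs <- list(screen_scores = bundle$screen$per_drug,
               plate_quality = bundle$screen$plate_quality,
               rescreen = bundle$rescreen,
               metrics = bundle$metrics,
               cellular_scores = bundle$cellular)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) next
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(tabs[[nm]], p, row.names = FALSE, quote = FALSE)
    paths[[nm]] <- p
  }
  invisible(paths)
}
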