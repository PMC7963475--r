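# End-to-end orchestration: simulate -> bin -> network -> domains ->
# bootstrap -> regions -> signal, behind a single validated configuration,
# with per-stage seeds derived from one master seed and a checksum manifest.

#' Configure a full pipeline run
#'
#' All stage parameters in one validated object. Per-stage seeds are
#' derived from the master seed by a fixed counter scheme
#' (`stage_seed = master_seed + 1000 * stage_index`), so any stage can be
#' reproduced in isolation.
#'
#' @param world A [world_config()] (synthetic input mode), or `NULL` when
#'   `presence`, `coarse` are supplied directly to [run_pipeline()].
#' @param archetypes List of [archetype_spec()] objects (synthetic mode).
#' @param restriction_rho Geographic restriction fraction in (0, 1]; 1
#'   disables restriction.
#' @param d Fixed division count, or `NULL` to select via `d_candidates`.
#' @param d_candidates Candidate divisions for [select_divisions()].
#' @param min_range_cells Range-size filter threshold.
#' @param n_runs Restarts for the main domain search.
#' @param n_runs_boot Restarts per bootstrap network.
#' @param B Number of bootstrap networks.
#' @param jaccard_threshold Domain-matching threshold for support.
#' @param min_species Major-domain species threshold.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(world = world_config(),
                       archetypes = default_archetypes(),
                       restriction_rho = 1,
                       d = 12L, d_candidates = 5:30,
                       min_range_cells = 5L,
                       n_runs = 1000L, n_runs_boot = 100L, B = 100L,
                       jaccard_threshold = 0.5, min_species = 50L,
                       seed = 1L) {
  if (!(restriction_rho > 0 && restriction_rho <= 1)) {
    stop_config("restriction_rho must be in (0, 1]")
  }
  structure(list(
    world = world, archetypes = archetypes,
    restriction_rho = restriction_rho,
    d = d, d_candidates = d_candidates,
    min_range_cells = as.integer(min_range_cells),
    n_runs = as.integer(n_runs), n_runs_boot = as.integer(n_runs_boot),
    B = as.integer(B),
    jaccard_threshold = jaccard_threshold,
    min_species = as.integer(min_species),
    seed = as.integer(seed)
  ), class = "run_config")
}

stage_seed <- function(config, k) config$seed + 1000L * k

#' Default planted archetypes
#'
#' Four well-separated climate archetypes near the corners of the default
#' climate space (two energy levels crossed with two water levels), 60
#' species each: the canonical recoverable ground truth for validation
#' runs.
#'
#' @param breadth Kernel standard deviation, as a fraction of each axis
#'   range (default 0.06).
#' @param n_species Species per archetype.
#' @param occupancy_rho Fraction of suitable cells occupied per species.
#' @param energy_range,water_range Axis ranges the centres are placed in.
#' @return List of four [archetype_spec()] objects.
#' @export
default_archetypes <- function(breadth = 0.06, n_species = 60L,
                               occupancy_rho = 0.6,
                               energy_range = c(0, 2000),
                               water_range = c(0, 3000)) {
  es <- energy_range[1] + c(0.25, 0.75) * diff(energy_range)
  ws <- water_range[1] + c(0.25, 0.75) * diff(water_range)
  b <- breadth * c(diff(energy_range), diff(water_range))
  list(
    archetype_spec(c(es[1], ws[1]), b, n_species, occupancy_rho),
    archetype_spec(c(es[1], ws[2]), b, n_species, occupancy_rho),
    archetype_spec(c(es[2], ws[1]), b, n_species, occupancy_rho),
    archetype_spec(c(es[2], ws[2]), b, n_species, occupancy_rho)
  )
}

#' Run the full niche-domain pipeline
#'
#' Executes all stages in order on a synthetic world (or supplied inputs),
#' optionally writing every artifact class to `out_dir`: climate rasters,
#' presence, bin edges, profiles, the Pajek network, the partition, the
#' support table, the region map, and the signal report. When `out_dir` is
#' given, a `manifest.csv` with MD5 checksums of every artifact is written;
#' deterministic stages reproduce identical checksums under an identical
#' config.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param presence,coarse Optional pre-built inputs (raster + presence
#'   mode); when supplied the synthetic stage is skipped.
#' @param verbose Print stage summaries?
#' @return A list with every intermediate and final object plus the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL, presence = NULL,
                         coarse = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(...)
  t0 <- Sys.time()
  artifacts <- character(0)
  emit <- function(path) artifacts <<- c(artifacts, path)

  world <- NULL
  planted <- NULL
  if (is.null(presence) || is.null(coarse)) {
    world <- generate_climate_world(config$world)
    coarse <- aggregate_world(world)
    pool <- generate_species_pool(world, config$archetypes,
                                  min_range_cells = config$min_range_cells,
                                  seed = stage_seed(config, 1L))
    presence <- pool$presence
    planted <- pool$planted_labels
    if (config$restriction_rho < 1) {
      presence <- apply_geographic_restriction(
        presence, config$restriction_rho, coarse$land,
        min_range_cells = config$min_range_cells,
        seed = stage_seed(config, 2L))
      planted <- planted[names(presence$cells)]
    }
    say("simulate: ", n_species(presence), " species on ",
        sum(coarse$land), " coarse land cells")
  }

  presence <- filter_small_ranges(presence, config$min_range_cells)
  say("filter: ", n_species(presence), " species kept (removed ",
      nrow(attr(presence, "removed")), ")")

  if (is.null(config$d)) {
    sel <- select_divisions(presence, coarse,
                            d_candidates = config$d_candidates,
                            seed = stage_seed(config, 3L))
    d <- sel$d_star
    say("divisions: d* = ", d)
  } else {
    sel <- NULL
    d <- config$d
  }
  grid <- bin_grid(coarse, d)
  assignment <- assign_bins(coarse, grid)
  say("bin: ", grid$d_e, " x ", grid$d_w, " effective divisions, ",
      nrow(assignment$bins), " occupied bins")

  profiles <- niche_profiles(presence, assignment)
  network <- build_network(profiles)
  say("network: ", nrow(network$bins), " bins, ", length(network$species),
      " species, W = ", format(network$W))

  partition <- detect_domains(network, n_runs = config$n_runs,
                              seed = stage_seed(config, 4L))
  say("domains: ", max(partition$module), " finest domains, L = ",
      format(partition$codelength, digits = 6), " bits")

  support <- NULL
  boot_parts <- NULL
  if (config$B > 0L) {
    boots <- bootstrap_networks(presence, coarse, assignment, B = config$B,
                                seed = stage_seed(config, 5L))
    boot_parts <- lapply(seq_along(boots), function(b) {
      detect_domains(boots[[b]], n_runs = config$n_runs_boot,
                     seed = stage_seed(config, 5L) + b,
                     hierarchical = FALSE)
    })
    support <- domain_support(partition, boot_parts,
                              jaccard_threshold = config$jaccard_threshold)
    say("bootstrap: support quantiles ",
        paste(format(stats::quantile(support$support), digits = 2),
              collapse = " "))
  }

  regions <- region_map(assignment, partition)
  spec <- bin_specificity(network, partition)
  s_p <- project_specificity(assignment, spec)
  s_a <- actual_specificity(network, partition, presence, assignment)
  signal <- geographical_signal(s_a, s_p)
  say("signal: G = ", format(signal$G, digits = 4), " over ",
      signal$n_cells_used, " cells")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    if (!is.null(world)) {
      emit(write_ascii_grid(world$energy_fine, p("energy_fine.asc")))
      emit(write_ascii_grid(world$water_fine, p("water_fine.asc")))
      utils::write.csv(data.frame(species_id = names(planted),
                                  archetype = unname(planted)),
                       p("planted_labels.csv"), row.names = FALSE)
      emit(p("planted_labels.csv"))
    }
    emit(write_presence_csv(presence, p("presence.csv")))
    emit(write_edges_csv(grid, p("bin_edges.csv")))
    emit(write_profiles_csv(profiles, p("profiles.csv")))
    emit(write_pajek(network, p("network.net")))
    write_partition(partition, p("partition.csv"), p("partition.json"))
    emit(p("partition.csv")); emit(p("partition.json"))
    if (!is.null(support)) {
      utils::write.csv(support, p("support.csv"), row.names = FALSE)
      emit(p("support.csv"))
    }
    emit(write_ascii_grid(regions$labels, p("region_map.asc")))
    emit(write_ascii_grid(s_p, p("specificity_projected.asc")))
    emit(write_ascii_grid(s_a, p("specificity_actual.asc")))
    summ <- domain_summary(partition, regions, s_p, support)
    utils::write.csv(summ, p("domain_summary.csv"), row.names = FALSE)
    emit(p("domain_summary.csv"))
    jsonlite::write_json(list(G = signal$G,
                              n_cells_used = signal$n_cells_used,
                              n_cells_excluded = signal$n_cells_excluded),
                         p("signal.json"), auto_unbox = TRUE, digits = NA)
    emit(p("signal.json"))
    # effective config echoed with the seed, plus software version
    cfg_echo <- unclass(config)
    cfg_echo$world <- if (!is.null(config$world)) unclass(config$world)
    cfg_echo$archetypes <- lapply(config$archetypes, unclass)
    jsonlite::write_json(
      list(package_version = as.character(utils::packageVersion("nichedomains")),
           config = cfg_echo),
      p("config.json"), auto_unbox = TRUE, digits = NA)
    emit(p("config.json"))
    manifest <- data.frame(
      file = basename(artifacts),
      md5 = unname(tools::md5sum(artifacts)),
      stringsAsFactors = FALSE
    )
    utils::write.csv(manifest, p("manifest.csv"), row.names = FALSE)
  } else {
    manifest <- NULL
  }

  say("done in ", format(round(difftime(Sys.time(), t0, units = "secs"), 1)))
  list(
    world = world, coarse = coarse, presence = presence,
    planted_labels = planted, selection = sel, grid = grid,
    assignment = assignment, profiles = profiles, network = network,
    partition = partition, support = support,
    bootstrap_partitions = boot_parts, regions = regions,
    bin_spec = spec, S_P = s_p, S_A = s_a, signal = signal,
    manifest = manifest, config = config
  )
}
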