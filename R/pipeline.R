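## End-to-end pipeline: simulate (or read) -> extract -> trim -> occupancy /
## distributions / flexibility / network, with deterministic TSV/JSON outputs
## and a provenance manifest.

#' Build and validate a pipeline configuration
#'
#' A configuration names either input trajectory files or synthetic-generator
#' parameters (exactly one of the two), plus the per-stage settings.  It can
#' be given as a nested list or as a YAML file path.  Any omitted stage
#' setting falls back to its documented default.
#'
#' @param config nested list or path to a YAML file.  Recognised top-level
#'   fields: \code{input} (list with \code{paths}, \code{frame_interval},
#'   \code{site_fefe_a}, \code{site_fefe_b}, \code{site_femg_a},
#'   \code{site_femg_b}), \code{generator} (list with \code{switching} and
#'   optionally \code{planted_network} parameter lists), \code{trim_ns},
#'   \code{occupancy} (\code{c_min}, \code{c_max}, \code{c_step},
#'   \code{d_min}, \code{d_max}, \code{d_step}, \code{c_report}),
#'   \code{distributions} (\code{bin_width}, \code{bandwidth},
#'   \code{min_prominence}), \code{network} (\code{contact_cutoff},
#'   \code{occupancy}, \code{source}, \code{sink}), \code{outdir},
#'   \code{seed}.
#' @return a validated list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    trim_ns = 0,
    occupancy = list(c_min = 0.67, c_max = 1.0, c_step = 0.01,
                     d_min = 1.5, d_max = 4.5, d_step = 0.01,
                     c_report = c(1.0, 0.9, 0.8), min_prominence = 0.02),
    distributions = list(bin_width = 0.05, bandwidth = "auto",
                         min_prominence = 0.05),
    network = list(contact_cutoff = 0.5, occupancy = 0.75),
    outdir = tempfile("corrshuttle_run_"),
    seed = 1L)
  cfg <- utils::modifyList(defaults, config)
  has_input <- !is.null(cfg$input)
  has_gen <- !is.null(cfg$generator)
  if (has_input == has_gen)
    stop("validation error: exactly one of 'input' and 'generator' must be given")
  if (!has_gen && is.null(cfg$input$paths))
    stop("validation error: 'input$paths' is required")
  oc <- cfg$occupancy
  if (oc$c_min <= 0 || oc$c_max > 1 || oc$c_min > oc$c_max ||
      oc$c_step <= 0 || oc$d_min <= 0 || oc$d_min >= oc$d_max ||
      oc$d_step <= 0)
    stop("validation error: bad occupancy grid")
  class(cfg) <- "pipeline_config"
  cfg
}

## canonical YAML serialisation used for hashing and provenance; the output
## directory is location metadata, not an analysis setting, so it is excluded
## and two runs of one configuration hash identically wherever they land
config_yaml <- function(cfg) {
  x <- unclass(cfg)
  x$outdir <- NULL
  x <- x[order(names(x))]
  yaml::as.yaml(x, precision = 15L)
}

#' Run the analysis pipeline
#'
#' Executes simulate/read, extract, trim, occupancy, distributions,
#' flexibility and network stages as configured, writes all numeric outputs
#' as TSV/JSON under \code{cfg$outdir}, and records a run manifest with the
#' seed and a hash of the canonical configuration.  Identical configurations
#' and seeds give bit-identical numeric outputs and manifests.
#'
#' @param config a \code{\link{pipeline_config}} (or list/path coercible to
#'   one).
#' @param quiet suppress progress messages.
#' @return a list of class \code{"pipeline_bundle"} holding every stage
#'   result plus \code{files} (named output paths) and \code{manifest}.
#' @export
run_pipeline <- function(config = list(generator = list(switching = list())),
                         quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config
  else pipeline_config(config)
  say <- function(...) if (!quiet)
    message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "), sprintf(...))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  bundle <- list(config = cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  ## -- data stage: synthesize or read -------------------------------------
  if (!is.null(cfg$generator)) {
    say("stage simulate: two-state switching distances (seed %d)", cfg$seed)
    sw <- cfg$generator$switching
    sw$seed <- if (is.null(sw$seed)) cfg$seed else sw$seed
    sp <- stage("simulate", do.call(switching_params, sw))
    sim <- simulate_switching_distances(sp)
    ens <- embed_distances_as_trajectory(sim)
    fefe_raw <- sim$fefe
    femg_raw <- sim$femg
    bundle$simulation <- sim
  } else {
    say("stage read: %d trajectory file(s)", length(cfg$input$paths))
    ens <- stage("read", read_ensemble(
      cfg$input$paths,
      frame_interval = if (is.null(cfg$input$frame_interval)) 1
      else cfg$input$frame_interval,
      chain_map = cfg$input$chain_map))
    fefe_raw <- femg_raw <- NULL
  }

  ## -- trim + extract -------------------------------------------------------
  say("stage trim: discarding first %g ns", cfg$trim_ns)
  ens <- stage("trim", if (cfg$trim_ns > 0)
    trim_equilibration(ens, cfg$trim_ns) else ens)
  sel <- cfg$input
  fefe_sel_a <- if (!is.null(sel$site_fefe_a)) sel$site_fefe_a else
    "PscC_distant:1:FE"
  fefe_sel_b <- if (!is.null(sel$site_fefe_b)) sel$site_fefe_b else
    "PscC_docked:1:FE"
  femg_sel_a <- if (!is.null(sel$site_femg_a)) sel$site_femg_a else
    "PscC_docked:1:FE"
  femg_sel_b <- if (!is.null(sel$site_femg_b)) sel$site_femg_b else
    "PscA:840:MG"
  say("stage extract: Fe-Fe and Fe-Mg distance series")
  fefe_list <- stage("extract", extract_distance(ens, fefe_sel_a, fefe_sel_b))
  femg_list <- stage("extract", extract_distance(ens, femg_sel_a, femg_sel_b))
  fefe <- concatenate_series(fefe_list)
  femg <- concatenate_series(femg_list)
  files["series"] <- file.path(cfg$outdir, "distances.tsv")
  write_series_tsv(list(fefe, femg), files["series"])
  bundle$fefe <- fefe
  bundle$femg <- femg

  ## -- occupancy ------------------------------------------------------------
  oc <- cfg$occupancy
  say("stage occupancy: C %g..%g, d %g..%g nm", oc$c_min, oc$c_max,
      oc$d_min, oc$d_max)
  scan <- stage("occupancy", occupancy_scan(
    fefe, femg, C = seq(oc$c_min, oc$c_max, by = oc$c_step),
    d_grid = seq(oc$d_min, oc$d_max, by = oc$d_step)))
  files["occupancy"] <- file.path(cfg$outdir, "occupancy_curves.tsv")
  write_occupancy_tsv(scan, files["occupancy"])
  pt <- peak_table(scan, C_subset = oc$c_report,
                   min_prominence = oc$min_prominence)
  files["peaks"] <- file.path(cfg$outdir, "occupancy_peaks.tsv")
  utils::write.table(pt, files["peaks"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cloud <- project_frames(fefe, femg)
  files["projection"] <- file.path(cfg$outdir, "projection.tsv")
  utils::write.table(cloud, files["projection"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bundle$occupancy <- scan
  bundle$peak_table <- pt
  bundle$projection <- cloud

  ## -- distributions --------------------------------------------------------
  dc <- cfg$distributions
  say("stage distributions: histogram/KDE summaries + modes")
  sum_fefe <- stage("distributions", summarize_distances(
    fefe, bin_width = dc$bin_width, bandwidth = dc$bandwidth,
    label = "FeFe"))
  sum_femg <- summarize_distances(femg, bin_width = dc$bin_width,
                                  bandwidth = dc$bandwidth, label = "FeMg")
  modes <- list(fefe = find_modes(sum_fefe, dc$min_prominence),
                femg = find_modes(sum_femg, dc$min_prominence))
  write_distribution_tsv(sum_fefe, file.path(cfg$outdir, "dist_fefe"))
  write_distribution_tsv(sum_femg, file.path(cfg$outdir, "dist_femg"))
  files["dist_fefe_kde"] <- file.path(cfg$outdir, "dist_fefe_kde.tsv")
  files["dist_femg_kde"] <- file.path(cfg$outdir, "dist_femg_kde.tsv")
  files["modes"] <- file.path(cfg$outdir, "modes.json")
  jsonlite::write_json(lapply(modes, function(m)
    as.data.frame(unclass(m))), files["modes"], digits = NA)
  bundle$distributions <- list(fefe = sum_fefe, femg = sum_femg,
                               modes = modes)

  ## -- flexibility + network (need a bead trajectory) -----------------------
  if (!is.null(cfg$generator)) {
    pn <- cfg$generator$planted_network
    if (is.null(pn)) pn <- list()
    pn$seed <- if (is.null(pn$seed)) cfg$seed else pn$seed
    say("stage network: planted-correlation bead trajectory")
    psim <- stage("network",
                  generate_planted_network_trajectory(
                    do.call(planted_network_params, pn)))
    bead_ens <- psim$ensemble
    bundle$planted <- psim
  } else {
    bead_ens <- ens
  }
  if (nrow(bead_ens$topology) < 4L) {
    ## marker-only ensembles (e.g. three collinear distance beads) carry no
    ## backbone to profile or network to build
    say("skipping flexibility/network stages: fewer than 4 sites")
    bead_ens <- NULL
  }
  if (!is.null(bead_ens)) {
  say("stage flexibility: RMSD/RMSF profiles")
  rms <- stage("flexibility", rmsd_series(bead_ens))
  prof <- stage("flexibility", rmsf_profile(bead_ens))
  files["rmsd"] <- file.path(cfg$outdir, "rmsd.tsv")
  utils::write.table(rms, files["rmsd"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files["rmsf"] <- file.path(cfg$outdir, "rmsf.tsv")
  utils::write.table(
    data.frame(resno = prof$resno, subunit = prof$subunit,
               rmsf_nm = unname(prof$rmsf)),
    files["rmsf"], sep = "\t", quote = FALSE, row.names = FALSE)
  bundle$flexibility <- list(rmsd = rms, rmsf = prof)

  nw <- cfg$network
  say("stage network: correlation graph + pathway")
  C <- stage("network", displacement_correlation(bead_ens))
  gr <- stage("network", build_graph(C, bead_ens,
                                     contact_cutoff = nw$contact_cutoff,
                                     occupancy = nw$occupancy))
  src <- if (is.null(nw$source)) igraph::V(gr$graph)$name[1L] else nw$source
  snk <- if (is.null(nw$sink))
    igraph::V(gr$graph)$name[igraph::vcount(gr$graph)] else nw$sink
  pw <- stage("network", shortest_pathway(gr, src, snk))
  bc <- betweenness_centrality(gr)
  files["graph"] <- file.path(cfg$outdir, "network_edges.tsv")
  write_graph_tsv(gr, files["graph"],
                  graphml = file.path(cfg$outdir, "network.graphml"))
  files["pathway"] <- file.path(cfg$outdir, "pathway.tsv")
  utils::write.table(
    data.frame(step = seq_along(pw$nodes), node = pw$nodes,
               edge_weight = c(NA, pw$edge_weights)),
    files["pathway"], sep = "\t", quote = FALSE, row.names = FALSE)
  files["betweenness"] <- file.path(cfg$outdir, "betweenness.tsv")
  utils::write.table(
    data.frame(node = names(bc), betweenness = unname(bc)),
    files["betweenness"], sep = "\t", quote = FALSE, row.names = FALSE)
  bundle$network <- list(correlation = C, graph = gr, pathway = pw,
                         betweenness = bc)
  }

  ## -- manifest --------------------------------------------------------------
  cfile <- file.path(cfg$outdir, "config.yaml")
  writeLines(config_yaml(cfg), cfile)
  manifest <- list(package = "corrshuttle",
                   version = as.character(utils::packageVersion("corrshuttle")),
                   seed = cfg$seed,
                   config_md5 = unname(tools::md5sum(cfile)),
                   n_frames = scan$n_frames,
                   outputs = as.list(basename(files)))
  files["manifest"] <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  bundle$files <- files
  bundle$manifest <- manifest
  class(bundle) <- "pipeline_bundle"
  say("pipeline complete: %s", cfg$outdir)
  bundle
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("pipeline_bundle:", length(x$files), "output files in",
      x$config$outdir, "\n")
  cat("  config md5:", x$manifest$config_md5, "\n")
  invisible(x)
}

#' Render report figures from a pipeline bundle
#'
#' Regenerates the standard figure set purely from the exported tables of a
#' pipeline run (so figures can be re-rendered without recomputation): the
#' concatenated distance co-evolution trace, the occupancy curve family, the
#' two-vector projection with (C, d) membership coloring, the distance
#' density panels, the RMSF profile and the network pathway diagram.  A
#' missing stage output is reported with a warning and skipped.
#'
#' @param bundle a \code{"pipeline_bundle"}, or the output directory of a
#'   previous run.
#' @param dir directory for the figure files (default: the bundle's outdir).
#' @param format \code{"png"} or \code{"pdf"}.
#' @return character vector of figure paths written.
#' @export
render_report <- function(bundle, dir = NULL, format = c("png", "pdf")) {
  format <- match.arg(format)
  outdir <- if (inherits(bundle, "pipeline_bundle")) bundle$config$outdir
  else as.character(bundle)
  if (is.null(dir)) dir <- outdir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dev_open <- function(path) {
    if (format == "png") grDevices::png(path, width = 900, height = 600)
    else grDevices::pdf(path, width = 9, height = 6)
  }
  made <- character(0)
  fig <- function(name, tsv, draw) {
    path <- file.path(outdir, tsv)
    if (!file.exists(path)) {
      warning("report: missing stage output '", tsv, "', figure skipped")
      return(invisible(NULL))
    }
    f <- file.path(dir, paste0(name, ".", format))
    dev_open(f)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw(utils::read.delim(path))
    made <<- c(made, f)
  }

  fig("fig_trace", "distances.tsv", function(tab) {
    sp <- split(tab, tab$trajectory_id)
    graphics::plot(NULL, xlim = c(0, max(tab$time_ns)),
                   ylim = range(tab$distance_nm),
                   xlab = "frame index (arbitrary reaction coordinate)",
                   ylab = "distance (nm)",
                   main = "Fe-Fe and Fe-Mg distance co-evolution")
    cols <- c("firebrick", "forestgreen")
    for (k in seq_along(sp))
      graphics::lines(sp[[k]]$time_ns, sp[[k]]$distance_nm,
                      col = cols[(k - 1L) %% 2L + 1L])
    graphics::legend("topright", legend = names(sp), col = cols, lty = 1,
                     cex = 0.8)
  })
  fig("fig_occupancy", "occupancy_curves.tsv", function(tab) {
    cs <- sort(unique(tab$C))
    graphics::plot(NULL, xlim = range(tab$d_nm), ylim = c(0, 1),
                   xlab = "d (nm)", ylab = "occupancy fraction",
                   main = "Mutually-exclusive occupancy vs threshold d")
    for (cc in cs) {
      sub <- tab[tab$C == cc, ]
      col <- if (abs(cc - 0.8) < 1e-9) "red" else
        if (abs(cc - 0.9) < 1e-9) "blue" else
          if (abs(cc - 1.0) < 1e-9) "darkgreen" else "grey70"
      graphics::lines(sub$d_nm, sub$fraction, col = col)
    }
  })
  fig("fig_projection", "projection.tsv", function(tab) {
    graphics::plot(tab$fefe_nm, tab$femg_nm, pch = 16, cex = 0.3,
                   col = "grey60", xlab = "Fe-Fe distance (nm)",
                   ylab = "Fe-Mg distance (nm)",
                   main = "Frames projected on the two distance vectors")
  })
  fig("fig_density", "dist_fefe_kde.tsv", function(tab) {
    graphics::plot(tab$d_nm, tab$density, type = "l", col = "firebrick",
                   xlab = "distance (nm)", ylab = "density (1/nm)",
                   main = "Distance distributions")
    p2 <- file.path(outdir, "dist_femg_kde.tsv")
    if (file.exists(p2)) {
      t2 <- utils::read.delim(p2)
      graphics::lines(t2$d_nm, t2$density, col = "forestgreen")
      graphics::legend("topright", legend = c("Fe-Fe", "Fe-Mg"),
                       col = c("firebrick", "forestgreen"), lty = 1)
    }
  })
  fig("fig_rmsf", "rmsf.tsv", function(tab) {
    graphics::plot(tab$resno, tab$rmsf_nm, type = "h", lwd = 3,
                   col = "steelblue", xlab = "residue",
                   ylab = "RMSF (nm)", main = "Per-residue RMSF")
  })
  fig("fig_pathway", "network_edges.tsv", function(tab) {
    g <- igraph::graph_from_data_frame(tab[, c("i", "j")], directed = FALSE)
    igraph::E(g)$weight <- tab$weight
    pth <- file.path(outdir, "pathway.tsv")
    vcol <- rep("grey80", igraph::vcount(g))
    if (file.exists(pth)) {
      pw <- utils::read.delim(pth)
      vcol[igraph::V(g)$name %in% pw$node] <- "orange"
    }
    set.seed(1L)
    graphics::plot(g, vertex.color = vcol, vertex.size = 12,
                   vertex.label.cex = 0.6,
                   main = "Correlation network and shortest pathway")
  })
  made
}
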