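# File formats, run configuration and command-line entry points.
#
# Coordinates are serialised as whitespace-delimited per-frame blocks: a
# commented metadata header, then for each frame a "frame <k>" line followed
# by one "locus_index x y z" line per locus. Full %.17g precision makes the
# round trip bit-exact. Matrices are delimited text with a commented header.

#' Write an ensemble to a text coordinate container
#'
#' @param ensemble A `wlc_ensemble`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  m <- ensemble$model
  meta <- c(
    "# meioMC ensemble v1",
    sprintf("# name %s", ensemble$spec$name),
    sprintf("# n_loci %d", ensemble$spec$n_loci),
    sprintf("# retained %d", ensemble$retained_count),
    sprintf("# length_bp %.17g", ensemble$spec$length_bp),
    sprintf("# centromere_bp %.17g", ensemble$spec$centromere_bp),
    sprintf("# bond_length_nm %.17g", ensemble$spec$bond_length_nm),
    sprintf("# radius_nm %.17g", m$geometry$radius_nm),
    sprintf("# spb_direction %.17g %.17g %.17g",
            m$geometry$spb_direction[1], m$geometry$spb_direction[2],
            m$geometry$spb_direction[3]),
    sprintf("# mode %s", m$tether$mode),
    sprintf("# nu %.17g", m$tether$nu),
    sprintf("# persistence_nm %.17g", m$persistence_nm),
    sprintf("# n_total %.17g", ensemble$schedule$n_total),
    sprintf("# n_burn_in %.17g", ensemble$schedule$n_burn_in),
    sprintf("# thin %d", ensemble$schedule$thin),
    sprintf("# seed %d", ensemble$schedule$seed),
    sprintf("# acceptance_rate %.17g", ensemble$acceptance_rate)
  )
  N <- ensemble$spec$n_loci
  M <- ensemble$retained_count
  pos <- ensemble$positions
  blocks <- vapply(seq_len(M), function(k) {
    xyz <- pos[, , k]
    paste(c(sprintf("frame %d", k),
            sprintf("%d %.17g %.17g %.17g", seq_len(N), xyz[, 1], xyz[, 2],
                    xyz[, 3])), collapse = "\n")
  }, character(1))
  writeLines(c(meta, blocks), path)
  invisible(path)
}

#' Read an ensemble written by [write_ensemble()]
#'
#' Restores coordinates bit-exactly and rebuilds spec, model and schedule from
#' the metadata header. Truncated files are detected via the frame count and
#' rejected rather than partially loaded.
#'
#' @param path File written by [write_ensemble()].
#' @return A `wlc_ensemble`.
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "# meioMC ensemble v1")
    stop("not a meioMC ensemble file (version header missing): ", path)
  hdr <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (h in hdr[-1]) {
    parts <- strsplit(sub("^# ", "", h), " ")[[1]]
    meta[[parts[1]]] <- parts[-1]
  }
  num <- function(key) as.numeric(meta[[key]])
  N <- as.integer(num("n_loci"))
  M <- as.integer(num("retained"))

  body <- lines[!startsWith(lines, "#")]
  frame_idx <- startsWith(body, "frame ")
  n_frames <- sum(frame_idx)
  if (n_frames != M || length(body) != M * (N + 1))
    stop("corrupt or truncated ensemble file: expected ", M, " frames of ",
         N, " loci, found ", n_frames, " frames / ", length(body), " lines")
  coord_lines <- body[!frame_idx]
  vals <- scan(text = coord_lines, what = double(), quiet = TRUE)
  vals <- matrix(vals, ncol = 4, byrow = TRUE)
  pos <- array(0, dim = c(N, 3, M))
  pos[] <- aperm(array(t(vals[, 2:4]), dim = c(3, N, M)), c(2, 1, 3))

  spec <- chromosome_spec(num("length_bp"), num("centromere_bp"), n_loci = N,
                          name = paste(meta$name, collapse = " "))
  geometry <- nuclear_geometry(num("radius_nm"), num("spb_direction"))
  mode <- meta$mode[1]
  tether <- if (mode == "none") tether_spec("none")
  else tether_spec(mode, nu = num("nu"), mu = geometry$spb_direction)
  model <- energy_model(spec, persistence_nm = num("persistence_nm"),
                        geometry = geometry, tether = tether)
  schedule <- sampler_schedule(num("n_total"), num("n_burn_in"),
                               thin = as.integer(num("thin")),
                               seed = as.integer(num("seed")))
  structure(list(
    positions = pos, spec = spec, model = model, schedule = schedule,
    retained_count = M, acceptance_rate = num("acceptance_rate"),
    step_angles = NULL,
    final_conformation = as_conformation(pos[, , M])
  ), class = "wlc_ensemble")
}

#' Write / read a distance map as delimited text
#'
#' @param map A `distance_map`.
#' @param path Output file.
#' @return `path` (write) or a `distance_map` (read).
#' @export
write_distance_map <- function(map, path) {
  hdr <- c("# meioMC distance_map v1",
           sprintf("# kind %s", map$kind),
           sprintf("# n_samples %.17g", map$n_samples),
           sprintf("# nd_nm %.17g", map$nd_nm),
           "# units fraction_of_nuclear_diameter")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(map$values, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_distance_map
#' @export
read_distance_map <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "# meioMC distance_map v1")
    stop("not a meioMC distance_map file: ", path)
  hdr <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (h in hdr[-1]) {
    parts <- strsplit(sub("^# ", "", h), " ")[[1]]
    meta[[parts[1]]] <- parts[-1]
  }
  vals <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t")
  values <- as.matrix(vals)
  dimnames(values) <- NULL
  nd <- as.numeric(meta$nd_nm)
  structure(list(values = values, values_nm = values * nd,
                 kind = meta$kind[1], n_samples = as.numeric(meta$n_samples),
                 specs = NULL, nd_nm = nd, diag_sd = NULL),
            class = "distance_map")
}

# --- run configuration -----------------------------------------------------

config_schema <- function() {
  list(
    scenario = c("kind", "condition", "chromosome", "chromosome_b",
                 "persistence_nm", "scale", "nu"),
    geometry = c("radius_nm", "spb_direction"),
    top = c("scenario", "geometry", "seed", "output", "plots",
            "excluded_volume", "write_ensembles")
  )
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected with the offending key named. The schema shipped
#' at `system.file("extdata", "config-schema.yaml", package = "meioMC")`
#' documents every key.
#'
#' @param path YAML file.
#' @return A validated config list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  schema <- config_schema()
  bad <- setdiff(names(cfg), schema$top)
  if (length(bad)) stop("unknown config key: ", bad[1])
  if (is.null(cfg$scenario)) stop("config is missing the 'scenario' block")
  bad <- setdiff(names(cfg$scenario), schema$scenario)
  if (length(bad)) stop("unknown config key: scenario.", bad[1])
  if (!is.null(cfg$geometry)) {
    bad <- setdiff(names(cfg$geometry), schema$geometry)
    if (length(bad)) stop("unknown config key: geometry.", bad[1])
  }
  sc <- cfg$scenario
  sc$kind <- sc$kind %||% "homologue"
  if (!sc$kind %in% c("homologue", "heterologue", "timecourse"))
    stop("unknown scenario kind: ", sc$kind)
  if (sc$kind != "timecourse") {
    if (is.null(sc$condition)) stop("scenario.condition is required")
    if (!sc$condition %in% names(condition_presets()))
      stop("unknown condition name: ", sc$condition)
  }
  if (is.null(sc$chromosome)) stop("scenario.chromosome is required")
  if (!sc$chromosome %in% names(chromosome_presets()))
    stop("unknown chromosome name: ", sc$chromosome)
  if (sc$kind == "heterologue") {
    if (is.null(sc$chromosome_b)) stop("scenario.chromosome_b is required")
    if (!sc$chromosome_b %in% names(chromosome_presets()))
      stop("unknown chromosome name: ", sc$chromosome_b)
  }
  sc$persistence_nm <- sc$persistence_nm %||% 200
  sc$scale <- sc$scale %||% "desk"
  if (is.character(sc$scale) && !sc$scale %in% names(scale_presets()))
    stop("unknown scale name: ", sc$scale)
  cfg$scenario <- sc
  cfg$seed <- cfg$seed %||% 1
  cfg$output <- cfg$output %||% "meiomc-run"
  cfg$plots <- isTRUE(cfg$plots)
  cfg$excluded_volume <- isTRUE(cfg$excluded_volume)
  cfg$write_ensembles <- isTRUE(cfg$write_ensembles)
  geom <- cfg$geometry
  cfg$geometry_obj <- nuclear_geometry(
    radius_nm = geom$radius_nm %||% 1000,
    spb_direction = unlist(geom$spb_direction) %||% c(0, 0, 1))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- bundle output ---------------------------------------------------------

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_bundle <- function(bundle, dir, cfg = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(bundle$allelic_profile, file.path(dir, "allelic_profile.tsv"))
  if (!is.null(bundle$allelic_rank))
    write_tsv(data.frame(bin = seq_along(bundle$allelic_rank$binned_means),
                         mean_nd = bundle$allelic_rank$binned_means),
              file.path(dir, "allelic_rank_scores.tsv"))
  if (!is.null(bundle$ectopic_rank))
    write_tsv(data.frame(bin = seq_along(bundle$ectopic_rank$binned_means),
                         mean_nd = bundle$ectopic_rank$binned_means),
              file.path(dir, "ectopic_rank_scores.tsv"))
  if (!is.null(bundle$map))
    write_distance_map(bundle$map, file.path(dir, "distance_map.tsv"))
  cl <- bundle$telomere_cloud
  if (!is.null(cl)) {
    cloud <- do.call(rbind, lapply(names(cl), function(copy) {
      do.call(rbind, lapply(c("tel1", "tel2"), function(tl) {
        m <- cl[[copy]][[tl]]
        data.frame(copy = copy, telomere = tl, x = m[, 1], y = m[, 2],
                   z = m[, 3])
      }))
    }))
    write_tsv(cloud, file.path(dir, "telomere_cloud.tsv"))
  }
  meta <- c(
    sprintf("kind: %s", bundle$kind),
    sprintf("condition: %s", bundle$condition),
    sprintf("chromosome_a: %s", bundle$spec_a$name),
    sprintf("chromosome_b: %s", bundle$spec_b$name),
    sprintf("persistence_nm: %g", bundle$persistence_nm),
    sprintf("seed: %d", bundle$seed),
    sprintf("n_total: %g", bundle$schedule$n_total),
    sprintf("n_burn_in: %g", bundle$schedule$n_burn_in),
    sprintf("thin: %d", bundle$schedule$thin),
    sprintf("retained_count: %d", bundle$retained_count),
    sprintf("acceptance_rate_a: %.6f", bundle$acceptance_rates[["a"]]),
    sprintf("acceptance_rate_b: %.6f", bundle$acceptance_rates[["b"]]))
  writeLines(meta, file.path(dir, "metadata.yaml"))
  if (!is.null(bundle$ensembles)) {
    write_ensemble(bundle$ensembles$a, file.path(dir, "ensemble_a.txt"))
    write_ensemble(bundle$ensembles$b, file.path(dir, "ensemble_b.txt"))
  }
  if (!is.null(cfg))
    yaml::write_yaml(cfg[setdiff(names(cfg), "geometry_obj")],
                     file.path(dir, "resolved_config.yaml"))
  write_manifest(dir)
  invisible(dir)
}

write_manifest <- function(dir) {
  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.tsv")
  md5 <- tools::md5sum(file.path(dir, files))
  write_tsv(data.frame(file = files, md5 = unname(md5)),
            file.path(dir, "manifest.tsv"))
}

# --- command-line operations -----------------------------------------------

#' Run a simulation scenario from a config file
#'
#' Resolves the scenario in a YAML config (see [read_run_config()]), runs it,
#' and writes the analytics bundle -- metadata, allelic profile, rank curves,
#' distance map, telomere cloud, optional heatmap PNG and a manifest with
#' content hashes -- to the configured output directory.
#'
#' @param config_path Path to a YAML run configuration.
#' @return The bundle directory, invisibly.
#' @export
cli_simulate <- function(config_path) {
  cfg <- read_run_config(config_path)
  sc <- cfg$scenario
  if (sc$kind == "homologue") {
    bundle <- run_homologue_experiment(
      sc$condition, sc$chromosome, sc$persistence_nm, scale = sc$scale,
      seed = cfg$seed, nu = sc$nu, geometry = cfg$geometry_obj,
      excluded_volume = cfg$excluded_volume,
      keep_ensembles = cfg$write_ensembles)
    write_bundle(bundle, cfg$output, cfg)
    if (cfg$plots) plot_bundle_png(bundle, cfg$output)
  } else if (sc$kind == "heterologue") {
    bundle <- run_heterologue_experiment(
      sc$condition, sc$chromosome, sc$chromosome_b, sc$persistence_nm,
      scale = sc$scale, seed = cfg$seed, nu = sc$nu,
      geometry = cfg$geometry_obj, excluded_volume = cfg$excluded_volume,
      keep_ensembles = cfg$write_ensembles)
    write_bundle(bundle, cfg$output, cfg)
    if (cfg$plots) plot_bundle_png(bundle, cfg$output)
  } else {
    tc <- run_timecourse(sc$chromosome, sc$persistence_nm, scale = sc$scale,
                         seed = cfg$seed, geometry = cfg$geometry_obj)
    dir.create(cfg$output, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tc$bundles))
      write_bundle(tc$bundles[[nm]], file.path(cfg$output, nm))
    comp <- do.call(rbind, lapply(names(tc$comparisons), function(nm) {
      cc <- tc$comparisons[[nm]]
      data.frame(condition = nm, baseline = "no_tether",
                 ks_statistic = cc$ks_statistic, ks_p = cc$ks_p,
                 wilcoxon_statistic = cc$wilcoxon_statistic,
                 wilcoxon_p = cc$wilcoxon_p)
    }))
    write_tsv(comp, file.path(cfg$output, "comparisons_vs_no_tether.tsv"))
    yaml::write_yaml(cfg[setdiff(names(cfg), "geometry_obj")],
                     file.path(cfg$output, "resolved_config.yaml"))
    write_manifest(cfg$output)
  }
  message("bundle written to ", cfg$output)
  invisible(cfg$output)
}

#' Recompute analytics from stored ensembles
#'
#' Reads ensemble containers written by [write_ensemble()] and recomputes
#' distance maps and rank curves without re-simulation. Modes: `"intra"`
#' (one ensemble), `"homologue"` / `"heterologue"` (two ensembles, paired by
#' sample index). Ensembles simulated in different nuclear geometries are
#' refused.
#'
#' @param ensemble_paths Character vector of ensemble files.
#' @param mode Analysis mode.
#' @param out_dir Output directory.
#' @return The output directory, invisibly.
#' @export
cli_analyze <- function(ensemble_paths, mode = c("homologue", "heterologue",
                                                 "intra"), out_dir = ".") {
  mode <- match.arg(mode)
  need <- if (mode == "intra") 1L else 2L
  if (length(ensemble_paths) != need)
    stop("mode '", mode, "' requires exactly ", need, " ensemble path(s)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (mode == "intra") {
    ens <- read_ensemble(ensemble_paths)
    map <- intra_ldm(ens)
    write_distance_map(map, file.path(out_dir, "distance_map.tsv"))
    off <- map$values[row(map$values) != col(map$values)]
    rk <- rank_scores(off, length(off) %/% 300L)
    write_tsv(data.frame(bin = seq_along(rk$binned_means),
                         mean_nd = rk$binned_means),
              file.path(out_dir, "rank_scores.tsv"))
  } else {
    ens_a <- read_ensemble(ensemble_paths[1])
    ens_b <- read_ensemble(ensemble_paths[2])
    map <- inter_ldm(ens_a, ens_b, kind = mode)
    write_distance_map(map, file.path(out_dir, "distance_map.tsv"))
    prof <- allelic_profile_any(map)
    write_tsv(prof, file.path(out_dir, "allelic_profile.tsv"))
    if (mode == "homologue") {
      ect <- ectopic_means(map)
      rk <- rank_scores(ect, length(ect) %/% 300L)
      write_tsv(data.frame(bin = seq_along(rk$binned_means),
                           mean_nd = rk$binned_means),
                file.path(out_dir, "ectopic_rank_scores.tsv"))
    }
  }
  write_manifest(out_dir)
  invisible(out_dir)
}

# --- plotting --------------------------------------------------------------

ldm_palette <- function(n = 256) {
  grDevices::colorRampPalette(c("#8b0000", "red", "yellow", "green",
                                "deepskyblue", "#00008b"))(n)
}

#' Heatmap of a locus distance map
#'
#' Renders the map with the fixed 0-1 ND colour scale running deep red (zero
#' distance) through yellow and green to deep blue (one nuclear diameter).
#'
#' @param map A `distance_map`.
#' @param main Plot title.
#' @export
plot_ldm <- function(map, main = sprintf("%s LDM", map$kind)) {
  v <- map$values
  graphics::image(seq_len(nrow(v)), seq_len(ncol(v)), v,
                  zlim = c(0, 1), col = ldm_palette(),
                  xlab = "locus (chromosome A)", ylab = "locus (chromosome B)",
                  main = main, useRaster = TRUE)
}

#' Allelic profile with standard-deviation band
#'
#' @param profile Data frame from [allelic_profile()].
#' @param main Plot title.
#' @export
plot_allelic_profile <- function(profile, main = "allelic distances") {
  x <- profile$locus
  m <- profile$mean_nd
  s <- profile$sd_nd
  graphics::plot(x, m, type = "n", ylim = c(0, max(m + s, 1, na.rm = TRUE)),
                 xlab = "locus (telomere to telomere)",
                 ylab = "mean allelic distance (ND)", main = main)
  if (!all(is.na(s)))
    graphics::polygon(c(x, rev(x)), c(m + s, rev(m - s)),
                      col = "grey30", border = NA)
  graphics::lines(x, m, col = "white", lwd = 2)
}

plot_bundle_png <- function(bundle, dir) {
  if (!is.null(bundle$map)) {
    grDevices::png(file.path(dir, "distance_map.png"), 800, 800)
    plot_ldm(bundle$map)
    grDevices::dev.off()
  }
  grDevices::png(file.path(dir, "allelic_profile.png"), 800, 500)
  plot_allelic_profile(bundle$allelic_profile,
                       main = sprintf("%s %s", bundle$condition,
                                      bundle$spec_a$name))
  grDevices::dev.off()
  write_manifest(dir)
  invisible(dir)
}
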