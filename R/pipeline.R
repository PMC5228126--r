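#' Study configuration
#'
#' Collects every knob of the end-to-end analysis.  In `"simulate"` mode a
#' full synthetic study is generated (retinas, counting frames, phylogeny,
#' behavioural traits) with known ground truth; in `"load"` mode counting
#' frames, outline, traits and tree are read from the configured files.
#'
#' Simulation defaults describe a typical single-foveate songbird study:
#' 29 species, 2-5 wholemount retinas each, 5 mm retinal radius, margin
#' density 500 and foveal density 3000-5000 cells/mm^2, fovea displaced
#' dorso-temporally (mean normalized position (-0.145, 0.057)), axis
#' steepness exponents highest dorsally/temporally, foveal peak density
#' rising with the planted configuration value, 50 um counting frames,
#' and behavioural traits generated from the true overall slope with
#' Brownian-motion phylogenetic error.
#'
#' @param mode `"simulate"` or `"load"`.
#' @param frames_file,outline_file,traits_file,tree_file Input paths (load
#'   mode).
#' @param out_dir Output directory for artifacts (`NULL` = don't write).
#' @param n_species,n_retinas_range Simulated species count and per-species
#'   retina count range.
#' @param radius,base_density Retina geometry and margin density (mm,
#'   cells/mm^2).
#' @param peak_density_range Range of simulated foveal peak densities
#'   (cells/mm^2): each species' peak density interpolates this range
#'   linearly in its latent configuration value.
#' @param fovea_mean,fovea_sd Mean and SD of simulated normalized fovea
#'   coordinates.
#' @param axis_steepness Named numeric: baseline steepness exponent per
#'   axis (at latent value 0).
#' @param steepness_gain Increase in every axis steepness exponent per unit
#'   latent value.  The per-species latent value, uniform on (0, 1), is the
#'   planted retinal-configuration axis: it raises both the quadrant
#'   steepness and the foveal peak density, so the true gradient slopes
#'   increase monotonically with it.
#' @param noise_cv Multiplicative density noise CV.
#' @param n_sites,frame_side Counting-frame sampling (sites per retina,
#'   frame side um).
#' @param frames_per_site Counting frames pooled per site (site density =
#'   pooled count / pooled area).
#' @param grid_step Map grid spacing, mm.
#' @param n_transect_points Samples per transect.
#' @param interp_method Interpolation for [build_topographic_map()].
#' @param smoothing Thin-plate smoothing parameter passed to
#'   [build_topographic_map()]; the default trades a small downward slope
#'   bias for stable peak localization under counting noise.
#' @param fovea_method Fovea localization on the mapped field: `"contour"`
#'   (centroid of the top isodensity region; robust under counting noise,
#'   the default) or `"max"` (see [locate_fovea()]).
#' @param fovea_level Super-level fraction for `fovea_method = "contour"`.
#' @param beta_head,beta_eye Planted effects of overall slope on log head
#'   movement rate and on degree of eye movement.
#' @param sigma2_head,sigma2_eye Brownian rates of the trait errors.
#' @param lambda_true Pagel's lambda used to simulate trait errors.
#' @param head_rate_base Baseline head movement rate (movements/min) at
#'   overall slope 0.
#' @param eye_base Baseline degree of eye movement (degrees).
#' @param lambda Lambda handling in the PGLS battery: `"ml"` or fixed.
#' @param pgls_method `"ML"` or `"REML"`.
#' @param alpha CI/test level.
#' @param seed Integer master seed (simulate mode).
#' @return A `study_config` object.
#' @export
study_config <- function(mode = c("simulate", "load"),
                         frames_file = NULL, outline_file = NULL,
                         traits_file = NULL, tree_file = NULL,
                         out_dir = NULL,
                         n_species = 29L, n_retinas_range = c(2L, 5L),
                         radius = 5, base_density = 500,
                         peak_density_range = c(3000, 5000),
                         fovea_mean = c(-0.145, 0.057),
                         fovea_sd = 0.05,
                         axis_steepness = c(nasal = 0.55, temporal = 1.05,
                                            dorsal = 1.20, ventral = 0.80),
                         steepness_gain = 0.4, noise_cv = 0.05,
                         n_sites = 300L, frame_side = 50,
                         frames_per_site = 4L,
                         grid_step = 0.2, n_transect_points = 10L,
                         interp_method = "tps", smoothing = 3,
                         fovea_method = "contour", fovea_level = 0.95,
                         beta_head = 0.25, beta_eye = 2,
                         sigma2_head = 0.05, sigma2_eye = 4,
                         lambda_true = 1,
                         head_rate_base = 12, eye_base = 2,
                         lambda = "ml", pgls_method = "ML",
                         alpha = 0.05, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "load") {
    files <- c(frames = frames_file, outline = outline_file,
               traits = traits_file, tree = tree_file)
    if (length(files) < 4 || any(!nzchar(files)))
      stop("load mode requires frames, outline, traits and tree files")
    missing <- files[!file.exists(files)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  cfg <- as.list(environment())
  structure(cfg, class = "study_config")
}

#' Read a study configuration from a YAML key-value file
#'
#' Keys mirror the arguments of [study_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(study_config)))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(vals$axis_steepness))
    vals$axis_steepness <- unlist(vals$axis_steepness)
  if (!is.null(vals$fovea_mean)) vals$fovea_mean <- unlist(vals$fovea_mean)
  do.call(study_config, vals)
}

#' Average per-retina measurements into one record per species
#'
#' Arithmetic mean per axis (and of the fovea coordinates) across the
#' retinas of each species.  An axis missing in every retina of a species
#' is flagged by an `NA` with a warning.
#'
#' @param per_retina Data frame with columns `species`, `retina_id`, the
#'   slope columns `nasal`, `temporal`, `dorsal`, `ventral`, `overall`, and
#'   optionally `x`, `y` (normalized fovea position).
#' @return Data frame with one row per species: averaged slopes, positions
#'   and `n_retinas`.
#' @export
species_average <- function(per_retina) {
  if (!nrow(per_retina)) stop("empty per-retina table")
  cols <- intersect(c("nasal", "temporal", "dorsal", "ventral", "overall",
                      "x", "y"), names(per_retina))
  sp <- unique(per_retina$species)
  out <- do.call(rbind, lapply(sp, function(s) {
    sub <- per_retina[per_retina$species == s, , drop = FALSE]
    row <- data.frame(species = s, n_retinas = nrow(sub))
    for (cc in cols) {
      v <- mean(sub[[cc]], na.rm = TRUE)
      if (is.nan(v)) {
        warning("species ", s, ": no data for '", cc, "' in any retina")
        v <- NA_real_
      }
      row[[cc]] <- v
    }
    row
  }))
  rownames(out) <- NULL
  out
}

## Measure a single retina: map (or direct field), fovea, normalized
## position, transect slopes.  Returns a one-row data frame.
.measure_retina <- function(field, species, retina_id, eye_side,
                            n_transect_points, fovea_method = "max",
                            fovea_level = 0.95) {
  fov <- locate_fovea(field, method = fovea_method, level = fovea_level)
  pos <- normalize_fovea_position(fov, field$outline, eye_side, species)
  sl <- suppressWarnings(
    transect_slopes(field, fovea = fov, n_points = n_transect_points,
                    species = species))
  data.frame(species = species, retina_id = retina_id,
             eye_side = pos$eye_side,
             nasal = sl$nasal$slope, temporal = sl$temporal$slope,
             dorsal = sl$dorsal$slope, ventral = sl$ventral$slope,
             overall = sl$overall$slope, x = pos$x, y = pos$y)
}

#' Run the full retinal-configuration study
#'
#' Orchestrates the pipeline: simulate (or load) counting frames per
#' retina, build topographic maps, locate and normalize the fovea, fit the
#' four axis gradient slopes plus the overall slope, average per species,
#' summarize the fovea position across species, compare slopes among
#' retinal regions, and run the comparative PGLS battery: log head movement
#' rate and degree of eye movement each regressed on the overall and four
#' regional slopes, eye movement on log head rate, and overall slope on log
#' axial length (the size-independence check) — twelve models.
#'
#' When `config$out_dir` is set, all artifacts are written there (CSV
#' tables, JSON reports, newick tree, and a `manifest.json` capturing the
#' configuration, seed and package version).
#'
#' @param config A [study_config()].
#' @return A `study_report` list: `species` (per-species record table),
#'   `per_retina`, `fovea_summary`, `region_comparison`, `pgls` (named list
#'   of 12 [pgls_fit()]s), `outliers` (species with |standardized residual|
#'   > 3 in any model), `tree`, `traits`, and in simulate mode `truth`
#'   (planted per-species values).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (config$mode == "simulate") {
    study <- .simulate_study_inputs(config)
  } else {
    study <- .load_study_inputs(config)
  }
  per_retina <- do.call(rbind, lapply(study$retinas, function(r)
    .measure_retina(r$field, r$species, r$retina_id, r$eye_side,
                    config$n_transect_points, config$fovea_method,
                    config$fovea_level)))
  species <- species_average(per_retina)

  missing_sp <- setdiff(species$species, study$tree$tip.label)
  if (length(missing_sp))
    stop("species absent from tree: ", paste(missing_sp, collapse = ", "))

  fovea_summary <- mean_position_with_ci(
    species[, c("species", "x", "y")], alpha = config$alpha)
  region <- region_glm(species)

  traits <- study$traits
  traits <- traits[match(species$species, traits$species), ]
  dat <- cbind(species, traits[, c("head_rate", "eye_movement",
                                   "axial_length")])
  dat$log_head_rate <- log_transform_rate(dat$head_rate)

  axes5 <- c("overall", "nasal", "temporal", "dorsal", "ventral")
  fit1 <- function(yv, xv, xname) {
    pgls_fit(stats::setNames(dat[[yv]], dat$species),
             matrix(dat[[xname]], ncol = 1,
                    dimnames = list(dat$species, xname)),
             study$tree, lambda = config$lambda,
             method = config$pgls_method)
  }
  pgls <- list()
  for (ax in axes5) pgls[[paste0("head_rate~", ax)]] <-
    fit1("log_head_rate", ax, ax)
  for (ax in axes5) pgls[[paste0("eye_movement~", ax)]] <-
    fit1("eye_movement", ax, ax)
  pgls[["eye_movement~head_rate"]] <- fit1("eye_movement", "log_head_rate",
                                           "log_head_rate")
  dat$log_axial_length <- log(dat$axial_length)
  pgls[["overall~log_axial_length"]] <- fit1("overall", "log_axial_length",
                                             "log_axial_length")

  outliers <- sort(unique(unlist(lapply(pgls, function(f)
    names(f$std_residuals)[abs(f$std_residuals) > 3]))))

  report <- structure(list(
    species = dat, per_retina = per_retina,
    fovea_summary = fovea_summary, region_comparison = region,
    pgls = pgls, outliers = outliers, tree = study$tree,
    traits = traits, truth = study$truth, config = config),
    class = "study_report")
  if (!is.null(config$out_dir)) .write_study_artifacts(report)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report:", nrow(x$species), "species,",
      nrow(x$per_retina), "retinas\n\n")
  cat("Fovea position summary (normalized coordinates):\n")
  print(round(as.data.frame(x$fovea_summary), 4))
  cat("\n")
  print(x$region_comparison)
  cat("\nPGLS battery:\n")
  for (nm in names(x$pgls)) {
    f <- x$pgls[[nm]]
    cat(sprintf("  %-28s %s = %6.2f, P = %.4g, adj R2 = %6.3f, lambda = %.2f\n",
                nm, f$df_label, f$F, f$p_value, f$r2_adj, f$lambda_hat))
  }
  if (length(x$outliers))
    cat("\nOutlier screen (|std resid| > 3):",
        paste(x$outliers, collapse = ", "), "\n")
  else cat("\nOutlier screen: none flagged\n")
  invisible(x)
}

## ---- simulate mode -------------------------------------------------------

.simulate_study_inputs <- function(config) {
  old <- .Random.seed_save()
  set.seed(config$seed)
  n <- config$n_species
  sp_names <- sprintf("sp%02d", seq_len(n))
  tree <- ape::rtree(n, tip.label = sp_names)

  latent <- stats::runif(n)
  fovx <- stats::rnorm(n, config$fovea_mean[1], config$fovea_sd)
  fovy <- stats::rnorm(n, config$fovea_mean[2], config$fovea_sd)
  n_ret <- sample(seq(config$n_retinas_range[1], config$n_retinas_range[2]),
                  n, replace = TRUE)
  retina_seeds <- sample.int(2^30, n * max(n_ret))

  axes <- c("nasal", "temporal", "dorsal", "ventral")
  pk <- config$peak_density_range[1] +
    diff(config$peak_density_range) * latent
  retinas <- list(); truth_rows <- list()
  for (i in seq_len(n)) {
    steep <- config$axis_steepness[axes] + config$steepness_gain * latent[i]
    true_spec <- retina_spec(config$radius, c(fovx[i], fovy[i]),
                             config$base_density, pk[i],
                             quadrant_steepness = steep, noise_cv = 0,
                             seed = 1L)
    true_field <- generate_density_field(true_spec, config$grid_step)
    true_sl <- suppressWarnings(transect_slopes(
      true_field, fovea = c(fovx[i], fovy[i]) * config$radius,
      n_points = config$n_transect_points, species = sp_names[i]))
    truth_rows[[i]] <- data.frame(
      species = sp_names[i], latent = latent[i], peak_density = pk[i],
      fovea_x = fovx[i], fovea_y = fovy[i],
      t(vapply(c(axes, "overall"), function(a) true_sl[[a]]$slope, 0)))
    for (r in seq_len(n_ret[i])) {
      rseed <- retina_seeds[(i - 1) * max(n_ret) + r]
      spec <- retina_spec(config$radius, c(fovx[i], fovy[i]),
                          config$base_density, pk[i],
                          quadrant_steepness = steep,
                          noise_cv = config$noise_cv, seed = rseed)
      field <- generate_density_field(spec, config$grid_step)
      frames <- sample_counting_frames(field, config$n_sites,
                                       config$frame_side,
                                       config$frames_per_site,
                                       seed = rseed)
      map <- build_topographic_map(frames, field$outline,
                                   config$grid_step,
                                   method = config$interp_method,
                                   smoothing = config$smoothing)
      retinas[[length(retinas) + 1L]] <-
        list(field = map, species = sp_names[i],
             retina_id = paste0(sp_names[i], "_r", r),
             eye_side = "right")
    }
  }
  truth <- do.call(rbind, truth_rows)

  head_seed <- sample.int(2^30, 1); eye_seed <- sample.int(2^30, 1)
  pred <- stats::setNames(truth$overall, truth$species)
  log_head <- simulate_traits_on_tree(
    trait_sim_spec(tree, beta0 = log(config$head_rate_base),
                   beta1 = config$beta_head,
                   lambda_true = config$lambda_true,
                   sigma2 = config$sigma2_head, seed = head_seed), pred)
  eye <- simulate_traits_on_tree(
    trait_sim_spec(tree, beta0 = config$eye_base,
                   beta1 = config$beta_eye,
                   lambda_true = config$lambda_true,
                   sigma2 = config$sigma2_eye, seed = eye_seed), pred)
  traits <- data.frame(
    species = truth$species,
    head_rate = exp(log_head$trait[match(truth$species, log_head$species)]),
    eye_movement = pmax(
      eye$trait[match(truth$species, eye$species)], 0.1),
    axial_length = exp(stats::rnorm(n, log(14), 0.15)))
  .Random.seed_restore(old)
  list(retinas = retinas, tree = tree, traits = traits, truth = truth)
}

## ---- load mode -----------------------------------------------------------

.load_study_inputs <- function(config) {
  frames_all <- read_counting_frames(config$frames_file)
  if (is.null(frames_all$species))
    stop("frames file needs a species column in load mode")
  if (is.null(frames_all$retina_id))
    frames_all$retina_id <- paste0(frames_all$species, "_r1")
  if (is.null(frames_all$eye_side)) frames_all$eye_side <- "right"
  outline_df <- utils::read.csv(config$outline_file,
                                stringsAsFactors = FALSE)
  traits <- read_traits(config$traits_file)
  tree <- parse_newick(file = config$tree_file)
  retinas <- lapply(unique(frames_all$retina_id), function(rid) {
    sub <- frames_all[frames_all$retina_id == rid, , drop = FALSE]
    outl <- if ("retina_id" %in% names(outline_df) &&
                rid %in% outline_df$retina_id)
      outline_df[outline_df$retina_id == rid, c("x", "y")]
    else outline_df[, c("x", "y")]
    cf <- counting_frames(sub$x, sub$y, sub$frame_side, sub$count)
    map <- build_topographic_map(cf, outl, config$grid_step,
                                 method = config$interp_method,
                                 smoothing = config$smoothing)
    list(field = map, species = sub$species[1], retina_id = rid,
         eye_side = sub$eye_side[1])
  })
  list(retinas = retinas, tree = tree, traits = traits, truth = NULL)
}

## ---- artifacts -----------------------------------------------------------

.write_study_artifacts <- function(report) {
  dir.create(report$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(report$config$out_dir, f)
  utils::write.csv(report$species, p("species.csv"), row.names = FALSE)
  utils::write.csv(report$per_retina, p("per_retina.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(axis = rownames(report$fovea_summary),
                         as.data.frame(report$fovea_summary)),
                   p("fovea_summary.csv"), row.names = FALSE)
  write_newick(report$tree, p("tree.nwk"))
  rc <- report$region_comparison
  jsonlite::write_json(list(
    means = rc$means, F = rc$F, df = rc$df, p_global = rc$p_global,
    pairwise = as.data.frame(rc$pairwise), mse = rc$mse),
    p("region_comparison.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  pg <- lapply(report$pgls, function(f)
    list(coefficients = as.list(f$coefficients), lambda = f$lambda_hat,
         sigma2 = f$sigma2_hat, F = f$F, df = f$df,
         df_label = f$df_label, p = f$p_value, r2 = f$r2,
         r2_adj = f$r2_adj, loglik = f$loglik, n = f$n))
  jsonlite::write_json(pg, p("pgls_battery.json"), auto_unbox = TRUE,
                       digits = NA)
  pg_csv <- do.call(rbind, lapply(names(report$pgls), function(nm) {
    f <- report$pgls[[nm]]
    data.frame(model = nm, slope_coef = unname(f$coefficients[2]),
               lambda = f$lambda_hat, F = f$F, df1 = f$df[1],
               df2 = f$df[2], df_label = f$df_label, p = f$p_value,
               r2 = f$r2, r2_adj = f$r2_adj, n = f$n)
  }))
  utils::write.csv(pg_csv, p("pgls_battery.csv"), row.names = FALSE)
  cfg <- report$config
  cfg_list <- unclass(cfg)
  cfg_list <- cfg_list[!vapply(cfg_list, is.null, TRUE)]
  cfg_list$out_dir <- NULL  # manifest stays identical across output paths
  jsonlite::write_json(list(
    package = "retgrad",
    version = as.character(utils::packageVersion("retgrad")),
    seed = cfg$seed, config = cfg_list,
    outliers = report$outliers),
    p("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(report$config$out_dir)
}
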