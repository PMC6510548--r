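# Configuration parsing, scenario-grid runs, result export and presets.

.scene_keys <- list(
  geometry = c("theta_s", "theta_v"),
  atmosphere = c("tau_a550", "angstrom", "g", "ssa", "scale_height",
                 "n_layers", "gas_absorption"),
  ocean = c("chla", "cdom_a440", "bottom_depth", "backscatter_ratio"),
  quenching = c("qI", "Ek", "ET", "phi_min", "phi_max"),
  emission = c("lambda0", "sigma", "window"),
  raman = c("bR488", "slope", "shift", "width", "enabled"),
  fdom = c("eta"),
  grids = c("excitation", "emission"),
  solver = c("n_mu", "n_modes", "tol", "max_orders", "n_water_layers",
             "raman_in_excitation"),
  grid = c("chla", "tau_a550", "theta_s"))

check_keys <- function(cfg) {
  bad <- setdiff(names(cfg), names(.scene_keys))
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), .scene_keys[[sec]])
    if (length(bad)) {
      stop("unknown config keys: ",
           paste(paste0(sec, "$", bad), collapse = ", "))
    }
  }
}

grid_from_spec <- function(g, default) {
  if (is.null(g)) return(default)
  if (!is.null(g$from)) return(seq(g$from, g$to, by = g$by))
  unlist(g)
}

#' Load a scene (and optional scenario grid) from a config file
#'
#' YAML or JSON structured text mirroring the [scene()] fields; omitted keys
#' fall back to the baseline defaults (aerosol optical depth 0.1, solar
#' zenith 30 degrees, Chla = 1, the standard quenching parameters and
#' emission line). Unknown keys and out-of-range values are rejected with
#' their key paths.
#'
#' @param path config file (".yml"/".yaml" or ".json")
#' @return list with `scene` (a `fluorrt_scene`) and `grid` (a named list of
#'   scenario sweep values, possibly empty)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  check_keys(cfg)
  config_to_scene(cfg)
}

config_to_scene <- function(cfg) {
  g <- function(sec, key, default) {
    v <- cfg[[sec]][[key]]
    if (is.null(v)) default else v
  }
  atm <- atmosphere_state(
    tau_a550 = g("atmosphere", "tau_a550", 0.1),
    angstrom = g("atmosphere", "angstrom", 0.3),
    g = g("atmosphere", "g", 0.75),
    ssa = g("atmosphere", "ssa", 0.98),
    scale_height = g("atmosphere", "scale_height", 2),
    n_layers = g("atmosphere", "n_layers", 10),
    gas_absorption = g("atmosphere", "gas_absorption", TRUE))
  oc <- ocean_state(
    chla = g("ocean", "chla", 1),
    cdom_a440 = cfg$ocean$cdom_a440,
    bottom_depth = cfg$ocean$bottom_depth,
    backscatter_ratio = g("ocean", "backscatter_ratio", 0.01))
  qp <- quenching_params(
    qI = g("quenching", "qI", 0.35), Ek = g("quenching", "Ek", 55),
    ET = g("quenching", "ET", 634),
    phi_min = g("quenching", "phi_min", 0.03),
    phi_max = g("quenching", "phi_max", 0.09))
  em <- emission_spec(
    lambda0 = g("emission", "lambda0", 685),
    sigma = g("emission", "sigma", 10.6),
    window = unlist(g("emission", "window", c(370, 690))))
  rm <- raman_params(
    bR488 = g("raman", "bR488", 2.6e-4), slope = g("raman", "slope", 5.3),
    shift = g("raman", "shift", 3350), width = g("raman", "width", 150),
    enabled = g("raman", "enabled", TRUE))
  sc <- scene(
    theta_s = g("geometry", "theta_s", 30),
    theta_v = g("geometry", "theta_v", 0),
    atmosphere = atm, ocean = oc, quenching = qp, emission = em,
    raman = rm, fdom_eta = g("fdom", "eta", 0),
    excitation_grid = grid_from_spec(cfg$grids$excitation,
                                     seq(370, 690, by = 10)),
    emission_grid = grid_from_spec(cfg$grids$emission,
                                   seq(640, 750, by = 2.5)),
    n_mu = g("solver", "n_mu", 32), n_modes = g("solver", "n_modes", 1),
    tol = g("solver", "tol", 1e-4),
    max_orders = g("solver", "max_orders", 100),
    n_water_layers = g("solver", "n_water_layers", 50),
    raman_in_excitation = g("solver", "raman_in_excitation", FALSE))
  grid <- cfg$grid
  if (is.null(grid)) grid <- list()
  list(scene = sc, grid = grid)
}

# replace one scalar knob of a scene, revalidating through the constructors
scene_with <- function(sc, chla = NULL, tau_a550 = NULL, theta_s = NULL) {
  atm <- sc$atmosphere
  oc <- sc$ocean
  if (!is.null(tau_a550)) {
    atm <- atmosphere_state(tau_a550 = tau_a550, angstrom = atm$angstrom,
                            g = atm$g, ssa = atm$ssa,
                            scale_height = atm$scale_height,
                            n_layers = atm$n_layers,
                            gas_absorption = atm$gas_absorption)
  }
  if (!is.null(chla)) {
    oc <- ocean_state(chla = chla, depth_grid = oc$depth_grid,
                      bottom_depth = oc$bottom_depth,
                      backscatter_ratio = oc$backscatter_ratio)
  }
  scene(theta_s = if (is.null(theta_s)) sc$theta_s else theta_s,
        theta_v = sc$theta_v, atmosphere = atm, ocean = oc,
        quenching = sc$quenching, emission = sc$emission, raman = sc$raman,
        fdom_eta = sc$fdom_eta, excitation_grid = sc$excitation_grid,
        emission_grid = sc$emission_grid, n_mu = sc$n_mu,
        n_modes = sc$n_modes, tol = sc$tol, max_orders = sc$max_orders,
        n_water_layers = sc$n_water_layers,
        raman_in_excitation = sc$raman_in_excitation)
}

#' Run a scenario grid
#'
#' Cross product of the supplied `chla`, `tau_a550` and `theta_s` lists
#' around a template scene; one simulation per combination. The solver is
#' deterministic, so reruns with the same configuration reproduce results
#' bit-exactly.
#'
#' @param grid named list with any of `chla`, `tau_a550`, `theta_s`
#' @param template a [scene()] supplying all other settings
#' @param decompose passed to [run_emission_pass()]
#' @param quiet suppress per-scene progress messages
#' @return object of class `fluorrt_grid`: list of `fluorrt_sim` results
#'   with a `meta` data.frame
#' @export
run_grid <- function(grid, template = scene(), decompose = FALSE,
                     quiet = FALSE) {
  vals <- list(chla = grid$chla %||% template$ocean$chla,
               tau_a550 = grid$tau_a550 %||% template$atmosphere$tau_a550,
               theta_s = grid$theta_s %||% template$theta_s)
  meta <- expand.grid(chla = vals$chla, tau_a550 = vals$tau_a550,
                      theta_s = vals$theta_s, KEEP.OUT.ATTRS = FALSE)
  results <- vector("list", nrow(meta))
  meta$status <- "ok"
  meta$seconds <- NA_real_
  for (k in seq_len(nrow(meta))) {
    sck <- scene_with(template, chla = meta$chla[k],
                      tau_a550 = meta$tau_a550[k],
                      theta_s = meta$theta_s[k])
    t0 <- Sys.time()
    results[[k]] <- tryCatch(
      simulate_scene(sck, decompose = decompose),
      error = function(e) {
        meta$status[k] <<- conditionMessage(e)
        NULL
      })
    meta$seconds[k] <- as.numeric(Sys.time() - t0, units = "secs")
    if (!quiet) {
      message(sprintf(
        "scene %d/%d (chla=%g, tau_a=%g, theta_s=%g): %s [%.1f s]",
        k, nrow(meta), meta$chla[k], meta$tau_a550[k], meta$theta_s[k],
        meta$status[k], meta$seconds[k]))
    }
  }
  structure(list(results = results, meta = meta, template = template,
                 config_hash = object_hash(list(meta[c(1:3)], template))),
            class = "fluorrt_grid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write grid results to disk
#'
#' One flat CSV per scenario (wavelength plus spectra columns plus the
#' scenario coordinates) together with a JSON metadata file recording the
#' configuration hash and solver settings.
#'
#' @param gridres a `fluorrt_grid` from [run_grid()]
#' @param dir output directory (created if needed)
#' @return invisibly, the written file paths
#' @export
write_results <- function(gridres, dir) {
  stopifnot(inherits(gridres, "fluorrt_grid"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (k in seq_along(gridres$results)) {
    r <- gridres$results[[k]]
    if (is.null(r)) next
    m <- gridres$meta[k, ]
    df <- cbind(r$spectra, chla = m$chla, tau_a550 = m$tau_a550,
                theta_s = m$theta_s)
    p <- file.path(dir, sprintf("scene_%03d.csv", k))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  meta_path <- file.path(dir, "meta.json")
  tmpl <- gridres$template
  jsonlite::write_json(list(
    config_hash = gridres$config_hash,
    scenes = gridres$meta,
    solver = list(n_mu = tmpl$n_mu, n_modes = tmpl$n_modes,
                  tol = tmpl$tol, max_orders = tmpl$max_orders,
                  n_water_layers = tmpl$n_water_layers),
    fixtures = list_fixtures()),
    meta_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, meta_path))
}

#' Read back grid results written by [write_results()]
#'
#' @param dir directory written by [write_results()]
#' @return list with `spectra` (list of data.frames) and `meta`
#' @export
read_results <- function(dir) {
  files <- sort(list.files(dir, "^scene_\\d+\\.csv$", full.names = TRUE))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  list(spectra = lapply(files, utils::read.csv), meta = meta)
}

#' Preset scenario bundles
#'
#' Named scenario grids for the standard sensitivity sweeps:
#' \describe{
#'   \item{fig1}{quantum-yield/IPAR profiles, Chla sweep 0.03-10,
#'     tau_a = 0.1, theta_s = 30}
#'   \item{fig2}{TOA spectra, Chla sweep 0-10 with gas absorption}
#'   \item{fig3}{TOO spectra, Chla sweep 0-10}
#'   \item{fig4}{aerosol sweep 0-0.5 at Chla = 10}
#'   \item{fig5}{solar-zenith sweep 0-78 at Chla = 10}
#' }
#'
#' @param name preset name
#' @return list with `grid` and `template` ready for [run_grid()]
#' @export
preset_scene <- function(name = c("fig1", "fig2", "fig3", "fig4", "fig5")) {
  name <- match.arg(name)
  switch(name,
    fig1 = list(grid = list(chla = c(0.03, 0.1, 1, 10)),
                template = scene(tau_a550 = 0.1, theta_s = 30)),
    fig2 = list(grid = list(chla = c(0, 0.03, 0.1, 1, 10)),
                template = scene(tau_a550 = 0.1, theta_s = 30)),
    fig3 = list(grid = list(chla = c(0, 0.03, 0.1, 1, 10)),
                template = scene(tau_a550 = 0.1, theta_s = 30)),
    fig4 = list(grid = list(tau_a550 = c(0, 0.1, 0.2, 0.5)),
                template = scene(chla = 10, theta_s = 30)),
    fig5 = list(grid = list(theta_s = c(0, 30, 60, 78)),
                template = scene(chla = 10, tau_a550 = 0.1)))
}
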