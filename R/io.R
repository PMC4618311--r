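# File formats: tables as TSV with header (floats printed with %.10g,
# readers tolerate CRLF line endings and '#' comment lines), reports and
# configs as JSON/YAML, dendrograms as Newick, images as TIFF.

#' Write a data frame as a TSV table
#'
#' @param x data frame.
#' @param path output path.
#' @param float_format sprintf format for numeric columns.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path, float_format = "%.10g") {
  y <- as.data.frame(x)
  for (j in seq_along(y)) {
    if (is.numeric(y[[j]]) && !is.integer(y[[j]]))
      y[[j]] <- sprintf(float_format, y[[j]])
  }
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table (tolerant of CRLF and comment lines)
#'
#' @param path input path.
#' @param required_cols column names that must be present; mismatch is an
#'   error naming the missing columns.
#' @return data frame.
#' @export
read_tsv_table <- function(path, required_cols = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(lines)]
  x <- tryCatch(
    utils::read.table(text = lines, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE),
    error = function(e) {
      # locate the first malformed row for the message
      hdr <- strsplit(lines[1], "\t")[[1]]
      for (i in seq_along(lines)[-1]) {
        if (length(strsplit(lines[i], "\t")[[1]]) != length(hdr))
          stop(sprintf("malformed row at line %d of %s", i, path))
      }
      stop(e)
    })
  if (!is.null(required_cols)) {
    miss <- setdiff(required_cols, names(x))
    if (length(miss))
      stop(sprintf("header mismatch in %s: missing column(s) %s",
                   path, paste(miss, collapse = ", ")))
  }
  x
}

#' Write / read a meridian contour
#' @param meridian a [meridian_contour()].
#' @param path file path.
#' @return `path` / a [meridian_contour()].
#' @export
write_meridian <- function(meridian, path) {
  write_tsv_table(as.data.frame(meridian), path)
}

#' @rdname write_meridian
#' @export
read_meridian <- function(path) {
  x <- read_tsv_table(path, required_cols = c("s", "phi", "r", "z",
                                              "kappa_s", "kappa_theta"))
  meridian_contour(x$s, x$phi, x$r, x$z, x$kappa_s, x$kappa_theta)
}

#' Write an image stack as a multi-page TIFF
#' @param stack list of matrices.
#' @param path output .tif path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  mx <- max(vapply(stack, max, 0))
  tiff::writeTIFF(lapply(stack, function(m) m / mx), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Run the demonstration analysis pipeline on synthetic data
#'
#' Executes the full chain on generated inputs: synthesize a growing cell
#' and fiducial tracks, track outlines and measure curvature, fit the
#' wall velocity profile and strain rates, generate and fit a
#' plasmolysis pair, run the growth model, and analyse fluorescence
#' profiles (FWHA, clustering). All tables and reports are written under
#' `out_dir` along with a manifest carrying the configuration, its hash
#' and the seed.
#'
#' @param config named list (or path to a YAML file) with entries `seed`,
#'   and optional stage switches/sizes: `stages` (character subset of
#'   `c("synth", "geometry", "kinematics", "elasticity", "growth",
#'   "profiles")`), `n_frames`, `n_tracks`, `growth_steps`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = list(seed = 1), out_dir = tempfile("wm_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(seed = 1L,
                   stages = c("synth", "geometry", "kinematics",
                              "elasticity", "growth", "profiles"),
                   n_frames = 6L, n_tracks = 8L, growth_steps = 60L)
  bad <- setdiff(names(config), names(defaults))
  if (length(bad))
    stop(sprintf("unknown config entr%s: %s",
                 if (length(bad) > 1) "ies" else "y",
                 paste(bad, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config)
  need <- setdiff(cfg$stages, defaults$stages)
  if (length(need)) stop("unknown stage(s): ", paste(need, collapse = ", "))
  # dependency pre-flight: downstream stages need the synthetic inputs
  if (any(c("geometry", "kinematics", "profiles") %in% cfg$stages) &&
      !"synth" %in% cfg$stages)
    stop("stage dependency missing: 'synth' must run before analysis stages")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(x, name, kind = c("tsv", "json")) {
    kind <- match.arg(kind)
    p <- file.path(out_dir, name)
    if (kind == "tsv") write_tsv_table(x, p)
    else jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE)
    outputs <<- c(outputs, name)
    p
  }
  sc <- synthetic_scenario(seed = cfg$seed, n_frames = cfg$n_frames,
                           dh_mean = 0.3, fluctuation = 0.3,
                           noise_sd = list(image = 2, track = 0.02,
                                           profile = 4, contour = 0.01))
  stage_out <- list()
  if ("synth" %in% cfg$stages) {
    syn <- synth_cell_image_stack(sc)
    stage_out$synth <- syn
    emit(data.frame(frame = seq_along(syn$growth) + 1L, dh_um = syn$growth),
         "growth_increments.tsv")
  }
  if ("geometry" %in% cfg$stages) {
    syn <- stage_out$synth
    init <- resample_outline(syn$outlines[[1]], n = 60)
    tracked <- track_outlines(syn$stack, init)
    profs <- lapply(tracked, meridional_curvature)
    emit(profs[[1]], "curvature_frame1.tsv")
    pole <- locate_pole(syn$outlines[[1]], syn$outlines[[length(syn$outlines)]])
    emit(data.frame(x_px = pole$point[1], y_px = pole$point[2],
                    path_px = pole$path_length), "pole.tsv")
    stage_out$geometry <- list(tracked = tracked, pole = pole)
  }
  if ("kinematics" %in% cfg$stages) {
    m <- cap_cylinder_meridian(sc$cell_radius, flank = 6, n = 241)
    vp_true <- velocity_profile(b = 0.12, c = -0.03)
    tracks <- synth_qdot_tracks(vp_true, m, cfg$n_tracks, sc)
    samples <- do.call(rbind, lapply(tracks, relative_displacement,
                                     meridian = m))
    fit <- fit_velocity_profile(samples)
    prof <- strain_rates(fit, m)
    emit(samples, "qdot_samples.tsv")
    emit(as.data.frame(prof), "expansion_profile.tsv")
    emit(list(a = fit$a, b = fit$b, c = fit$c,
              rss = attr(fit, "rss"), n = attr(fit, "n")),
         "velocity_fit.json", "json")
    stage_out$kinematics <- list(fit = fit, profile = prof, meridian = m)
  }
  if ("elasticity" %in% cfg$stages) {
    truth <- elastic_params(58, 0.03)
    pair <- synth_plasmolysis_pair(truth, noise_sd = 0, seed = cfg$seed)
    est <- fit_elastic_params(pair$plasmolysed_meridian,
                              pair$turgid_meridian, grid_n = 4)
    emit(pair$plasmolysed, "plasmolysed_outline.tsv")
    emit(pair$turgid, "turgid_outline.tsv")
    emit(list(E_over_P = est$E_over_P, nu = est$nu,
              residual_um = attr(est, "residual")),
         "elastic_fit.json", "json")
    stage_out$elasticity <- est
  }
  if ("growth" %in% cfg$stages) {
    p <- elastic_params(40, 0.3)
    sim <- simulate_end_evolution(cap_cylinder_meridian(2, flank = 4, n = 41),
                                  canonical_incorporation(), p,
                                  steps = cfg$growth_steps,
                                  record_every = max(1L, cfg$growth_steps %/% 10))
    emit(as.data.frame(sim$final), "growth_final_meridian.tsv")
    kym <- as.data.frame(sim$kymograph$kappa)
    names(kym) <- sprintf("step%03d", sim$kymograph$time_min)
    emit(cbind(s_um = sim$kymograph$s_um, kym), "growth_kymograph.tsv")
    plot_kymograph(sim$kymograph, file.path(out_dir, "growth_kymograph.png"))
    outputs <- c(outputs, "growth_kymograph.png")
    stage_out$growth <- sim
  }
  if ("profiles" %in% cfg$stages) {
    fam <- list(narrow = list(family = "gaussian", params = list(sigma = 0.8)),
                broad = list(family = "cosine_power",
                             params = list(W = 3.5, p = 1)))
    conditioned <- list()
    for (nm in names(fam)) {
      raw <- synth_fluorescence_profiles(fam[[nm]]$family, fam[[nm]]$params,
                                         n_cells = 1, n_frames = 5,
                                         scenario = sc)
      conditioned[[nm]] <- condition_profile(raw[[1]])
      emit(conditioned[[nm]], sprintf("profile_%s.tsv", nm))
    }
    widths <- data.frame(
      marker = names(conditioned),
      fwha = vapply(conditioned, central_width, 0, fraction = 0.5),
      fw95a = vapply(conditioned, central_width, 0, fraction = 0.95))
    emit(widths, "profile_widths.tsv")
    dend <- compare_and_cluster_markers(conditioned, "width_features")
    writeLines(dend$newick, file.path(out_dir, "markers.nwk"))
    outputs <- c(outputs, "markers.nwk")
    stage_out$profiles <- list(widths = widths, dendrogram = dend)
  }
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, pretty = TRUE)
  manifest <- list(config = cfg,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   seed = cfg$seed,
                   outputs = c("config.json", outputs),
                   version = as.character(utils::packageVersion("wallmorph")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
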