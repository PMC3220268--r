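## Config handling: a run config is a plain named list (or a YAML file that
## parses to one). Selections in config are lists with any of
## chains / ranges / atom_names / element_class.

config_selection <- function(x) {
  if (inherits(x, "atom_selection")) return(x)
  ranges <- x$ranges
  if (!is.null(ranges) && !is.list(ranges)) ranges <- list(ranges)
  if (!is.null(ranges)) ranges <- lapply(ranges, as.numeric)
  atom_selection(chains = x$chains, ranges = ranges,
                 atom_names = if (is.null(x$atom_names)) "ANY" else x$atom_names,
                 element_class = if (is.null(x$element_class)) "ALL" else x$element_class)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      abort("arpdyn_config_error", "config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("arpdyn_config_error", "config must be a list or YAML path")
  config
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

## Tidy CSV with a provenance comment line so outputs are self-describing.
write_tidy_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# arpdyn config_md5=%s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

hist_to_df <- function(h) {
  k <- length(h$counts)
  data.frame(bin_lo = h$bin_edges[seq_len(k)], bin_hi = h$bin_edges[-1L],
             count = h$counts, density = h$density)
}

load_config_trajectory <- function(cfg) {
  inp <- cfg$input
  if (is.null(inp)) abort("arpdyn_config_error", "config lacks an 'input' section")
  if (!is.null(inp$synthetic)) {
    s <- inp$synthetic
    spec <- traj_sim_spec(
      n_atoms_fixed = s$n_atoms_fixed %||% 40L,
      n_atoms_mobile = s$n_atoms_mobile %||% 40L,
      rotation_axis = s$rotation_axis %||% c(0, 0, 1),
      angle_schedule = s$angle_schedule %||% seq(0, 30, length.out = 101L),
      axis_offset = s$axis_offset %||% 20,
      noise_sd = s$noise_sd %||% 0.5,
      dt_ps = s$dt_ps %||% 10,
      geometry_seed = s$geometry_seed %||% 1L)
    sim <- simulate_reorientation_traj(spec, seed = cfg$seed %||% 1L)
    return(sim$traj)
  }
  if (!is.null(inp$pdb)) {
    if (!file.exists(inp$pdb))
      abort("arpdyn_config_error", "input PDB not found: %s", inp$pdb)
    return(read_pdb(inp$pdb, dt_ps = inp$dt_ps %||% 1))
  }
  if (!is.null(inp$table)) {
    if (!file.exists(inp$table))
      abort("arpdyn_config_error", "input trajectory not found: %s", inp$table)
    return(read_table_traj(inp$table, n_atoms = inp$n_atoms,
                           dt_ps = inp$dt_ps %||% 1))
  }
  abort("arpdyn_config_error", "input must supply 'synthetic', 'pdb' or 'table'")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

first_frame_structure <- function(traj) {
  md_structure(traj$topology$atoms, frame_xyz(traj, 1L))
}

#' Run the trajectory-geometry analysis track
#'
#' Config-driven orchestration of the structural analyses: aligned RMSD
#' series and distribution against the initial (and optionally a surrogate
#' active) reference, per-residue RMSD profile, inter-subunit contact
#' series and distribution, salt-bridge minimum-distance series and pooled
#' distributions, and coordinate PCA (scree, projections, porcupine
#' vectors). All outputs are tidy CSVs under `config$output_dir`, plus a
#' `manifest.json`; any stage failure removes partial outputs and aborts
#' with the stage name.
#'
#' @param config a named list or path to a YAML file. Recognised sections:
#'   `input` (one of `synthetic`, `pdb`, `table`), `selections` (named
#'   `align` and `measure` selection configs), `window`
#'   (`t_start`/`t_end`/`stride`), `contacts`
#'   (`group_a`/`group_b`/`cutoff`/`stride`), `salt_bridges` (list of
#'   donor/acceptor selection configs with labels), `pca` (`enable`,
#'   `npcs`), `active_transform` (`axis`, `angle_deg`, `translation`),
#'   `output_dir`, `seed`.
#' @return invisibly, a manifest list (`outputs`, `config_md5`, summary
#'   values).
#' @export
run_trajectory_track <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$output_dir)) abort("arpdyn_config_error", "config lacks 'output_dir'")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  written <- character()
  emit <- function(df, name) {
    p <- file.path(cfg$output_dir, name)
    write_tidy_csv(df, p, hash)
    written <<- c(written, p)
    p
  }
  stage <- "validate"
  result <- tryCatch({
    traj <- local({stage <<- "load"; load_config_trajectory(cfg)})

    stage <- "validate"
    if (is.null(cfg$selections$align) || is.null(cfg$selections$measure))
      abort("arpdyn_config_error", "config needs selections$align and selections$measure")
    align_sel <- config_selection(cfg$selections$align)
    measure_sel <- config_selection(cfg$selections$measure)
    resolve_selection(align_sel, traj$topology)
    resolve_selection(measure_sel, traj$topology)

    reference <- first_frame_structure(traj)
    if (!is.null(cfg$window)) {
      stage <- "window"
      traj <- traj_window(traj, cfg$window$t_start, cfg$window$t_end,
                          cfg$window$stride %||% 1L)
    }

    stage <- "rmsd"
    series_init <- aligned_rmsd_series(traj, reference, align_sel, measure_sel,
                                       reference_tag = "INITIAL")
    emit(as.data.frame(series_init), "rmsd_series_initial.csv")
    emit(hist_to_df(rmsd_distribution(series_init)), "rmsd_hist_initial.csv")

    summary_vals <- list(mean_rmsd_initial = mean(series_init$values))

    if (!is.null(cfg$active_transform)) {
      tr <- cfg$active_transform
      rot <- rotation_about_axis(tr$axis %||% c(0, 0, 1), tr$angle_deg %||% 0)
      ctr <- tr$center %||% colMeans(reference$xyz[resolve_selection(measure_sel, reference), , drop = FALSE])
      tf <- rigid_transform(rot, as.numeric(ctr) - as.vector(rot %*% as.numeric(ctr)) +
                              (tr$translation %||% c(0, 0, 0)))
      active <- make_active_surrogate(reference, measure_sel, tf)
      series_act <- aligned_rmsd_series(traj, active, align_sel, measure_sel,
                                        reference_tag = "ACTIVE")
      emit(as.data.frame(series_act), "rmsd_series_active.csv")
      emit(hist_to_df(rmsd_distribution(series_act)), "rmsd_hist_active.csv")
      summary_vals$mean_rmsd_active <- mean(series_act$values)
    }

    stage <- "per_residue_rmsd"
    prr <- per_residue_rmsd(traj, reference, align_sel, measure_sel)
    emit(as.data.frame(prr), "per_residue_rmsd.csv")

    if (!is.null(cfg$contacts)) {
      stage <- "contacts"
      cspec <- contact_spec(config_selection(cfg$contacts$group_a),
                            config_selection(cfg$contacts$group_b),
                            cutoff = cfg$contacts$cutoff %||% 3.5)
      cser <- contact_series(traj, cspec, stride = cfg$contacts$stride %||% 1L)
      emit(as.data.frame(cser), "contact_series.csv")
      emit(hist_to_df(histogram_result(cser$counts,
                                       bins = cfg$contacts$bins %||% 50L)),
           "contact_hist.csv")
      summary_vals$mean_contacts <- mean(cser$counts)
    }

    if (!is.null(cfg$salt_bridges)) {
      stage <- "salt_bridges"
      all_series <- list()
      rows <- list()
      for (sb in cfg$salt_bridges) {
        spec <- pair_distance_spec(config_selection(sb$donor),
                                   config_selection(sb$acceptor),
                                   label = sb$label %||% "pair")
        ser <- distance_series(traj, spec, stride = sb$stride %||% 1L)
        all_series[[spec$label]] <- ser
        rows[[spec$label]] <- as.data.frame(ser)
      }
      emit(do.call(rbind, rows), "saltbridge_series.csv")
      hists <- lapply(names(all_series), function(lb) {
        df <- hist_to_df(distance_distribution(all_series[[lb]]))
        df$label <- lb
        df
      })
      emit(do.call(rbind, hists), "saltbridge_hist.csv")
    }

    if (isTRUE(cfg$pca$enable %||% TRUE)) {
      stage <- "pca"
      model <- fit_pca(traj, align_sel, measure_sel, reference)
      npcs <- min(cfg$pca$npcs %||% 10L, length(model$lambda))
      emit(variance_fractions(model, npcs), "pca_scree.csv")
      proj <- project_frames(traj, model, pcs = seq_len(min(2L, npcs)),
                             reference = reference)
      emit(as.data.frame(proj), "pca_projection.csv")
      porc <- porcupine(model, 1L, scale_sd = 1)
      ## two-model PDB (base, tip) for external visualisation
      ca_sel <- measure_sel; ca_sel$element_class <- "CA"
      ca_idx <- resolve_selection(ca_sel, traj$topology)
      porc_topo <- md_structure(traj$topology$atoms[ca_idx, ], porc$base)
      porc_traj <- md_trajectory(
        porc_topo, rbind(xyz_flatten(porc$base), xyz_flatten(porc$tip)), c(0, 1))
      pdb_path <- file.path(cfg$output_dir, "pca_porcupine.pdb")
      write_pdb(porc_traj, pdb_path)
      written <- c(written, pdb_path)
      emit(data.frame(chain = porc$atom_keys$chain, resno = porc$atom_keys$resno,
                      base_x = porc$base[, 1], base_y = porc$base[, 2],
                      base_z = porc$base[, 3], tip_x = porc$tip[, 1],
                      tip_y = porc$tip[, 2], tip_z = porc$tip[, 3],
                      length_A = porc$lengths),
           "pca_porcupine.csv")
      summary_vals$pc1_fraction <- variance_fractions(model, 1L)$fraction[1L]
    }

    stage <- "manifest"
    manifest <- list(track = "trajectory", config_md5 = hash,
                     outputs = basename(written), summary = summary_vals)
    jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }, arpdyn_error = function(e) {
    unlink(written)
    abort("arpdyn_pipeline_error", "stage '%s' failed: %s", stage,
          conditionMessage(e))
  })
  invisible(result)
}

#' Run the assembly-kinetics analysis track
#'
#' For each configured curve (a CSV of `time_s`,`signal_AU` or a synthetic
#' spec), converts fluorescence to polymer concentration, extracts the
#' half-time and the assembly rate at the configured polymerized fraction,
#' and inverts R = k+[A][E] to a filament-end concentration; writes the
#' per-curve results, the ends-vs-concentration table, and optionally a
#' pointed-end Kd fit.
#'
#' @param config list or YAML path. Sections: `curves` (list; each with
#'   either `file` + `calibration` (`f_baseline`,`f_plateau`,
#'   `critical_conc`) + `total_actin`, or `synthetic`
#'   (curve_sim_spec fields), plus `arp_conc_nM` and optional `seed`),
#'   `kinetics` (`k_plus`, `rate_fraction`, `slope_window`), `pointed_end`
#'   (optional: `conc`, `rate` vectors), `output_dir`, `seed`.
#' @return invisibly, a manifest list.
#' @export
run_kinetics_track <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$output_dir)) abort("arpdyn_config_error", "config lacks 'output_dir'")
  if (!length(cfg$curves)) abort("arpdyn_config_error", "config lists no curves")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  written <- character()
  emit <- function(df, name) {
    p <- file.path(cfg$output_dir, name)
    write_tidy_csv(df, p, hash)
    written <<- c(written, p)
    p
  }
  stage <- "validate"
  result <- tryCatch({
    kc <- cfg$kinetics
    kcfg <- kinetics_config(k_plus = kc$k_plus %||% 10,
                            rate_fraction = kc$rate_fraction %||% 0.8,
                            slope_window = kc$slope_window %||% 0.05)
    stage <- "curves"
    results <- list()
    rows <- list()
    for (i in seq_along(cfg$curves)) {
      cc <- cfg$curves[[i]]
      if (!is.null(cc$synthetic)) {
        s <- cc$synthetic
        spec <- curve_sim_spec(
          filament_ends = s$filament_ends,
          total_actin = s$total_actin %||% 4,
          critical_conc = s$critical_conc %||% 0,
          k_plus = s$k_plus %||% kcfg$k_plus,
          f_baseline = s$f_baseline %||% 0, f_plateau = s$f_plateau %||% 1,
          duration = s$duration %||% 3000, dt = s$dt %||% 1)
        sim <- simulate_assembly_curve(spec, seed = cc$seed %||% cfg$seed %||% 1L)
        curve <- sim$curve; cal <- sim$calibration
      } else if (!is.null(cc$file)) {
        if (!file.exists(cc$file))
          abort("arpdyn_config_error", "curve file not found: %s", cc$file)
        tab <- utils::read.csv(cc$file, comment.char = "#")
        curve <- assembly_curve(tab[[1L]], tab[[2L]],
                                total_actin = cc$total_actin %||% 4)
        cal <- curve_calibration(cc$calibration$f_baseline,
                                 cc$calibration$f_plateau,
                                 cc$calibration$critical_conc %||% 0.1)
      } else abort("arpdyn_config_error", "curve %d has neither 'file' nor 'synthetic'", i)
      res <- analyze_assembly_curve(curve, cal, kcfg,
                                    arp_conc = cc$arp_conc_nM %||% NA_real_)
      results[[i]] <- res
      rows[[i]] <- data.frame(curve = i, arp_conc_nM = res$arp_conc_nM,
                              t_half_s = res$t_half, rate_nM_s = res$rate_nM_s,
                              filament_ends_nM = res$filament_ends_nM,
                              censored = res$censored)
    }
    per_curve <- do.call(rbind, rows)
    emit(per_curve, "curve_results.csv")

    summary_vals <- list(n_curves = length(results))
    ok <- !vapply(results, function(r) r$censored, TRUE)
    if (sum(ok) >= 1L) {
      stage <- "ends_table"
      ends_tab <- ends_vs_concentration(results[ok])
      emit(ends_tab, "ends_vs_concentration.csv")
      summary_vals$max_fold_change <- max(ends_tab$fold_change, na.rm = TRUE)
    }

    if (!is.null(cfg$pointed_end)) {
      stage <- "pointed_end"
      fit <- fit_pointed_end_kd(as.numeric(cfg$pointed_end$conc),
                                as.numeric(cfg$pointed_end$rate))
      emit(data.frame(kd = fit$kd, rate_free = fit$rate_free,
                      rate_bound = fit$rate_bound,
                      identifiable = fit$identifiable),
           "pointed_end_fit.csv")
      summary_vals$kd <- fit$kd
    }

    stage <- "manifest"
    manifest <- list(track = "kinetics", config_md5 = hash,
                     outputs = basename(written), summary = summary_vals)
    jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }, arpdyn_error = function(e) {
    unlink(written)
    abort("arpdyn_pipeline_error", "stage '%s' failed: %s", stage,
          conditionMessage(e))
  })
  invisible(result)
}
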