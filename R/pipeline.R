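#' Pipeline run configuration
#'
#' One serializable object carrying every knob of a full analysis run; its
#' hash and seed are echoed into the provenance header of every output file
#' so results can be traced back to the configuration that produced them.
#'
#' @param seed Global seed; all randomness in a run flows from it.
#' @param lattice_radius Rings of the column lattice (1 = seven columns).
#' @param template A [circuit_template()] (or named overrides list).
#' @param truncation_box Optional named `xmin..zmax` box applied after
#'   generation.
#' @param min_synapses Per-connection threshold for per-column maps and
#'   subfields.
#' @param region_breaks Base/shaft/tip boundaries on normalized dendritic
#'   position.
#' @param snap_radius_um Synapse-to-skeleton attachment radius.
#' @param emd `list(tau, gain, dt, speeds)` for the detector stage.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, lattice_radius = 1L,
                       template = circuit_template(),
                       truncation_box = NULL, min_synapses = 2L,
                       region_breaks = c(1 / 3, 2 / 3), snap_radius_um = 2,
                       emd = list(tau = 0.15, gain = 1, dt = 0.002,
                                  speeds = c(0.5, 1, 2, 5)),
                       out_dir = "t4_run") {
  if (!inherits(template, "circuit_template")) {
    template <- do.call(circuit_template, as.list(template))
  }
  structure(list(seed = as.integer(seed),
                 lattice_radius = as.integer(lattice_radius),
                 template = template, truncation_box = truncation_box,
                 min_synapses = min_synapses, region_breaks = region_breaks,
                 snap_radius_um = snap_radius_um, emd = emd,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path File path.
#' @rdname run_config_io
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[setdiff(names(raw), "template")]
  cfg <- do.call(run_config, args)
  if (!is.null(raw$template)) {
    tpl <- raw$template
    # YAML turns named numeric vectors into lists; restore them
    for (f in c("fractions", "signs", "field_offset_units")) {
      if (!is.null(tpl[[f]])) tpl[[f]] <- unlist(tpl[[f]])
    }
    if (!is.null(tpl$weight_maps)) {
      tpl$weight_maps <- lapply(tpl$weight_maps, as.data.frame)
    }
    cfg$template <- do.call(circuit_template, tpl)
  }
  cfg
}

#' @param config A `run_config`.
#' @rdname run_config_io
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  out$template <- unclass(out$template)
  # yaml drops names of atomic vectors; store the named ones as maps
  for (f in c("fractions", "signs", "field_offset_units")) {
    out$template[[f]] <- as.list(out$template[[f]])
  }
  out$template$weight_maps <- lapply(out$template$weight_maps, as.list)
  yaml::write_yaml(out, path)
  invisible(path)
}

stage_dir <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  config$out_dir
}

json_out <- function(x, path, config) {
  x$provenance <- list(seed = config$seed, config = config_hash(config))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Pipeline stage: generate a synthetic dataset
#'
#' Generates the seeded synthetic connectome (optionally truncating it at
#' the configured box) and writes `neurons.tsv`, `synapses.tsv`,
#' `lattice.tsv`, one SWC per skeleton and a JSON manifest, each carrying
#' the config hash and seed.
#'
#' @param config A [run_config()].
#' @return The generated [connectome()] (invisibly writes files).
#' @export
cmd_generate <- function(config) {
  out <- stage_dir(config)
  prov <- provenance_line(config)
  ds <- make_circuit(config$template, make_lattice(config$lattice_radius),
                     seed = config$seed)
  if (!is.null(config$truncation_box)) {
    ds <- truncate_connectome(ds, unlist(config$truncation_box))
  }
  write_neuron_table(ds$neurons, file.path(out, "neurons.tsv"), prov)
  write_synapse_table(ds$synapses, file.path(out, "synapses.tsv"), prov)
  write_lattice(ds$lattice, file.path(out, "lattice.tsv"), prov)
  skel_dir <- file.path(out, "skeletons")
  dir.create(skel_dir, showWarnings = FALSE)
  for (id in names(ds$skeletons)) {
    write_swc(ds$skeletons[[id]],
              file.path(skel_dir, paste0(gsub("[:,]", "_", id), ".swc")),
              prov)
  }
  json_out(list(volume_bounds = as.list(ds$volume_bounds),
                column_spacing_um = ds$column_spacing_um,
                n_neurons = nrow(ds$neurons),
                n_synapses = nrow(ds$synapses),
                skeletons = names(ds$skeletons)),
           file.path(out, "manifest.json"), config)
  invisible(ds)
}

analysed_t4s <- function(dataset) {
  ids <- names(dataset$skeletons)
  ids[cell_type_of(dataset, ids) %in% T4_SUBTYPES]
}

#' Pipeline stage: connectivity summaries
#'
#' Writes the type-level connectivity matrix, per-T4 input fractions and
#' per-column input-count maps.
#' @param dataset A [connectome()].
#' @param config A [run_config()].
#' @return List of the computed tables, invisibly written under
#'   `config$out_dir`.
#' @export
cmd_connectivity <- function(dataset, config) {
  out <- stage_dir(config)
  prov <- provenance_line(config)
  m <- connectivity_matrix(dataset, by = "type")
  write_connectivity_matrix(m, file.path(out, "connectivity_matrix.tsv"), prov)
  t4s <- analysed_t4s(dataset)
  fr <- lapply(t4s, function(id) input_fractions(dataset, id))
  names(fr) <- t4s
  json_out(list(input_fractions = fr),
           file.path(out, "input_fractions.json"), config)
  percol <- list()
  for (t4 in t4s) {
    for (ty in c("Mi1", "Mi9", "Mi4", "C3", "CT1", "T4")) {
      pc <- per_column_counts(dataset, t4, ty,
                              min_synapses = config$min_synapses)
      if (nrow(pc)) percol[[paste(t4, ty, sep = "|")]] <-
          cbind(t4_id = t4, pre_type = ty, pc)
    }
  }
  percol_df <- do.call(rbind, c(percol, list(make.row.names = FALSE)))
  con <- file(file.path(out, "per_column_counts.tsv"), "w")
  writeLines(paste0("# ", prov), con)
  utils::write.table(percol_df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(list(matrix = m, fractions = fr, per_column = percol_df))
}

#' Pipeline stage: anatomical subfields and offsets
#'
#' Writes the per-(T4, type) subfield offset table and, where Tm3 and Mi1
#' L1-based centres are computable, the raw and completeness-adjusted
#' Tm3-Mi1 offsets.
#' @inheritParams cmd_connectivity
#' @export
cmd_subfields <- function(dataset, config) {
  out <- stage_dir(config)
  prov <- provenance_line(config)
  rep_df <- subfield_report(dataset, min_synapses = config$min_synapses)
  tm3 <- list()
  for (t4 in analysed_t4s(dataset)) {
    for (mode in c("raw", "adjusted")) {
      o <- tryCatch(tm3_mi1_offset(dataset, t4, mode),
                    error = function(e) NULL)
      if (!is.null(o)) {
        tm3[[paste(t4, mode)]] <- data.frame(
          t4_id = t4, pre_type = "Tm3", cx = NA, cy = NA,
          dx = o$dx, dy = o$dy, mode = mode,
          n_synapses = sum(o$tm3$n_psd))
      }
    }
  }
  rep_df <- rbind(rep_df, do.call(rbind, c(tm3, list(make.row.names = FALSE))))
  con <- file(file.path(out, "subfield_offsets.tsv"), "w")
  writeLines(paste0("# ", prov), con)
  writeLines("# adjusted mode: per-Tm3 weights are PSD count / completeness", con)
  utils::write.table(rep_df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(rep_df)
}

#' Pipeline stage: dendritic synapse maps and segregation tests
#'
#' Writes the per-synapse dendritic mapping TSV and a JSON of segregation
#' tests between the canonical base-located (Mi4) and tip-located (Mi9)
#' inputs on each analysed T4.
#' @inheritParams cmd_connectivity
#' @export
cmd_dendrites <- function(dataset, config) {
  out <- stage_dir(config)
  prov <- provenance_line(config)
  maps <- list()
  seg <- list()
  for (t4 in analysed_t4s(dataset)) {
    m <- mapped_inputs(dataset, t4, config$snap_radius_um,
                       config$region_breaks)
    maps[[t4]] <- cbind(t4_id = t4, m)
    s <- tryCatch(segregation(dataset, t4, "Mi4", "Mi9",
                              n_perm = 1000L, seed = config$seed,
                              snap_radius_um = config$snap_radius_um),
                  error = function(e) NULL)
    if (!is.null(s)) {
      seg[[t4]] <- list(pair = s$pair, index = s$index, p_value = s$p_value,
                        mean_base_type = s$mean_a, mean_tip_type = s$mean_b,
                        n = c(s$n_a, s$n_b))
    }
  }
  map_df <- do.call(rbind, c(maps, list(make.row.names = FALSE)))
  con <- file(file.path(out, "dendrite_map.tsv"), "w")
  writeLines(paste0("# ", prov), con)
  utils::write.table(map_df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  json_out(list(segregation = seg), file.path(out, "segregation.json"),
           config)
  invisible(list(map = map_df, segregation = seg))
}

#' Pipeline stage: T4-T4 selectivity audit
#' @inheritParams cmd_connectivity
#' @export
cmd_selectivity <- function(dataset, config) {
  out <- stage_dir(config)
  rep <- t4_selectivity_report(dataset)
  json_out(list(n_connections = rep$n_connections,
                n_violations = rep$n_violations,
                connections = rep$connections),
           file.path(out, "selectivity.json"), config)
  invisible(rep)
}

#' Pipeline stage: anatomy-derived motion detectors
#'
#' Builds a BL detector for each analysed T4 from its measured excitatory
#' (Mi1/Tm3-side, here Mi1) and inhibitory (Mi4/C3/CT1) subfield centres
#' and writes the DSI table over the configured speeds.
#' @inheritParams cmd_connectivity
#' @export
cmd_emd <- function(dataset, config) {
  out <- stage_dir(config)
  prov <- provenance_line(config)
  rows <- list()
  for (t4 in analysed_t4s(dataset)) {
    cfg <- tryCatch(
      anatomy_detector(dataset, t4, min_synapses = config$min_synapses,
                       tau = config$emd$tau, gain = config$emd$gain,
                       dt = config$emd$dt),
      error = function(e) NULL)
    if (is.null(cfg)) next
    tun <- direction_tuning(cfg, speeds = config$emd$speeds)
    rows[[t4]] <- cbind(t4_id = t4,
                        predicted_pd = attr(cfg, "predicted_pd"), tun)
  }
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  con <- file(file.path(out, "emd_dsi.tsv"), "w")
  writeLines(paste0("# ", prov), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(df)
}

#' Anatomy-derived BL detector for one T4
#'
#' Excitatory channel at the Mi1 subfield centre (the shaft inputs;
#' Tm3 lacks a per-column subfield), inhibitory delayed channel at the
#' synapse-count-weighted combination of the Mi4, C3 and CT1 centres.
#'
#' @param dataset A [connectome()].
#' @param t4_id Target T4.
#' @param min_synapses Per-connection threshold for the subfields.
#' @param tau,gain,dt Passed to [detector_config()].
#' @return A `detector_config` (BL) with a `predicted_pd` attribute.
#' @export
anatomy_detector <- function(dataset, t4_id, min_synapses = 2L, tau = 0.15,
                             gain = 1, dt = 0.002) {
  exc <- subfield_centre(dataset, t4_id, "Mi1", min_synapses)
  inh_types <- c("Mi4", "C3", "CT1")
  inh <- list()
  w <- numeric()
  for (ty in inh_types) {
    sf <- tryCatch(subfield_centre(dataset, t4_id, ty, min_synapses),
                   error = function(e) NULL)
    if (!is.null(sf)) {
      inh[[ty]] <- sf$centre
      w <- c(w, sf$n_synapses)
    }
  }
  if (!length(inh)) {
    stop("anatomy_detector: ", t4_id, " has no inhibitory subfield")
  }
  circuit_from_anatomy(excitatory = exc$centre, inhibitory = inh,
                       weights_inh = w, tau = tau, gain = gain, dt = dt)
}

#' Run the full pipeline and write a summary report
#'
#' generate -> validate -> connectivity -> subfields -> dendrites ->
#' selectivity -> emd -> report. Deterministic for a fixed config; the
#' summary JSON (`report.json`) carries the config hash and seed and
#' aggregates the headline quantities of every stage.
#'
#' @param config A [run_config()].
#' @return The summary list, invisibly; all outputs under `config$out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  ds <- cmd_generate(config)
  findings <- validate_connectome(ds)
  if (nrow(findings)) {
    stop("run_pipeline: generated dataset failed validation with ",
         nrow(findings), " finding(s)")
  }
  conn <- cmd_connectivity(ds, config)
  sub <- cmd_subfields(ds, config)
  den <- cmd_dendrites(ds, config)
  sel <- cmd_selectivity(ds, config)
  emd <- cmd_emd(ds, config)
  summary <- list(
    n_neurons = nrow(ds$neurons),
    n_synapses = nrow(ds$synapses),
    n_tbars = length(unique(ds$synapses$tbar_id)),
    validation_findings = nrow(findings),
    input_fractions = conn$fractions,
    selectivity = list(n_connections = sel$n_connections,
                       n_violations = sel$n_violations),
    segregation = den$segregation,
    emd = if (!is.null(emd)) split(emd[, c("speed", "dsi")], emd$t4_id)
  )
  json_out(summary, file.path(config$out_dir, "report.json"), config)
  invisible(summary)
}
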