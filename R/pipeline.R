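#' Pipeline configuration
#'
#' Collects every stage parameter and the master seed. The master seed
#' is fanned out per stage and unit via [derive_seed()], so stages can
#' be rerun independently with identical results.
#'
#' @param seed Master seed.
#' @param outdir Output directory.
#' @param n_per_group Neurons per firing-phenotype group.
#' @param n_connections Named counts of simulated connections per
#'   connection preset.
#' @param n_sweeps_per_connection Sweeps per connection.
#' @param n_drug_per_group Drug traces per neuromodulation group.
#' @param n_morph_per_archetype Morphologies per archetype.
#' @param dvdt_threshold_mv_ms AP detection criterion (mV/ms).
#' @param burst_isi_max_ms Burst ISI criterion (ms).
#' @param voxel_edge_um Density-map voxel edge (um).
#' @param smooth_sigma_um Density-map Gaussian SD (um).
#' @param isosurface_pct Density-map percentile threshold.
#' @param drug_noise_sd_mv Drug-trace noise SD (mV).
#' @param qc [qc_policy()].
#' @param stages Character vector of stages to run (subset of
#'   `"intrinsic"`, `"synaptic"`, `"pharm"`, `"morpho"`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("l6run"),
                            n_per_group = 10L,
                            n_connections = c(foxp2_pos = 16L,
                                              foxp2_neg = 13L,
                                              ct_l6b = 7L),
                            n_sweeps_per_connection = 40L,
                            n_drug_per_group = 8L,
                            n_morph_per_archetype = 4L,
                            dvdt_threshold_mv_ms = 20,
                            burst_isi_max_ms = 15,
                            voxel_edge_um = 50,
                            smooth_sigma_um = 50,
                            isosurface_pct = 80,
                            drug_noise_sd_mv = 0.3,
                            qc = qc_policy(),
                            stages = c("intrinsic", "synaptic", "pharm",
                                       "morpho")) {
  structure(as.list(environment()), class = "pipeline_config")
}

default_protocol <- function() {
  step_protocol(seq(-100, 400, by = 20), step_onset_ms = 200,
                step_duration_ms = 1000, inter_sweep_interval_s = 5)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Simulates the four firing-phenotype cohorts, the facilitating and
#' depressing connection groups, the neuromodulation cohorts and the
#' morphology archetype groups; runs every analysis stage on them; and
#' writes feature tables, connection and drug summaries, morphometric
#' records, density-map projections, group statistics, the archived
#' config and a per-stage log under `config$outdir`. Deterministic for
#' a fixed config.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    config[setdiff(names(config), "qc")],
    file.path(config$outdir, "config.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  log <- list()
  res <- list()

  if ("intrinsic" %in% config$stages) {
    proto <- default_protocol()
    groups <- c("ct_l6a", "ct_l6b", "cc_burst_rapid", "cc_multipolar_slow")
    recs <- list()
    for (g in groups) {
      for (i in seq_len(config$n_per_group)) {
        sim <- simulate_adex(g, proto,
                             seed = derive_seed(config$seed, g, i))
        rec <- tryCatch(
          extract_features(sim$sweepset, config$dvdt_threshold_mv_ms,
                           config$burst_isi_max_ms),
          error = function(e) NULL)
        if (!is.null(rec)) {
          rec$group <- g
          rec$neuron_id <- sprintf("%s_%02d", g, i)
          recs[[length(recs) + 1L]] <- rec
        }
      }
    }
    features <- do.call(rbind, lapply(recs, function(r) {
      cols <- Reduce(union, lapply(recs, names))
      r[setdiff(cols, names(r))] <- NA
      r[cols]
    }))
    write_records(features, file.path(config$outdir, "intrinsic_features.tsv"))
    write_feature_table(features,
                        file.path(config$outdir, "intrinsic_summary.tsv"))
    tests <- list()
    for (feat in c("r_in_mohm", "rheobase_pa", "ap_half_width_ms")) {
      x <- features[[feat]][features$group == "ct_l6a"]
      y <- features[[feat]][features$group == "cc_burst_rapid"]
      if (sum(!is.na(x)) > 0 && sum(!is.na(y)) > 0) {
        tr <- mann_whitney_u(x, y)
        tests[[feat]] <- data.frame(feature = feat, statistic = tr$statistic,
                                    p_value = tr$p_value, method = tr$method)
      }
    }
    stats_df <- do.call(rbind, tests)
    write_records(stats_df, file.path(config$outdir, "intrinsic_tests.tsv"))
    res$intrinsic <- list(features = features, tests = stats_df)
    log$intrinsic <- nrow(features)
  }

  if ("synaptic" %in% config$stages) {
    conn <- list()
    for (preset in names(config$n_connections)) {
      pars <- tm_preset(preset)
      for (i in seq_len(config$n_connections[[preset]])) {
        sim <- simulate_connection(pars, n_aps = 10, n_sweeps =
                                     config$n_sweeps_per_connection,
                                   seed = derive_seed(config$seed, preset, i))
        s <- connection_summary(sim$paired, pre_cell_class = preset)
        conn[[length(conn) + 1L]] <- data.frame(
          preset = preset, connection = i,
          epsp1_amplitude_mv = s$epsp1_amplitude_mv, ppr = s$ppr,
          analytic_a1 = sim$ground_truth$amplitudes_mv[1],
          analytic_ppr = sim$ground_truth$ppr)
      }
    }
    conn <- do.call(rbind, conn)
    write_records(conn, file.path(config$outdir, "connections.tsv"))
    amp_test <- ppr_test <- NULL
    if (all(c("foxp2_pos", "foxp2_neg") %in% conn$preset)) {
      amp_test <- mann_whitney_u(
        conn$epsp1_amplitude_mv[conn$preset == "foxp2_pos"],
        conn$epsp1_amplitude_mv[conn$preset == "foxp2_neg"])
      ppr_test <- mann_whitney_u(conn$ppr[conn$preset == "foxp2_pos"],
                                 conn$ppr[conn$preset == "foxp2_neg"])
    }
    res$synaptic <- list(connections = conn, amp_test = amp_test,
                         ppr_test = ppr_test)
    log$synaptic <- nrow(conn)
  }

  if ("pharm" %in% config$stages) {
    drug_groups <- list(
      l6a_ct = list(delta = 10.1, label = "ACh 30 uM"),
      l6b_ct = list(delta = 18.9, label = "ACh 30 uM"),
      l6a_cc = list(delta = -1.4, label = "ACh 30 uM"),
      l6b_cc = list(delta = 6.3, label = "ACh 30 uM"))
    rows <- list()
    for (g in names(drug_groups)) {
      for (i in seq_len(config$n_drug_per_group)) {
        pars <- drug_response_params(
          delta_vm_mv = drug_groups[[g]]$delta,
          noise_sd_mv = config$drug_noise_sd_mv)
        sim <- simulate_drug_application(pars, seed =
                                           derive_seed(config$seed, g, i),
                                         drug_label = drug_groups[[g]]$label)
        r <- delta_vm(sim$trace)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, trace = i, delta_vm_mv = r$delta_vm_mv,
          response_class = r$response_class,
          true_delta_mv = drug_groups[[g]]$delta)
      }
    }
    drugs <- do.call(rbind, rows)
    write_records(drugs, file.path(config$outdir, "drug_responses.tsv"))
    fr <- lapply(split(drugs$response_class, drugs$group), function(cl) {
      responder_fraction(as.character(cl), "depolarizing")
    })
    res$pharm <- list(responses = drugs, depol_fraction = fr)
    log$pharm <- nrow(drugs)
  }

  if ("morpho" %in% config$stages) {
    ctx <- layer_context()
    arcs <- c("upright_pc", "inverted_pc", "multipolar")
    morph_rows <- list()
    maps <- list()
    for (a in arcs) {
      amaps <- list()
      for (i in seq_len(config$n_morph_per_archetype)) {
        gen <- generate_morphology(a, ctx,
                                   seed = derive_seed(config$seed, a, i))
        norm <- normalize_thickness(gen$morphology, ctx, ctx$wm_depth_um)
        mm <- morphometrics(norm$morphology, norm$ctx)
        mm$archetype <- a
        morph_rows[[length(morph_rows) + 1L]] <- mm
        amaps[[i]] <- voxelize(norm$morphology, norm$ctx,
                               config$voxel_edge_um, "barrel_centered",
                               "dendrite")
      }
      avg <- average_group(amaps)
      sm <- smooth_map(avg, config$smooth_sigma_um)
      thr <- percentile_threshold(sm, config$isosurface_pct)
      prof <- project_map(sm, "1d_depth", ctx)
      utils::write.csv(prof, file.path(config$outdir,
                                       sprintf("density_1d_%s.csv", a)),
                       row.names = FALSE)
      maps[[a]] <- list(average = avg, smoothed = sm,
                        threshold = thr$threshold, profile_1d = prof)
    }
    morph <- do.call(rbind, morph_rows)
    write_records(morph, file.path(config$outdir, "morphometrics.tsv"))
    res$morpho <- list(records = morph, density = maps)
    log$morpho <- nrow(morph)
  }

  log_df <- data.frame(stage = names(log), n_records = unlist(log))
  write_records(log_df, file.path(config$outdir, "log.tsv"))
  invisible(res)
}
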