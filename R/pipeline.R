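# End-to-end orchestration: a demo mode running every stage on packaged
# synthetic fixtures, and a structure mode running the comparison /
# network / rigidity / RTA / ENM stages on local PDB or mmCIF files.
# All analyses are offline; fetching inputs is a separate explicit step.

# 31-bit polynomial rolling hash (config fingerprinting only)
.fnv1a <- function(s) {
  h <- 216613626
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Assemble a pipeline configuration
#'
#' @param inputs named character vector of structure paths (structure
#'   mode) or NULL (demo mode)
#' @param ligand_codes hetero residue names treated as ligands of
#'   interest (default GTP and the NAD/NAI synonyms for NADH)
#' @param site_radius ligand-neighborhood radius, Angstrom (default 3.0)
#' @param hbond_cutoff analysis H-bond cutoff, kcal/mol (default -0.5)
#' @param mutation_cutoff H-bond cutoff for mutation diffs (default -1.0)
#' @param dilution grid: c(start, stop, step) (default c(0, -2, 0.01))
#' @param gnm_cutoff,anm_cutoff ENM cutoffs, Angstrom
#' @param mutations list of `MutationSpec`s (structure mode)
#' @param out_dir output directory
#' @param seed RNG seed
#' @return `PipelineConfig` list
#' @export
pipeline_config <- function(inputs = NULL,
                            ligand_codes = c("GTP", "NAD", "NAI"),
                            site_radius = 3.0, hbond_cutoff = -0.5,
                            mutation_cutoff = -1.0,
                            dilution = c(0, -2, 0.01),
                            gnm_cutoff = 7.3, anm_cutoff = 15,
                            mutations = list(),
                            out_dir = tempfile("rigidnet_"), seed = 1) {
  stopifnot(site_radius >= 0, hbond_cutoff <= 0, mutation_cutoff <= 0,
            dilution[3] > 0, gnm_cutoff > 0, anm_cutoff > 0)
  structure(list(inputs = inputs, ligand_codes = ligand_codes,
                 site_radius = site_radius, hbond_cutoff = hbond_cutoff,
                 mutation_cutoff = mutation_cutoff, dilution = dilution,
                 gnm_cutoff = gnm_cutoff, anm_cutoff = anm_cutoff,
                 mutations = mutations, out_dir = out_dir, seed = seed),
            class = "PipelineConfig")
}

.stage <- function(bundle, name, fn) {
  res <- tryCatch(list(ok = TRUE, value = fn()),
                  error = function(e) list(ok = FALSE, error = conditionMessage(e)))
  bundle$stages[[name]] <- res
  if (!res$ok) {
    bundle$status <- "partial"
    message("stage '", name, "' failed: ", res$error)
  }
  bundle
}

.write_tsv <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the analysis pipeline
#'
#' With `config$inputs = NULL` runs the demo on synthetic fixtures
#' (helix rotation, allosteric toy RTA + AUC, framework DOF table,
#' dihedral ensemble geometry, dilution of a generated peptide). With
#' named input paths runs the structure stages on each file (first model)
#' and on consecutive pairs. Outputs are TSV/JSON under `config$out_dir`
#' plus a `manifest.json` with the package version, seed and config
#' hash. Stage failures mark the bundle "partial" and the exit code
#' nonzero.
#'
#' @param config a `PipelineConfig`
#' @return the report bundle (list), invisibly; `$status` is "complete"
#'   or "partial", `$exit_code` 0 or 1
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- function(...) file.path(config$out_dir, ...)
  bundle <- list(status = "complete", stages = list(), out_dir = config$out_dir)
  demo <- is.null(config$inputs)
  if (demo) {
    bundle <- .stage(bundle, "helix_rotation", function() {
      hx <- gen_ideal_helix(20, rotation = 20.1)
      rot <- helix_rotation_angle(hx$reference, hx$transformed,
                                  hx$helix_residues, hx$core_residues)
      fit <- superpose(hx$reference, hx$transformed,
                       residues = hx$core_residues)
      prof <- per_residue_ca_rmsd(hx$reference, hx$transformed, fit)
      .write_tsv(prof, od("helix_ca_rmsd.tsv"))
      .write_json(list(angle = rot$angle, sense = rot$sense,
                       core_rmsd = fit$rmsd), od("helix_rotation.json"))
      list(angle = rot$angle, sense = rot$sense)
    })
    bundle <- .stage(bundle, "rta_toy", function() {
      toy <- gen_allosteric_toy(2, seed = config$seed)
      tr <- rta_transmission(toy$network, toy$siteA, toy$siteB)
      prof <- rta_scan_profile(toy$network, toy$siteB)
      .write_tsv(prof, od("rta_profile.tsv"))
      idx <- seq_len(nrow(prof))
      auc <- allosteric_auc(idx, ifelse(is.na(prof$intensity), 0,
                                        prof$intensity))
      hs <- call_hotspots(prof)
      .write_json(list(transmitted = tr$transmitted, auc = auc$value,
                       hotspots = hs), od("rta_summary.json"))
      list(transmitted = tr$transmitted, auc = auc$value)
    })
    bundle <- .stage(bundle, "frameworks", function() {
      rows <- lapply(list(c("chain", 7), c("ring", 6), c("tree", 8)),
                     function(sp) {
        fw <- gen_body_bar_framework(sp[1], as.integer(sp[2]),
                                     seed = config$seed)
        pg <- pebble_game_dof(fw$network)
        data.frame(topology = sp[1], n_bodies = as.integer(sp[2]),
                   expected_dof = fw$expected_internal_dof,
                   computed_dof = pg$internal_dof,
                   redundant = pg$redundant_bars)
      })
      df <- do.call(rbind, rows)
      .write_tsv(df, od("framework_dof.tsv"))
      df
    })
    bundle <- .stage(bundle, "transition_geometry", function() {
      n_res <- 9; n_frames <- 40
      phi <- matrix(seq(-120, 120, length.out = n_frames), n_res, n_frames,
                    byrow = TRUE)
      gen <- gen_dihedral_ensemble(n_frames, phi, cosine_amplitude = 6,
                                   noise_sd = 0.3, seed = config$seed)
      rec <- peptide_geometry(gen$ensemble)
      .write_tsv(rec, od("peptide_geometry.tsv"))
      zone <- transition_zone_scan(rec)
      .write_tsv(zone, od("transition_zone.tsv"))
      fit <- fit_distortion_models(rec, "angle_C1_N_CA", "cosine_in_phi")
      .write_json(list(model = fit$model,
                       coefficients = as.list(fit$coefficients),
                       r_squared = fit$r_squared), od("distortion_fit.json"))
      list(amplitude = unname(fit$coefficients["I"]), r2 = fit$r_squared)
    })
    bundle <- .stage(bundle, "dilution", function() {
      gen <- gen_dihedral_ensemble(1, matrix(-57, 12, 1), psi = -47,
                                   seed = config$seed)
      m <- add_polar_hydrogens(gen$ensemble$frames[[1]])
      ds <- dilution_series(m, start = 0, stop = -2, step = 0.1)
      .write_tsv(ds, od("dilution_series.tsv"))
      ds
    })
  } else {
    models <- lapply(config$inputs, read_structure)
    for (nm in names(models)) {
      m <- models[[nm]]
      bundle <- .stage(bundle, paste0("rigidity_", nm), function() {
        mh <- if (any(m$element == "H")) m else add_polar_hydrogens(m)
        net <- build_constraint_network(mh, config$hbond_cutoff)
        dec <- rigid_clusters(net)
        write_cluster_tsv(dec, od(paste0("clusters_", nm, ".tsv")))
        ds <- dilution_series(net, config$dilution[1], config$dilution[2],
                              config$dilution[3])
        .write_tsv(ds, od(paste0("dilution_", nm, ".tsv")))
        list(lrc = dec$lrc_size, n_clusters = dec$n_clusters,
             dof = dec$internal_dof)
      })
      bundle <- .stage(bundle, paste0("enm_", nm), function() {
        gm <- gnm_modes(m, config$gnm_cutoff)
        st <- mode_stats(gm, 2)
        dom <- domain_split_hinges(gm, 2)
        .write_json(list(dispersion = st$frequency_dispersion,
                         collectivity = st$collectivity,
                         hinges = dom$hinges), od(paste0("gnm_", nm, ".json")))
        st
      })
      bundle <- .stage(bundle, paste0("interactions_", nm), function() {
        mh <- if (any(m$element == "H")) m else add_polar_hydrogens(m)
        rin <- interaction_network(mh)
        .write_tsv(rin, od(paste0("interactions_", nm, ".tsv")))
        nrow(rin)
      })
      ligs <- ligand_keys(m)
      lig_names <- vapply(ligs, function(k)
        m$res_name[residue_atom_idx(m, k)[1]], "")
      wanted <- ligs[lig_names %in% config$ligand_codes]
      if (length(wanted) >= 1) {
        bundle <- .stage(bundle, paste0("rta_", nm), function() {
          mh <- if (any(m$element == "H")) m else add_polar_hydrogens(m)
          net <- build_constraint_network(mh, config$hbond_cutoff)
          target <- site_definition(
            paste0(nm, "_site"),
            residues = select_neighborhood(mh, wanted[1],
                                           config$site_radius)$residues)
          prof <- rta_scan_profile(net, target,
                                   cutoffs = config$hbond_cutoff)
          .write_tsv(prof, od(paste0("rta_", nm, ".tsv")))
          ok <- !is.na(prof$intensity)
          auc <- if (sum(ok) >= 2)
            allosteric_auc(seq_len(sum(ok)), prof$intensity[ok])$value
          else NA_real_
          .write_json(list(auc = auc, hotspots = call_hotspots(prof)),
                      od(paste0("rta_", nm, ".json")))
          auc
        })
      }
    }
    if (length(models) >= 2) {
      nms <- names(models)
      for (k in seq_along(nms)[-1]) {
        a <- nms[1]; b <- nms[k]
        bundle <- .stage(bundle, paste0("compare_", a, "_", b), function() {
          fit <- superpose(models[[a]], models[[b]])
          prof <- per_residue_ca_rmsd(models[[a]], models[[b]], fit)
          .write_tsv(prof, od(paste0("ca_rmsd_", a, "_", b, ".tsv")))
          list(rmsd = fit$rmsd)
        })
      }
    }
    for (mu in config$mutations) {
      nm <- names(models)[1]
      bundle <- .stage(bundle, paste0("mutation_", mu$site, "_", mu$to_aa),
                       function() {
        mut <- apply_point_mutation(models[[nm]], mu)
        diffr <- rigidity_diff(models[[nm]], mut, config$mutation_cutoff)
        .write_json(list(site = diffr$site,
                         delta_lrc = diffr$delta_lrc_size,
                         lost_hbonds = diffr$lost_hbonds,
                         gained_hbonds = diffr$gained_hbonds,
                         n_splits = length(diffr$split_clusters)),
                    od(paste0("mutation_", mu$site, "_", mu$to_aa, ".json")))
        diffr$delta_lrc_size
      })
    }
  }
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "mutations")],
                               auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "rigidnet",
    version = as.character(utils::packageVersion("rigidnet")),
    mode = if (demo) "demo" else "structures",
    seed = config$seed,
    config_hash = .fnv1a(as.character(cfg_json)),
    config = jsonlite::fromJSON(cfg_json),
    status = bundle$status,
    stages = lapply(bundle$stages, function(s)
      if (s$ok) "ok" else paste("error:", s$error)))
  .write_json(manifest, od("manifest.json"))
  bundle$exit_code <- if (bundle$status == "complete") 0L else 1L
  invisible(bundle)
}
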