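#' Default pipeline configuration
#'
#' Every tunable of the staged pipeline with its default; user configs
#' (YAML or list) override these keys.  The effective merged configuration
#' is written to the output directory of every run together with the seed,
#' so any output file traces back to the exact configuration that produced
#' it.
#'
#' @return Nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    stages = c("synth", "refine", "analyze"),
    output_dir = "epsrlite_run",
    seed = 1,
    system = list(template = "NIF", conformer = "alpha", n_molecules = 16,
                  density = 0.09, temperature_K = 300),
    synth = list(noise_sigma = 0.005, q_min = 0.6, q_max = 25.0, dq = 0.02,
                 n_snapshots = 10, stride = 5, max_sweeps = 200),
    compress = list(target_fsdp_height = NULL, window = c(0.6, 2.0),
                    equil_sweeps = 30, max_steps = 40),
    refine = list(target = NULL, n_iterations = 10, sweeps_per_iter = 10,
                  ensemble_size = 50, ensemble_stride = 2, use_scale = FALSE,
                  nh_o_min = 2.9),
    analyze = list(d_max = 3.5, angle_min = 120, r_cut = 5),
    crystal = list(cif = NULL, supercell = c(3, 3, 3),
                   donor_element = "N", acceptor_element = "O"),
    scan_conformers = list(fractions = c(0, 0.1, 0.2, 0.3),
                           conformer_b = "flipped", n_iterations = 4,
                           ensemble_size = 20)
  )
}

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

.validate_config <- function(cfg) {
  known <- c("synth", "build", "compress", "refine", "analyze", "crystal",
             "scan_conformers")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop("config error in 'stages': unknown stage(s) ",
                        paste(bad, collapse = ", "))
  if (!is.numeric(cfg$system$density) || cfg$system$density <= 0)
    stop("config error in 'system$density': must be positive")
  if (cfg$system$n_molecules < 1)
    stop("config error in 'system$n_molecules': must be >= 1")
  fr <- cfg$scan_conformers$fractions
  if (any(fr < 0 | fr > 1))
    stop("config error in 'scan_conformers$fractions': values must lie in [0, 1]")
  invisible(cfg)
}

.pipeline_template <- function(cfg) {
  switch(cfg$system$template,
         NIF = nif_template(cfg$system$conformer),
         FEL = fel_template(cfg$system$conformer),
         PVP = build_pvp_oligomer(5),
         stop("config error in 'system$template': unknown template ",
              cfg$system$template))
}

#' Run the staged pipeline
#'
#' Executes the requested stages in order (`synth` | `build` | `compress` |
#' `refine` | `analyze` | `crystal` | `scan_conformers`), writing each
#' stage's outputs plus provenance (merged config, seed, package version)
#' into the output directory.  Stage errors propagate as R errors.
#'
#' @param config A YAML file path or a nested list overriding
#'   [default_run_config()] keys.
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .validate_config(.merge_config(default_run_config(), config))
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(out, "config_used.yaml"))
  writeLines(c(sprintf("seed: %d", cfg$seed),
               sprintf("package: epsrlite %s",
                       as.character(utils::packageVersion("epsrlite"))),
               sprintf("R: %s", R.version.string)),
             file.path(out, "provenance.txt"))
  ff <- reference_forcefield()
  tpl <- .pipeline_template(cfg)
  state <- list()
  set.seed(cfg$seed)
  for (stage in cfg$stages) {
    message("stage: ", stage)
    if (stage == "synth") {
      spec <- synthetic_spec(tpl, n_molecules = cfg$system$n_molecules,
                             density = cfg$system$density,
                             temperature_K = cfg$system$temperature_K,
                             noise_sigma = cfg$synth$noise_sigma,
                             q_min = cfg$synth$q_min, q_max = cfg$synth$q_max,
                             dq = cfg$synth$dq, forcefield = ff,
                             seed = cfg$seed)
      fluid <- generate_reference_fluid(spec,
                                        n_snapshots = cfg$synth$n_snapshots,
                                        stride = cfg$synth$stride,
                                        max_sweeps = cfg$synth$max_sweeps)
      pe <- make_pseudo_experiment(fluid)
      write_sq(pe$pattern, file.path(out, "pseudo_experiment_sq.dat"))
      writeLines(sprintf("true_density_atoms_A3: %.6f", pe$truth$density),
                 file.path(out, "ground_truth.txt"))
      state$target <- pe$pattern
      state$config <- fluid$config
    } else if (stage == "build") {
      state$config <- build_configuration(tpl,
                                          n_molecules = cfg$system$n_molecules,
                                          density = cfg$system$density,
                                          temperature_K = cfg$system$temperature_K,
                                          seed = cfg$seed)
      write_config_xyz(state$config, file.path(out, "starting_box.xyz"))
    } else if (stage == "compress") {
      if (is.null(cfg$compress$target_fsdp_height))
        stop("config error in 'compress$target_fsdp_height': required for the compress stage")
      if (is.null(state$config)) stop("compress stage needs a configuration (run build or synth first)")
      cp <- compress_box(state$config, ff, cfg$compress$target_fsdp_height,
                         window = cfg$compress$window,
                         equil_sweeps = cfg$compress$equil_sweeps,
                         max_steps = cfg$compress$max_steps)
      state$config <- cp$config
      write.csv(cp$trace, file.path(out, "compression_trace.csv"),
                row.names = FALSE)
    } else if (stage == "refine") {
      if (!is.null(cfg$refine$target)) state$target <- read_sq(cfg$refine$target)
      if (is.null(state$target)) stop("refine stage needs a target S(Q) (synth stage or refine$target path)")
      if (is.null(state$config))
        state$config <- build_configuration(tpl,
                                            n_molecules = cfg$system$n_molecules,
                                            density = cfg$system$density,
                                            temperature_K = cfg$system$temperature_K,
                                            seed = cfg$seed)
      cons <- nh_o_constraints(cfg$refine$nh_o_min)
      fit <- refine_to_data(state$config, ff, state$target,
                            n_iterations = cfg$refine$n_iterations,
                            constraints = cons,
                            sweeps_per_iter = cfg$refine$sweeps_per_iter,
                            ensemble_size = cfg$refine$ensemble_size,
                            ensemble_stride = cfg$refine$ensemble_stride,
                            use_scale = cfg$refine$use_scale)
      state$fit <- fit
      state$config <- fit$config
      write_sq(fit$S_model, file.path(out, "model_sq.dat"))
      write.csv(data.frame(iteration = seq_along(fit$r_history),
                           r_factor = fit$r_history),
                file.path(out, "r_factor_history.csv"), row.names = FALSE)
      write_config_xyz(fit$config, file.path(out, "refined_box.xyz"))
    } else if (stage == "analyze") {
      if (is.null(state$config)) stop("analyze stage needs a configuration")
      ps <- if (!is.null(state$fit)) state$fit$pairset else
        compute_partial_gr(state$config)
      don <- "N_NHR"
      accs <- intersect(c("O_carbonyl", "O_nitro"), ps$types)
      gtab <- data.frame(r = ps$r)
      for (b in accs) {
        key <- if (don <= b) paste(don, b, sep = ":") else paste(b, don, sep = ":")
        if (!is.null(ps$g[[key]])) {
          gtab[[paste0("g_", b)]] <- ps$g[[key]]
          nn <- running_coordination(ps, don, b, threshold = 0.4)
          gtab[[paste0("n_", b)]] <- nn$n
        }
      }
      write.csv(gtab, file.path(out, "n_o_partials.csv"), row.names = FALSE)
      cen <- hbond_census(state$config,
                          hbond_criteria(cfg$analyze$d_max,
                                         cfg$analyze$angle_min))
      write.csv(cen$bonds, file.path(out, "hbond_census.csv"),
                row.names = FALSE)
      writeLines(c(sprintf("bonds_per_donor: %.4f", cen$per_donor),
                   sprintf("d_max_A: %.2f", cen$criteria$d_max),
                   sprintf("angle_min_deg: %.1f", cen$criteria$angle_min)),
                 file.path(out, "hbond_summary.txt"))
    } else if (stage == "crystal") {
      if (is.null(cfg$crystal$cif)) stop("config error in 'crystal$cif': path required for the crystal stage")
      cs <- parse_cif(cfg$crystal$cif)
      ct <- crystal_contacts(cs, donor_element = cfg$crystal$donor_element,
                             acceptor_element = cfg$crystal$acceptor_element,
                             supercell = cfg$crystal$supercell)
      write.csv(ct, file.path(out, "crystal_contacts.csv"), row.names = FALSE)
      writeLines(sprintf("crystal_density_g_cm3: %.4f", crystal_density(cs)),
                 file.path(out, "crystal_density.txt"))
    } else if (stage == "scan_conformers") {
      if (is.null(state$target)) stop("scan_conformers stage needs a target S(Q)")
      tplB <- switch(cfg$system$template, NIF = nif_template(cfg$scan_conformers$conformer_b),
                     FEL = fel_template("S"), stop("no alternate conformer for template"))
      sc <- scan_conformer_fraction(cfg$scan_conformers$fractions,
                                    state$target, list(tpl, tplB),
                                    n_molecules = cfg$system$n_molecules,
                                    density = cfg$system$density, ff = ff,
                                    seed = cfg$seed,
                                    temperature_K = cfg$system$temperature_K,
                                    n_iterations = cfg$scan_conformers$n_iterations,
                                    ensemble_size = cfg$scan_conformers$ensemble_size)
      write.csv(sc, file.path(out, "conformer_scan.csv"), row.names = FALSE)
    }
  }
  invisible(out)
}
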