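# End-to-end orchestration: generate a synthetic system + trajectory, run
# every analysis, and write a fixed output layout (TSV tables + JSON
# summaries with a manifest for reproducibility).

#' Preset run configurations
#'
#' The presets encode the reference compositions and caging thresholds of
#' the four study systems: two 22-bp duplexes at 20/25/30 A axis separation
#' (30 spermidine, 84 K+, 90 Cl-, 31308 water) and a 146-bp
#' nucleosome-like superhelical duplex (100 spermidine, 156 K+, 166 Cl-,
#' 50583 water; caged counts normalized by 3 for comparison against the
#' 22-bp systems).
#'
#' @param tag one of "dd20", "dd25", "dd30", "nucleosome".
#' @param n_frames,frame_dt trajectory length and frame interval (ns).
#' @param seed RNG seed.
#' @return a `"run_config"` list.
#' @export
preset_config <- function(tag = c("dd20", "dd25", "dd30", "nucleosome"),
                          n_frames = 21L, frame_dt = 25, seed = 1L) {
  tag <- match.arg(tag)
  base <- list(
    system_tag = tag,
    crit = cage_criterion(system_tag = tag),
    thresholds = conformer_thresholds(),
    dyn = dynamics_spec(p_enter = 0.05, p_exit = 0.05, noise_sigma = 0.5,
                        n_frames = n_frames, frame_dt = frame_dt,
                        seed = seed),
    fraction_caged = 0.4,
    dr = 0.1, r_cut_cn = 4.55, r_cut_dd_total = 6.4, r_cut_dd_per_P = 6.5,
    n_o_cutoff = 3.5, smoothing_window = 3L, prominence = 0.2,
    sample_interval = frame_dt, t_start = 0, normalization = 1,
    traj_format = "pdb", seed = seed
  )
  if (tag == "nucleosome") {
    base$superhelix <- superhelix_spec()
    base$n_polyamine <- 100L
    base$n_K <- 156L; base$n_Cl <- 166L; base$n_water <- 50583L
    base$box <- c(130, 130, 110)
    base$segments <- list(1:67, 80:146)
    base$normalization <- 3
  } else {
    sep <- c(dd20 = 20, dd25 = 25, dd30 = 30)[[tag]]
    base$spec <- system_spec(separation = sep)
  }
  structure(base, class = "run_config")
}

#' Generate structure, trajectory and ground-truth files for a run
#'
#' Writes `structure.pdb`, `trajectory.pdb` (or `.dcd`),
#' `ground_truth.json` (true states per frame with the generator
#' parameters and seed) and `manifest.json` into `out_dir`.
#'
#' @param config a `"run_config"` (see [preset_config()]).
#' @param out_dir output directory.
#' @param force overwrite an existing output directory.
#' @return invisibly, a list with the system, trajectory and file paths.
#' @export
run_generate <- function(config, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !force)
    stop_dnacage("output directory %s exists; use force = TRUE to overwrite",
                 out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (config$system_tag == "nucleosome") {
    sys <- build_superhelix(config$superhelix)
    sys$box <- config$box
    sys$n_K <- config$n_K; sys$n_Cl <- config$n_Cl
    sys$n_water <- config$n_water
    set.seed(config$seed)
    partners <- cage_partners(sys, config$segments)
    sys <- place_polyamines(sys, n = config$n_polyamine,
                            n_caged = round(config$fraction_caged *
                                              config$n_polyamine),
                            crit = config$crit, partners = partners)
    partners <- cage_partners(sys, config$segments)
  } else {
    sys <- assemble_two_duplex_system(config$spec, config$fraction_caged,
                                      seed = config$seed, crit = config$crit)
    partners <- cage_partners(sys)
  }
  gen <- generate_trajectory(sys, config$dyn, crit = config$crit)
  paths <- list(
    structure = file.path(out_dir, "structure.pdb"),
    trajectory = file.path(out_dir,
                           paste0("trajectory.", config$traj_format)),
    ground_truth = file.path(out_dir, "ground_truth.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_structure(sys, paths$structure)
  write_trajectory(gen$trajectory, paths$trajectory)
  jsonlite::write_json(list(
    states = unname(apply(gen$states$caged, 1L, as.integer, simplify = FALSE)),
    times = gen$states$times,
    p_enter = config$dyn$p_enter, p_exit = config$dyn$p_exit,
    noise_sigma = config$dyn$noise_sigma, seed = config$seed,
    threshold = config$crit$threshold
  ), paths$ground_truth, auto_unbox = TRUE, digits = NA)
  manifest <- config_manifest(config)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(system = sys, trajectory = gen$trajectory,
                 states = gen$states, partners = partners, paths = paths))
}

config_manifest <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  flat <- strip(config)
  js <- jsonlite::toJSON(flat, auto_unbox = TRUE, digits = NA, force = TRUE)
  list(config = flat, config_md5 = digest_string(as.character(js)))
}

digest_string <- function(s) {
  tf <- tempfile()
  writeLines(s, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

#' Analyze a generated (or external) run directory
#'
#' Reads `structure.pdb` and the trajectory from `dir`, runs the full
#' analysis battery, and writes RDF/CN TSVs, the groove-width TSV, the
#' state matrix TSV, bridge table TSV, and JSON summaries into
#' `file.path(dir, "analysis")`. When a `ground_truth.json` sidecar is
#' present, the classifier/ground-truth agreement is reported.
#'
#' @param config the `"run_config"` used to generate the run.
#' @param dir run directory produced by [run_generate()].
#' @return a list of results (also serialized as `summary.json`).
#' @export
run_analyze <- function(config, dir) {
  spath <- file.path(dir, "structure.pdb")
  tpath <- file.path(dir, paste0("trajectory.", config$traj_format))
  if (!file.exists(tpath))
    stop_dnacage("missing trajectory file %s", tpath)
  sys <- read_structure(spath)
  traj <- read_trajectory(sys, tpath, frame_dt = config$dyn$frame_dt)
  out <- file.path(dir, "analysis")
  dir.create(out, showWarnings = FALSE)
  partners <- if (config$system_tag == "nucleosome")
    cage_partners(sys, config$segments) else cage_partners(sys)

  pa_heavy <- select_region(sys, NULL, "polyamine_heavy")
  duplexes <- sys$duplexes
  d1 <- duplexes[[1L]]
  # region RDFs + total CNs against the first duplex (averaged over both
  # duplexes when two are present)
  rdfs <- list()
  for (tag in c("minor", "major", "phosphate")) {
    sel <- select_region(sys, d1, tag)
    rdfs[[tag]] <- compute_rdf(traj, pa_heavy, sel, dr = config$dr)
    tsv <- data.frame(r_mid = rdfs[[tag]]$r_mid, g = rdfs[[tag]]$g,
                      p = rdfs[[tag]]$p_counts)
    utils::write.table(tsv, file.path(out, sprintf("rdf_%s.tsv", tag)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  cn_prof <- lapply(c(minor = "minor", major = "major"), function(tag)
    per_residue_cn(traj, pa_heavy,
                   if (length(duplexes) > 1L) duplexes else d1,
                   tag, r_cut = config$r_cut_cn))
  for (tag in names(cn_prof))
    utils::write.table(cn_prof[[tag]]$profile,
                       file.path(out, sprintf("cn_%s.tsv", tag)),
                       sep = "\t", row.names = FALSE, quote = FALSE)

  dd <- NULL
  if (length(duplexes) >= 2L) {
    dd <- rdf_dd(traj, duplexes[[1L]], duplexes[[2L]],
                 r_cut_total = config$r_cut_dd_total,
                 r_cut_per_P = config$r_cut_dd_per_P, dr = config$dr)
  } else if (config$system_tag == "nucleosome") {
    d <- duplexes[[1L]]
    segP <- lapply(config$segments, function(s) {
      ids <- c(d$phos$I$P[d$phos$I$bp %in% s], d$phos$II$P[d$phos$II$bp %in% s])
      ids[!is.na(ids)]
    })
    dd <- rdf_dd(traj, segP[[1L]], segP[[2L]],
                 r_cut_total = config$r_cut_dd_total,
                 r_cut_per_P = config$r_cut_dd_per_P, dr = config$dr)
  }
  if (!is.null(dd))
    utils::write.table(dd$per_P, file.path(out, "cn_dd_per_P.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

  gw <- groove_widths(traj, d1)
  utils::write.table(gw$profile, file.path(out, "groove_widths.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  period <- minima_periodicity(gw, config$smoothing_window, config$prominence)

  st <- state_series(traj, config$crit, config$sample_interval,
                     partners = partners)
  utils::write.table(cbind(molecule = st$molecule_ids, st$caged * 1L),
                     file.path(out, "state_matrix.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  summ <- state_summary(st, normalization = config$normalization,
                        t_start = config$t_start)
  counts <- caged_count_series(st, normalization = config$normalization)
  eed <- ee_distribution(traj, st, config$thresholds)
  res <- residence_stats(st)

  bridges <- detect_bridges(frame_xyz(traj, n_frames(traj)), sys,
                            duplexes[[1L]],
                            duplexes[[min(2L, length(duplexes))]],
                            n_o_cutoff = config$n_o_cutoff)
  utils::write.table(as.data.frame(bridges),
                     file.path(out, "bridges.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  agreement <- NA_real_
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    gt_m <- if (is.matrix(gt$states)) gt$states == 1L else
      do.call(rbind, lapply(gt$states, function(s) s == 1L))
    use <- match(round(st$times, 9), round(gt$times, 9))
    agreement <- mean(gt_m[, use] == st$caged)
  }

  summary <- list(
    system_tag = config$system_tag,
    n_molecules = length(sys$polyamines),
    net_charge = total_charge(sys),
    caged_count_series = counts,
    state_summary = list(
      n_always_caged = summ$n_always_caged,
      n_always_uncaged = summ$n_always_uncaged,
      n_mixed = summ$n_mixed,
      ratio_single_to_mixed = summ$ratio_single_to_mixed,
      normalization = summ$normalization_factor, t_start = summ$t_start),
    ee_fractions = eed[c("caged", "uncaged")],
    minor_minima_spacing = period$mean_spacing,
    groove_minor_range = range(gw$minor_width, na.rm = TRUE),
    groove_major_range = range(gw$major_width, na.rm = TRUE),
    cn_dd_total = if (!is.null(dd)) dd$cn_total else NULL,
    n_bridges = nrow(bridges),
    p_exit_hat = res$p_exit_hat, p_enter_hat = res$p_enter_hat,
    ground_truth_agreement = agreement
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(c(summary, list(rdfs = rdfs, cn_profiles = cn_prof, dd = dd,
                            groove = gw, states = st)))
}
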