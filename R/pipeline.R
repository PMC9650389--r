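# Full workflow orchestration: preprocess -> parse -> charges -> fit (twice)
# -> shared grid -> potentials -> skins + cylinder -> SI matrix ->
# clustering + multiscale bootstrap -> AU flagging -> outputs.

.config_defaults <- function() {
  list(
    input = NULL,              # character vector of PDB paths, or a dir
    reference = "builtin",     # "builtin" or a PDB path
    charge_table = NULL,       # optional extra charge-table TSV
    selection = "calpha",      # atom pairing for the fit
    probe_radius = 1,          # skin probe sigma, A
    skin_thickness = 25,       # skin delta, A
    cylinder_radius = 40,      # A
    cylinder_length = 33,      # A
    cylinder_center = NULL,    # explicit placement overrides auto
    cylinder_axis = NULL,
    grid_spacing = 1,          # A
    grid_padding = 5,          # A
    dielectric = 78.4,
    ionic_strength = 0.05,     # mol/L
    temperature = 298.15,      # K
    cluster_input = "si",      # "si" or "d"
    scales = seq(0.5, 1.4, by = 0.1),
    nboot = 1000,
    seed = 1,
    au_threshold = 0.95,
    out = NULL                 # output directory; NULL = nothing written
  )
}

#' Validate and complete a run configuration
#'
#' Fills defaults, checks ranges and unit sanity, and rejects unknown keys
#' (suggesting the nearest valid key) and contradictory settings.
#'
#' @param config Named list of overrides (may be empty).
#' @return Completed configuration list of class `mep_config`.
#' @export
validate_config <- function(config = list()) {
  defaults <- .config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    hints <- vapply(unknown, function(k) {
      cand <- agrep(k, names(defaults), max.distance = 0.4, value = TRUE)
      if (length(cand) > 0) sprintf("'%s' (did you mean '%s'?)", k, cand[1])
      else sprintf("'%s'", k)
    }, character(1))
    abort(paste0("unknown config keys: ", paste(hints, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)

  chk <- function(ok, msg) if (!ok) abort(paste0("invalid config: ", msg))
  chk(cfg$probe_radius >= 0, "probe_radius must be >= 0")
  chk(cfg$skin_thickness > 0, "skin_thickness must be > 0")
  chk(cfg$cylinder_radius > 0, "cylinder_radius must be > 0")
  chk(cfg$cylinder_length > 0, "cylinder_length must be > 0")
  chk(cfg$grid_spacing > 0, "grid_spacing must be > 0")
  chk(cfg$grid_padding >= 0, "grid_padding must be >= 0")
  chk(cfg$dielectric > 0, "dielectric must be > 0")
  chk(cfg$ionic_strength >= 0, "ionic_strength must be >= 0")
  chk(cfg$temperature > 0, "temperature must be > 0")
  chk(cfg$nboot >= 1, "nboot must be >= 1")
  chk(all(cfg$scales > 0), "scales must be positive")
  chk(cfg$au_threshold >= 0 && cfg$au_threshold <= 1,
      "au_threshold must be in [0, 1]")
  chk(cfg$cluster_input %in% c("si", "d"), "cluster_input must be 'si' or 'd'")
  chk(cfg$selection %in% c("calpha", "all"),
      "selection must be 'calpha' or 'all'")
  if (xor(is.null(cfg$cylinder_center), is.null(cfg$cylinder_axis))) {
    abort(paste0("invalid config: cylinder_center and cylinder_axis must be ",
                 "given together (or both omitted for auto-placement)"))
  }
  if (!is.null(cfg$cylinder_center)) {
    chk(length(cfg$cylinder_center) == 3 && length(cfg$cylinder_axis) == 3,
        "cylinder_center and cylinder_axis must have 3 components")
  }
  structure(cfg, class = "mep_config")
}

.resolve_inputs <- function(input) {
  if (is.null(input)) abort("no input files given")
  if (length(input) == 1 && dir.exists(input)) {
    input <- sort(list.files(input, pattern = "\\.pdb$", full.names = TRUE))
  }
  missing <- input[!file.exists(input)]
  if (length(missing) > 0) {
    abort(paste0("input files not found: ", paste(missing, collapse = ", ")))
  }
  input
}

.load_reference <- function(reference) {
  if (identical(reference, "builtin")) {
    path <- system.file("extdata", "reference_synthetic.pdb",
                        package = "mepsim")
    if (nzchar(path)) {
      parse_structure(path, label = "reference")
    } else {
      reference_structure()
    }
  } else {
    parse_structure(reference, label = "reference")
  }
}

#' Run the full comparison pipeline
#'
#' Executes every stage on a set of pMHC-I PDB files and, when an output
#' directory is configured, writes `si_matrix.tsv`, `dist_matrix.tsv`,
#' `points_used.tsv`, `fit_rmsd.tsv`, `tree.nwk`, `nodes.tsv`,
#' `report.json` and `run.log`.
#'
#' @param config A config list (validated with [validate_config()]) or a
#'   ready `mep_config`.
#' @return Object of class `mep_run`: `config` (fully resolved, enough to
#'   re-run identically), `fit_rmsd`, `cylinder`, `simmat`, `ptree`,
#'   `prescreen` (advisory analytic similarity matrix), `flagged`,
#'   `log` (character vector).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "mep_config")) config else
    validate_config(config)
  logline <- character(0)
  t0 <- proc.time()[3]
  say <- function(stage, label = "-") {
    logline <<- c(logline, sprintf("[%8.2fs] %-12s %s",
                                   proc.time()[3] - t0, stage, label))
  }
  stage <- function(name, label, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed for '%s': %s", name, label,
                    conditionMessage(e)))
    })
  }

  files <- .resolve_inputs(cfg$input)
  if (length(files) < 3) {
    abort(sprintf(
      "a minimum of three input files is required (got %d)", length(files)))
  }
  reference <- .load_reference(cfg$reference)

  model <- if (is.null(cfg$charge_table)) default_charge_model() else
    default_charge_model(extra = utils::read.table(
      cfg$charge_table, header = TRUE, sep = "\t", stringsAsFactors = FALSE))

  structures <- vector("list", length(files))
  for (i in seq_along(files)) {
    lab <- sub("\\.[^.]*$", "", basename(files[i]))
    s <- stage("parse", lab, parse_structure(files[i], label = lab))
    say("parse", lab)
    structures[[i]] <- stage("charges", lab, assign_charges_radii(s, model))
    say("charges", lab)
  }

  fit <- stage("fit", "all",
               fit_all(structures, reference, selection = cfg$selection))
  for (lab in fit$rmsd$label) say("fit", lab)
  structures <- fit$structures

  cyl <- stage("cylinder", "reference", place_cylinder(
    reference, center = cfg$cylinder_center, axis = cfg$cylinder_axis,
    radius = cfg$cylinder_radius, length = cfg$cylinder_length))
  say("cylinder", sprintf("center (%.2f, %.2f, %.2f) axis (%.3f, %.3f, %.3f)",
                          cyl$center[1], cyl$center[2], cyl$center[3],
                          cyl$axis[1], cyl$axis[2], cyl$axis[3]))

  spec <- build_grid_spec(cyl, spacing = cfg$grid_spacing,
                          padding = cfg$grid_padding)
  say("grid", sprintf("%d points", spec$n))
  params <- elec_params(dielectric = cfg$dielectric,
                        ionic_strength = cfg$ionic_strength,
                        temperature = cfg$temperature)
  sp <- skin_params(probe = cfg$probe_radius,
                    thickness = cfg$skin_thickness)

  grids <- skins <- vector("list", length(structures))
  multipoles <- vector("list", length(structures))
  for (i in seq_along(structures)) {
    lab <- structure_label(structures[[i]])
    grids[[i]] <- stage("potential", lab,
                        compute_potential_grid(structures[[i]], spec, params))
    say("potential", lab)
    skins[[i]] <- stage("skin", lab,
                        compute_skin_mask(structures[[i]], spec, sp))
    say("skin", lab)
    multipoles[[i]] <- multipole_summary(structures[[i]])
  }

  cylm <- cylinder_mask(spec, cyl)
  simmat <- stage("similarity", "all", similarity_matrix(grids, skins, cylm))
  say("similarity", sprintf("%d pairs", choose(length(grids), 2)))

  # advisory analytic monopole-dipole prescreen (not used for clustering)
  n <- length(multipoles)
  pres <- diag(1, n)
  dimnames(pres) <- list(simmat$labels, simmat$labels)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pres[i, j] <- pres[j, i] <- tryCatch(
      prescreen_similarity(multipoles[[i]], multipoles[[j]]),
      error = function(e) NA_real_)
  }
  say("prescreen", "all")

  ptree <- stage("cluster", "all", cluster_with_bootstrap(
    simmat, input = cfg$cluster_input, scales = cfg$scales,
    nboot = cfg$nboot, seed = cfg$seed, au_threshold = cfg$au_threshold))
  say("cluster", sprintf("nboot %d x %d scales", cfg$nboot,
                         length(cfg$scales)))

  run <- structure(list(config = cfg,
                        fit_rmsd = fit$rmsd,
                        cylinder = cyl,
                        simmat = simmat,
                        prescreen = pres,
                        ptree = ptree,
                        flagged = significant_clusters(ptree),
                        log = logline),
                   class = "mep_run")
  if (!is.null(cfg$out)) write_run(run, cfg$out)
  run
}

#' Write all pipeline outputs
#'
#' @param run A `mep_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_labeled_matrix(run$simmat$SI, file.path(dir, "si_matrix.tsv"))
  write_labeled_matrix(run$simmat$D, file.path(dir, "dist_matrix.tsv"))
  write_labeled_matrix(run$simmat$points_used,
                       file.path(dir, "points_used.tsv"))
  utils::write.table(run$fit_rmsd, file.path(dir, "fit_rmsd.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_tree_newick(run$ptree, file.path(dir, "tree.nwk"))
  nodes <- tidy(run$ptree)
  utils::write.table(
    data.frame(node = nodes$node,
               leaves = nodes$leaves,
               height = sprintf("%.10g", nodes$height),
               au = sprintf("%.6f", nodes$au),
               bp = sprintf("%.6f", nodes$bp),
               flagged = nodes$flagged),
    file.path(dir, "nodes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  report <- list(
    version = as.character(utils::packageVersion("mepsim")),
    config = run$config[!vapply(run$config, is.null, logical(1))],
    seed = run$config$seed,
    cylinder = list(center = run$cylinder$center, axis = run$cylinder$axis,
                    radius = run$cylinder$radius,
                    length = run$cylinder$length),
    fit_rmsd = run$fit_rmsd,
    flagged_clusters = run$flagged)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(run$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.mep_run <- function(x, ...) {
  cat(sprintf("<mep_run> %d complexes, %d flagged cluster(s)\n",
              length(x$simmat$labels), length(x$flagged)))
  for (s in x$flagged) cat("  {", paste(s, collapse = ", "), "}\n")
  invisible(x)
}

#' One-row summary of a pipeline run
#' @param x A `mep_run`.
#' @param ... Unused.
#' @return Tibble: complex count, mean fit RMSD, off-diagonal SI range,
#'   flagged-cluster count, seed.
#' @export
glance.mep_run <- function(x, ...) {
  off <- x$simmat$SI[upper.tri(x$simmat$SI)]
  tibble(n_complexes = length(x$simmat$labels),
         mean_rmsd = mean(x$fit_rmsd$rmsd_pass2),
         min_si = min(off), max_si = max(off),
         n_flagged = length(x$flagged),
         seed = x$config$seed)
}

#' Tidy a pipeline run
#' @param x A `mep_run`.
#' @param ... Unused.
#' @return The tidy node table of the supported tree (see
#'   [tidy.mep_ptree()]).
#' @export
tidy.mep_run <- function(x, ...) tidy(x$ptree)
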