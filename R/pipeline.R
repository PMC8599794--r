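# Umbrella pipeline: synthesize -> melt -> restraints -> classify ->
# trajectory metrics, with JSON/TSV reports and a recorded configuration
# hash so identical configurations give identical reports.

PIPELINE_STAGES <- c("synth", "melt", "restraints", "classify", "metrics")

#' Pipeline run configuration
#'
#' @param outdir output directory (created if needed)
#' @param stages subset of \code{c("synth", "melt", "restraints",
#'   "classify", "metrics")}, executed in that canonical order
#' @param seed integer seed recorded in every report and used for all
#'   stochastic stages
#' @param sequence,end_class construct definition for the synthetic model
#' @param chi optional named chi overrides passed to
#'   \code{\link{topology_spec}}
#' @param tm_true,noise_sd,relax_rate_at_tm melting-curve generator
#'   parameters
#' @param n_frames,amplitude trajectory generator parameters
#' @return object of class \code{imclip_run_config}
#' @export
run_config <- function(outdir, stages = PIPELINE_STAGES, seed = 1L,
                       sequence = "CCCGAGA", end_class = "3'E", chi = NULL,
                       tm_true = 37, noise_sd = 0.01, relax_rate_at_tm = Inf,
                       n_frames = 200, amplitude = 0.3) {
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage name(s): ", paste(bad, collapse = ", "))
  structure(list(outdir = outdir, stages = stages, seed = as.integer(seed),
                 sequence = sequence, end_class = end_class, chi = chi,
                 tm_true = tm_true, noise_sd = noise_sd,
                 relax_rate_at_tm = relax_rate_at_tm,
                 n_frames = n_frames, amplitude = amplitude),
            class = "imclip_run_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(unclass(config)), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in order on a synthetic construct: builds
#' the idealized model, generates and analyses a heating/cooling melting
#' pair, generates NOE buildups and calibrates restraints, classifies
#' base pairs and the i-motif topology, and computes trajectory metrics
#' on a jittered ensemble. Each stage writes a JSON (and, where natural,
#' TSV/PDB) artifact into \code{config$outdir}; the combined report is
#' returned and written as \code{report.json}.
#'
#' @param config \code{\link{run_config}}
#' @return the report list, invisibly
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "imclip_run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config_hash = config_hash(config), seed = config$seed,
                 package_version = as.character(utils::packageVersion("imclip")),
                 stages = list())
  spec <- topology_spec(config$sequence, config$end_class, chi = config$chi)
  model <- build_model(spec)
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      err <- list(stage = name, error = conditionMessage(e))
      jsonlite::write_json(err, file.path(config$outdir, "error.json"),
                           auto_unbox = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    report$stages[[name]] <<- res
  }
  if ("synth" %in% config$stages) run_stage("synth", function() {
    pdb <- file.path(config$outdir, "model.pdb")
    write_structure(model, pdb)
    list(model_pdb = basename(pdb), n_atoms = nrow(model$atoms),
         sequence = paste(model$sequence, collapse = "-"))
  })
  if ("melt" %in% config$stages) run_stage("melt", function() {
    p <- thermo_params(tm_true = config$tm_true, noise_sd = config$noise_sd,
                       relax_rate_at_tm = config$relax_rate_at_tm,
                       seed = config$seed)
    heat <- generate_melting_curve(p, "heating")
    cool <- generate_melting_curve(p, "cooling")
    write_melting_csv(heat, file.path(config$outdir, "melting_heating.csv"))
    write_melting_csv(cool, file.path(config$outdir, "melting_cooling.csv"))
    fh <- melt_fit(heat); fc <- melt_fit(cool)
    hy <- hysteresis(fh$tm, fc$tm)
    list(tm = fh$tm, tren = fc$tm, hysteresis = hy$h,
         hysteresis_class = hy$class)
  })
  if ("restraints" %in% config$stages) run_stage("restraints", function() {
    prs <- model$meta$spec$purines
    pairs <- data.frame(chain1 = "A", resno1 = prs, atom1 = "H8",
                        chain2 = "B", resno2 = prs, atom2 = "H8")
    bu <- generate_noe_buildup(model, pairs, seed = config$seed)
    write_noe_csv(bu, file.path(config$outdir, "noe_buildup.csv"))
    rst <- noe_restraints(bu)
    write_restraints(rst, file.path(config$outdir, "restraints.tsv"))
    list(n_restraints = nrow(rst),
         categories = as.list(table(rst$category)))
  })
  if ("classify" %in% config$stages) run_stage("classify", function() {
    topo <- classify_topology(model)
    geoms <- lapply(topo$pairs, function(p)
      list(res1 = paste0(p$res1$chain, p$res1$resno),
           res2 = paste0(p$res2$chain, p$res2$resno),
           geometry = p$geometry, tightness = p$tightness))
    list(end_class = topo$end_class, compactness = topo$compactness,
         pairs = geoms)
  })
  if ("metrics" %in% config$stages) run_stage("metrics", function() {
    traj <- perturb_trajectory(model, n_frames = config$n_frames,
                               amplitude = config$amplitude,
                               seed = config$seed)
    avg <- average_structure(traj)
    pairs <- find_base_pairs(model)
    key <- vapply(pairs, function(p) p$res1$resno, numeric(1))
    ov <- NULL
    if (length(pairs) >= 2) {
      o <- order(key)
      ov <- stacking_overlap(avg, pairs[[o[1]]], pairs[[o[2]]])
    }
    list(n_frames = n_frames(traj),
         overlap_ring = if (!is.null(ov)) ov$area_ring else NA,
         overlap_exocyclic = if (!is.null(ov)) ov$area_with_exocyclic else NA)
  })
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
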