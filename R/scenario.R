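# End-to-end scenario runner: configuration, validation, artifact writing.
# A scenario binds simulation parameters to per-reaction digestion plans
# and droplet run configurations (SmaI for the VCN/REC reaction, AleI for
# the junction reaction, none for RT), with a single global seed fanned out
# into stage-specific substreams.

#' Default scenario configuration
#'
#' A reference scenario: 5' and 3' vectors at mean 8 and 12 vector
#' genomes per diploid genome, HR fraction `theta`, concatemer load
#' calibrated so the expected assay-detectable junction fraction equals
#' `concat_target`, and three reactions (SmaI VCN/REC, AleI junction, RT).
#'
#' @param name scenario name.
#' @param theta HR fraction.
#' @param concat_target target assay-detectable junction fraction; used to
#'   calibrate `concat_fraction` via [phi_for_concat_target()].
#' @param seed global seed.
#' @param host_genomes diploid genome equivalents.
#' @param n_droplets droplets per reaction.
#' @return scenario list (can be written with [write_scenario()]).
#' @export
default_scenario <- function(name = "reference", theta = 0.5,
                             concat_target = 0.04, seed = 1L,
                             host_genomes = 10000L, n_droplets = 20000L) {
  list(
    name = name,
    seed = as.integer(seed),
    sim = list(u5 = 8, u3 = 12, hr_fraction = theta,
               concat_target = concat_target,
               chain_length_p = 0.5,
               orientation_weights = c(1, 1, 1),
               host_genomes = as.integer(host_genomes)),
    reactions = list(
      vcn = list(digestion = "SmaI", mode = "calls",
                 n_droplets = as.integer(n_droplets)),
      junction = list(digestion = "AleI", mode = "calls",
                      n_droplets = as.integer(n_droplets)),
      rt = list(enabled = TRUE, leak_rate = 0.02, expr_rate = 2,
                n_droplets = as.integer(n_droplets))))
}

#' Read / write a scenario file (YAML)
#' @param path scenario file.
#' @return scenario list.
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  validate_scenario(sc)
  sc
}

#' @rdname read_scenario
#' @param scenario scenario list.
#' @export
write_scenario <- function(scenario, path) {
  validate_scenario(scenario)
  yaml::write_yaml(scenario, path)
  invisible(path)
}

validate_scenario <- function(sc) {
  fail <- function(field, why) stop_dq(sprintf("%s: %s", field, why),
                                       "scenario_invalid")
  if (is.null(sc$seed)) fail("seed", "missing")
  if (is.null(sc$sim)) fail("sim", "missing")
  num_in <- function(field, lo = -Inf, hi = Inf, default = NULL) {
    v <- sc$sim[[field]] %||% default
    if (is.null(v)) fail(paste0("sim.", field), "missing")
    if (!is.numeric(v) || any(v < lo) || any(v > hi))
      fail(paste0("sim.", field), sprintf("must be numeric in [%g, %g]", lo, hi))
    v
  }
  num_in("u5", 0); num_in("u3", 0); num_in("hr_fraction", 0, 1)
  if (is.null(sc$sim$concat_fraction) && is.null(sc$sim$concat_target))
    fail("sim.concat_fraction", "missing (or give sim.concat_target)")
  num_in("chain_length_p", 1e-6, 1, default = 0.5)
  num_in("host_genomes", 1)
  if (is.null(sc$reactions$vcn)) fail("reactions.vcn", "missing")
  if (is.null(sc$reactions$junction)) fail("reactions.junction", "missing")
  for (rx in c("vcn", "junction")) {
    nd <- sc$reactions[[rx]]$n_droplets %||% 20000L
    if (nd <= 0) fail(paste0("reactions.", rx, ".n_droplets"), "empty run: must be > 0")
  }
  invisible(sc)
}

scenario_sim_params <- function(sc, seed) {
  p0 <- sim_params(
    u5 = sc$sim$u5, u3 = sc$sim$u3, hr_fraction = sc$sim$hr_fraction,
    concat_fraction = sc$sim$concat_fraction %||% 0,
    chain_length_p = sc$sim$chain_length_p %||% 0.5,
    orientation_weights = unlist(sc$sim$orientation_weights %||% c(1, 1, 1)),
    host_genomes = sc$sim$host_genomes, seed = seed)
  if (!is.null(sc$sim$concat_target) && is.null(sc$sim$concat_fraction))
    p0$concat_fraction <- phi_for_concat_target(sc$sim$concat_target, p0)
  p0
}

#' Run a scenario end to end
#'
#' Simulates the molecule population, digests and runs each declared
#' reaction, writes all artifacts (species table, fragment tables, droplet
#' CSVs with metadata sidecars, quantification report JSON, log with all
#' seeds and defaults) into `out_dir`, and returns the `quant_report`.
#' Deterministic given the scenario: the global seed is fanned out into
#' fixed substreams for simulation, each reaction's partitioning, and
#' transcripts. A reaction whose declared digestion does not match the
#' protocol (e.g. VCN/REC without SmaI) is run anyway and flagged in the
#' report, since running it demonstrates the bias the digestion removes.
#'
#' @param scenario scenario list or path to a YAML scenario file.
#' @param out_dir artifact directory (created if needed).
#' @return the `quant_report`, invisibly; artifacts on disk.
#' @export
run_scenario <- function(scenario, out_dir) {
  sc <- if (is.character(scenario)) read_scenario(scenario) else
    validate_scenario(scenario)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(sc$seed, 6)
  constructs <- build_default_constructs()
  panel <- default_assay_panel(constructs$five_prime, constructs$three_prime)

  p <- scenario_sim_params(sc, seeds[1])
  sim <- simulate_sample(p)
  write_species_table(sim$population, file.path(out_dir, "species.tsv"))
  jsonlite::write_json(
    list(T5 = sim$truth$T5, T3 = sim$truth$T3, R = sim$truth$R,
         true_hr = sim$truth$true_hr, true_concat = sim$truth$true_concat),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = 10,
    pretty = TRUE)

  run_reaction <- function(rx_name, assay_names, expected_digestion, seed) {
    rx <- sc$reactions[[rx_name]]
    digestion <- rx$digestion %||% expected_digestion
    frags <- digest(sim$population, digestion, constructs, panel)
    sub <- panel_subset(panel, assay_names)
    cfg <- ddpcr_config(n_droplets = rx$n_droplets %||% 20000L,
                        noise_sd = rx$noise_sd %||% 50,
                        seed = seed)
    occ <- partition_fragments(frags, cfg)
    dd <- detect_droplets(occ, sub, mode = rx$mode %||% "calls")
    write_fragment_table(frags, file.path(out_dir, paste0(rx_name, "_fragments.tsv")))
    write_droplet_csv(dd, file.path(out_dir, paste0(rx_name, "_droplets.csv")),
                      digestion = digestion)
    gate_droplets(dd, sub, digestion = digestion)
  }

  g_vcn <- run_reaction("vcn", c("FIVE", "THREE", "REC", "TTN"), "SmaI", seeds[2])
  g_jx <- run_reaction("junction",
                       c("jxAB", "jxCD", "jxAD", "jxCB", "FIVE", "THREE"),
                       "AleI", seeds[3])

  g_rt <- NULL; g_mrt <- NULL
  rt <- sc$reactions$rt
  if (!is.null(rt) && isTRUE(rt$enabled %||% TRUE)) {
    tp <- simulate_transcripts(sim$population,
                               leak_rate = rt$leak_rate %||% 0.02,
                               expr_rate = rt$expr_rate %||% 2,
                               seed = seeds[4])
    tf <- transcript_fragments(tp)
    cfg <- ddpcr_config(n_droplets = rt$n_droplets %||% 20000L, seed = seeds[5])
    sub <- panel_subset(panel, c("FIVE_RT", "THREE_RT", "REC_RT"))
    dd <- detect_droplets(partition_fragments(tf, cfg), sub, mode = "calls")
    write_droplet_csv(dd, file.path(out_dir, "rt_droplets.csv"),
                      digestion = "none")
    g_rt <- gate_droplets(dd, sub, digestion = "none")
    # minus-RT control: no reverse transcription, no template
    mrt_tf <- structure(list(fragments = list(), counts = numeric(0),
                             enzymes = character(0)),
                        class = "fragment_population")
    dd0 <- detect_droplets(partition_fragments(mrt_tf, cfg), sub, mode = "calls")
    write_droplet_csv(dd0, file.path(out_dir, "minus_rt_droplets.csv"),
                      digestion = "none")
    g_mrt <- gate_droplets(dd0, sub, digestion = "none")
  }

  report <- quant_report(g_vcn, g_jx, rt_run = g_rt, minus_rt_run = g_mrt,
                         allow_protocol_mismatch = TRUE)
  for (f in report$flags) warning(f, call. = FALSE)
  write_report_json(report, file.path(out_dir, "report.json"))
  writeLines(c(
    sprintf("scenario: %s", sc$name %||% "unnamed"),
    sprintf("package: dualAAVquant %s",
            as.character(utils::packageVersion("dualAAVquant"))),
    sprintf("global_seed: %d", sc$seed),
    sprintf("substream_seeds: %s", paste(seeds, collapse = ",")),
    sprintf("sim: u5=%g u3=%g theta=%g phi=%g p=%g host_genomes=%d",
            p$u5, p$u3, p$hr_fraction, p$concat_fraction,
            p$chain_length_p, p$host_genomes)),
    file.path(out_dir, "run.log"))
  invisible(report)
}

#' Quantify from droplet exports alone
#'
#' Real-data entry point: gates and estimates from droplet CSVs (as
#' written by [write_droplet_csv()], or any CSV with the same schema and
#' metadata sidecar) without any simulation stage.
#'
#' @param vcn_csv SmaI-reaction droplet CSV.
#' @param junction_csv AleI-reaction droplet CSV (optional).
#' @param rt_csv,minus_rt_csv RT reaction CSVs (optional).
#' @param thresholds amplitude thresholds forwarded to [gate_droplets()].
#' @return a `quant_report`.
#' @export
quantify_only <- function(vcn_csv, junction_csv = NULL, rt_csv = NULL,
                          minus_rt_csv = NULL, thresholds = NULL) {
  constructs <- build_default_constructs()
  panel <- default_assay_panel(constructs$five_prime, constructs$three_prime)
  g <- function(path) {
    if (is.null(path)) return(NULL)
    dd <- read_droplet_csv(path)
    gate_droplets(dd, panel, thresholds = thresholds,
                  digestion = dd$digestion %||% NA_character_)
  }
  quant_report(g(vcn_csv), g(junction_csv), rt_run = g(rt_csv),
               minus_rt_run = g(minus_rt_csv),
               allow_protocol_mismatch = TRUE)
}
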