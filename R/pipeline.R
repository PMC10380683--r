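# One-call in-memory pipeline for simulation studies: simulate a
# population, run the SmaI VCN/REC reaction and (optionally) the AleI
# junction reaction, and assemble the quantification report, without any
# file artifacts. run_scenario() is the artifact-writing counterpart.

#' Simulate a sample and quantify it
#'
#' Runs the full in-silico protocol on one simulated sample: digestion
#' (SmaI for the VCN/REC reaction, AleI for the junction reaction),
#' Poisson droplet partitioning, calls-mode detection, gating and
#' estimation. Setting `vcn_digestion = "none"` skips the SmaI
#' pre-digestion, which reproduces the head-to-tail concatemer bias the
#' digestion exists to remove (the report is flagged accordingly).
#'
#' @param p a [sim_params()] object.
#' @param n_droplets droplets per reaction.
#' @param run_seed seed for the droplet stages (defaults to `p$seed + 1`).
#' @param vcn_digestion `"SmaI"` (protocol) or `"none"` (bias
#'   demonstration).
#' @param junction also run the AleI junction reaction.
#' @param constructs,panel defaults from [build_default_constructs()] and
#'   [default_assay_panel()].
#' @return list with `truth` (the simulation `ground_truth`) and `report`
#'   (the `quant_report`).
#' @export
simulate_and_quantify <- function(p, n_droplets = 20000L, run_seed = NULL,
                                  vcn_digestion = c("SmaI", "none"),
                                  junction = TRUE,
                                  constructs = NULL, panel = NULL) {
  vcn_digestion <- match.arg(vcn_digestion)
  if (is.null(constructs)) constructs <- build_default_constructs()
  if (is.null(panel))
    panel <- default_assay_panel(constructs$five_prime, constructs$three_prime)
  if (is.null(run_seed)) run_seed <- p$seed + 1L
  sim <- simulate_sample(p)

  gate_reaction <- function(enzyme, assay_names, seed) {
    frags <- digest(sim$population, enzyme, constructs, panel)
    cfg <- ddpcr_config(n_droplets = n_droplets, seed = seed)
    dd <- detect_droplets(partition_fragments(frags, cfg),
                          panel_subset(panel, assay_names), mode = "calls")
    gate_droplets(dd, digestion = enzyme)
  }
  g_vcn <- gate_reaction(vcn_digestion, c("FIVE", "THREE", "REC", "TTN"),
                         run_seed)
  g_jx <- if (junction)
    gate_reaction("AleI", c("jxAB", "jxCD", "jxAD", "jxCB", "FIVE", "THREE"),
                  run_seed + 1L)
  list(truth = sim$truth,
       report = quant_report(g_vcn, g_jx, allow_protocol_mismatch = TRUE))
}
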